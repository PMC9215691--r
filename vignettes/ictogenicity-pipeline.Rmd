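---
title: "Brain network ictogenicity from interictal EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain network ictogenicity from interictal EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

People with photosensitive epilepsy (PSE) show epileptiform EEG discharges
(a photoparoxysmal response, PPR) under intermittent photic stimulation.
`ictonet` implements a computational pipeline that asks whether the
predisposition is visible in *resting* interictal EEG, without any
stimulation: functional networks are inferred from 20-channel scalp EEG,
a phenomenological seizure model is placed on each network, and two
in-silico quantities are compared between a PPR and a non-PPR group:

* **Brain network ictogenicity (BNI)** — the mean fraction of simulated
  time the network's nodes spend in a seizure-like state; a proxy for
  widespread seizure propensity.
* **Node ictogenicity (NI)** — the normalised drop in BNI caused by
  deleting one node; a proxy for that region's contribution to seizure
  generation. Occipital NI (channels O1, O2) is the quantity of interest
  for photosensitivity.

Because the clinical recordings behind this design are not publicly
deposited, the package ships a synthetic-EEG generator with controllable
ground truth, so every stage — and the pipeline end to end — is testable.

## Signal conditioning

Raw segments (20 s per segment, three segments per subject, at least one
minute apart) pass through, in order:

1. **Downsampling to 250 Hz.** Implemented as Fourier resampling: the
   spectrum is truncated at the new Nyquist frequency and inverted on the
   coarser grid. Spectral truncation *is* the anti-alias filter; the method
   is delay-free and exact for band-limited signals, which matters because
   the phase estimates downstream must not inherit a resampler group delay
   (the installed polyphase resampler leaves a ~3-sample delay and a ~3%
   amplitude error on a 7 Hz tone; measured during development).
2. **Band-pass 6–9 Hz** (low alpha), fourth-order Butterworth applied
   forward and backward (`signal::filtfilt`), i.e. zero phase, squared
   magnitude response.
3. **Common-average re-reference**: at every sample the mean over the 20
   channels is subtracted. The clinical description ("rereferenced to the
   average of all artifact-free segments") is ambiguous between a
   per-segment and an across-segments reference; the per-segment reading is
   implemented. The reference is linear, so the choice does not interact
   with the filtering.

A canonical segment is therefore 20 x 5000 samples. Segment selection from
long recordings (`pick_segments`) is positional with an optional amplitude
veto (default off) — clinical artifact screening is manual and out of scope.

## Functional networks

Connectivity is the **phase-locking value**: with instantaneous phases from
the Hilbert transform (FFT construction), for channels *i, j*:

PLV_ij = |mean_k exp(i Δφ_ij(t_k))|, and the mean lag
τ_ij = arg Σ_k exp(i Δφ_ij(t_k)).

An edge survives only if

* **non-zero lag**: |τ_ij| > 2π/fs (0.0251 rad at 250 Hz). τ is signed, so
  the absolute value is used — the only reading consistent with removing
  zero-lag volume-conduction artefacts. Ties and boundary values reject.
* **surrogate significance**: the observed PLV strictly exceeds at least
  ⌈0.95·n⌉ of n surrogate PLVs (95 of 99 at the default). Surrogates are
  iterative amplitude-adjusted Fourier transform (IAAFT) series, 10
  iterations, ending on the amplitude-adjustment step so the sorted sample
  values of each surrogate equal the original's exactly. One surrogate per
  channel is drawn per replicate and the pair PLV is recomputed from the
  matched surrogate pair, so the null preserves both channels' spectra and
  amplitude distributions. Surrogates are band-passed again before phase
  extraction because IAAFT does not exactly preserve band limits.
* Surrogate seeds derive deterministically from (root seed, replicate,
  channel), making every network reproducible.

## The seizure model

Each node is a theta neuron:

dθ_i = [(1 − cos θ_i) + (1 + cos θ_i) I_i(t)] dt,
I_i = I₀ + σ/√dt η_i + (K/N) Σ_j PLV_ji [1 − cos(θ_j − θ^s)],

with I₀ = −1.2, σ = 0.6, Euler–Maruyama step dt = 0.01 in model-time
units. With I₀ < 0 there are two fixed points, a stable rest phase
θ^s = −arccos((1+I₀)/(1−I₀)) and its unstable mirror θ^u = −θ^s; input
pushes nodes through a saddle-node-on-invariant-circle bifurcation into
rotation, the seizure-like state. All nodes start at θ^s. Noise is read as
a stochastic-differential term (σ per unit √time, i.e. σ/√dt per step
inside I_i, multiplied by the (1 + cos θ) factor as written); the
alternative per-step-SD reading leaves the network dynamically dead (the
measured escape rate is ~0 per 10³ time units at any K), so the SDE reading
is the only one that makes the coupling sweep meaningful.

**Seizure-state bookkeeping.** A sample counts as ictal while the phase is
traversing the *escape arc* — the arc from θ^u counterclockwise through π
back to θ^s. Membership alone is not enough: the arc's endpoint is θ^s
itself, so plain membership would classify the sub-θ^s half of ordinary
resting noise as ictal (measured BNI ≈ 0.55 at K = 0 under that rule).
The classifier therefore uses minimal crossing bookkeeping: a node becomes
ictal when its counterclockwise offset from θ^s crosses θ^u − θ^s in a
forward step, and returns to rest when the offset falls back below that
value (falling back over the barrier, or completing the rotation). Constant
trajectories are classified by membership (a trajectory parked at π is
ictal throughout); a uniform rotation is ictal for exactly the arc fraction
beyond θ^u. With this rule BNI(K) on a default synthetic network rises
from 0 at K ≈ 1 to ≈ 0.75 at K = 40, with BNI(0) = 0.

For I₀ ≥ 0 the fixed points have merged; the simulator starts at the ghost
point 0 and classifies any displacement as ictal, so a suprathreshold
network reports fractions ≈ 1.

## BNI, calibration, and NI

* `bni(net, K)` — mean over nodes of the post-transient ictal fraction
  (transient: first 5% of steps), averaged over repetitions.
* `bni_hat` — trapezoidal area under BNI(K) for K in [1, 40] on a uniform
  40-point grid shared by all networks (raw area, range 0–39).
* `calibrate_K` — coarse scan then bisection to the K* where BNI = 0.5
  (tolerance 0.05 by default). In the NI formula BNIpre is fixed at the
  calibration level 0.5, not the realised value at K*, which is within
  tolerance by construction.
* `node_ictogenicity` — delete each node in turn, re-simulate at the same
  K*, NI(i) = (0.5 − BNIpost(i))/0.5. The K/N normalisation uses the
  reduced network size (N−1). Consequently removing a node that never
  rotates *raises* BNI slightly (the effective coupling grows and a
  zero-contributing node leaves the average), so NI can be mildly negative;
  this is expected and is exactly the signature the synthetic cohorts
  exploit (below). Calibration is per segment; a subject's profile is the
  mean of its (typically three) segment-level values.
* Seeds derive deterministically from (root, K index, repetition, deleted
  node), so NI columns are reproducible and node comparisons are not
  confounded by shared noise streams.

## Group statistics

The conventions are fixed to those that reproduce published worked
examples for two groups of 26 and 20 subjects:

* The reported "U statistic" is the rank sum W of group 1 (mid-ranks under
  ties); W = 724 at n₁ = 26 exceeds n₁n₂ = 520, so it cannot be the
  classical U, which is W − n₁(n₁+1)/2.
* Right tail: z = (W − μ − 0.5)/σ, p = 1 − Φ(z); two-sided:
  z = (W − μ − 0.5·sign(W − μ))/σ, p = 2(1 − Φ(|z|)); μ = n₁(n₁+n₂+1)/2,
  σ tie-corrected. These reproduce z = −1.23 (BNI), z = 2.49 (O2),
  z = −0.94 (C4), z = 1.72 (T4) and the corrected occipital p-values 0.013
  and 0.18 from the printed rank sums.
* For small tie-free samples (n ≤ 20) `ranksum` reports the exact p from
  the Mann–Whitney distribution instead of the normal approximation. The
  continuity-corrected approximation is within 0.02 of exact enumeration
  whenever both groups have at least 3 observations (total n ≤ 10,
  verified exhaustively) but deviates by up to 0.064 for group sizes 1–2,
  which is why the exact mode exists and engages automatically.
* Three Holm families, as in the published analysis: the BNI test (m = 1),
  the one-sided occipital NI tests {O1, O2} (m = 2), and the exploratory
  two-sided scan over the remaining 18 nodes (m = 18).
* Effect sizes are unpaired median differences with 95% BCa bootstrap CIs
  (5000 stratified resamples, seedable; percentile fallback with a warning
  when BCa is degenerate).
* ROC/AUC uses the Mann–Whitney identity AUC = U/(n₁n₂); sensitivity and
  specificity are reported at the Youden-optimal threshold (the source
  analyses do not state their threshold rule; among ties the higher
  sensitivity is taken).
* Supplementary measures: relative 6–9 Hz and 7.5–12.5 Hz Welch power
  (2 s Hann windows, 50% overlap, denominator 1–45 Hz — the total band is a
  package choice, the sources defer to cited methods) on the occipital
  channels, and occipital connectivity strength (in- plus out-strength,
  i.e. twice the row sum of the symmetric PLV matrix).

## The synthetic-EEG generator

Channels are stochastic Kuramoto-type phase oscillators observed through a
cosine plus white observation noise: natural frequencies uniform in 6–9 Hz,
pairwise pulls `coupling_gain * pair_coupling * sin(θ_j − θ_i + lag_ij)`,
phase diffusion `phase_noise_sd` (rad/√s), Euler–Maruyama with four
substeps per output sample, bit-reproducible given the spec. Defaults
(gain 110 rad/s, phase noise 6 rad/√s) make a 0.9 coupling lock any
detuning within the band with a lag bias below 0.1 rad, while uncoupled
channels decorrelate within a fraction of a second.

Lag targets come from a per-channel phase potential laid out as a
travelling wave: channels ranked front-to-back along the scalp get phases
evenly spaced over the full circle. Every coupled pair then has a
consistent lag of at least 2π/n (well above the zero-lag rejection
threshold), and — the real reason for the full-circle layout — the coherent
component cancels in the channel mean, so common-average re-referencing
does not leak a synchronous field into otherwise uncoupled channels. With a
partial-arc potential that leak is large enough to build spurious
significant edges on a fully detached channel (measured row sums ≈ 3.5).

**Cohort design.** Two facts shaped the two-group generator, both measured
during development. First, pairwise PLV in oscillator networks is
effectively bimodal: locking to a coherent cluster accumulates over edges,
so realistic meshes are either unlocked (PLV ≈ 0.1) or saturated
(PLV ≈ 0.8), and graded "hub-strength" manipulations do not survive PLV
inference. Second, networks that can barely reach BNI = 0.5 inside
K ∈ [1, 40] produce wildly noisy NI values, because the calibration
shortfall enters every node's NI. The default cohort therefore uses a
design robust to both: all channels except O2 form a uniformly coupled
coherent core (coupling 0.3) on which calibration always succeeds, and the
right occipital channel O2 is detached at baseline. The group-A
manipulation adds `occipital_boost` (default +0.4) to all couplings of O1
and O2, integrating O2 into the core. A detached node's NI sits reliably
near −0.13 (its removal raises K/N and drops a never-rotating node from the
network average) whereas an integrated node's NI is ≈ −0.02, giving a
subject-level separation of several pooled standard deviations while O1 —
in the core in both groups — shows no group difference, so the pipeline
reproduces an O2-specific effect. Subject- and segment-level variability is
relative (multiplicative truncated-normal) jitter on coupling strengths;
additive jitter would re-attach the detached channel and blur the ground
truth. Amplitudes are arbitrary units: the pipeline is amplitude-scale
invariant (phases only), so no microvolt calibration is attempted.

What the generator does *not* emulate: photic stimulation and PPR
waveforms, artefacts, 1/f broadband spectra, volume-conduction mixing
beyond the common reference, and any amplitude asymmetries. Passing tests
therefore demonstrate the pipeline's internal correctness and its ability
to recover a controlled occipital coupling manipulation — not clinical
performance on real EEG.

## Problem sizes used by the test-suite and acceptance script

Full-scale settings (the package defaults) are 20 s segments at 250 Hz, 99
surrogates, T = 4×10⁶ integration steps, a 40-point K grid. The test suite
and the acceptance script run the same code at reduced sizes chosen as the
smallest that keep Monte-Carlo error well below the effects being tested:
segments of 4–10 s, 19 surrogates where the decision level only requires
that the observed PLV beat all of them (1/20 = 0.05, the same level as
95 of 99), 2×10⁴–10⁵ integration steps, 5–8-point K grids, and cohorts of
13 + 10 subjects × 3 segments of 4 s on the 8-channel posterior montage. The
boost-recovery and type-I experiments use 5 cohort replicates per arm with
thresholds ≥ 4/5 and ≤ 1/5, preserving the intended 80%/20% rates. At the
measured effect size (separation ≈ 5–9 SD) these replicate counts have
essentially no resolution cost.

## Known limitations

* The theta-model seizure bookkeeping (crossing-based escape-arc
  occupancy) follows the published model description but the original
  MATLAB implementation may differ in discretisation details; results rely
  on invariants (monotonicity in K, calibration self-consistency), not
  bit-level agreement.
* BNI(K) saturates around 0.75–0.8 at K = 40 on dense synthetic networks
  because well transits during sustained rotation are not counted as
  ictal; the K-integrated BNI and all group comparisons are unaffected.
* `calibrate_K` returns a boundary K when the target is within tolerance
  at the scan edge, and errors otherwise ("network cannot reach BNI 0.5");
  subjects with uncalibratable segments are excluded with a message.
* The exploratory 18-node scan inherits the O1-in-core design: in
  synthetic cohorts the non-occipital nodes are exchangeable, so its Holm
  family should show no signal (and does not).
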