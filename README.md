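# ictonet

Brain network ictogenicity from interictal EEG functional networks.

`ictonet` is for researchers studying photosensitive epilepsy (and network
models of epilepsy generally) who want to quantify seizure propensity from
*resting* scalp EEG, without photic stimulation. It implements a complete,
tested pipeline:

1. **Signal conditioning** — downsampling to 250 Hz, zero-phase 6–9 Hz
   (low alpha) fourth-order Butterworth band-pass, common-average
   re-referencing (`preprocess_segment()`).
2. **Functional networks** — phase-locking value (PLV) connectivity from
   Hilbert phases, with volume-conduction control (edges with mean lag
   |τ| ≤ 2π/fs are rejected) and significance testing against 99 IAAFT
   surrogates at the 95% level (`build_network()`).
3. **Seizure modelling** — stochastic theta neurons
   `dθᵢ = [(1 − cos θᵢ) + (1 + cos θᵢ) Iᵢ] dt` with
   `Iᵢ = I₀ + σ/√dt·η + (K/N) Σⱼ PLVⱼᵢ [1 − cos(θⱼ − θˢ)]`
   (I₀ = −1.2, σ = 0.6) placed on each network (`simulate_theta()`).
4. **Ictogenicity** — brain network ictogenicity BNI(K) (mean fraction of
   time in the seizure-like rotating state), its robust K-integrated form
   BNÎ = ∫₁⁴⁰ BNI(K) dK, calibration of K to BNIpre = 0.5, and node
   ictogenicity NI(i) = (BNIpre − BNIpost(i))/BNIpre by single-node
   deletion (`bni_hat()`, `calibrate_K()`, `node_ictogenicity()`).
5. **Group statistics** — one-sided Mann–Whitney tests for BNI and
   occipital NI, an exploratory two-sided scan over the other nodes, Holm
   correction per family, BCa bootstrap median-difference effect sizes,
   ROC/AUC via the Mann–Whitney identity, and supplementary relative
   alpha-power and connectivity-strength comparisons (`ranksum()`,
   `run_cohort()`).

Because the clinical recordings this design targets are not publicly
available, the package includes a synthetic-EEG generator
(`generate_segment()`, `generate_cohort()`) — stochastic Kuramoto-type
phase oscillators with controllable pairwise coupling and lags — so the
whole pipeline is testable against known ground truth.

## Worked example: group statistics from published rank sums

For two groups of 26 (PPR) and 20 (non-PPR) subjects, the rank-sum
statistics reported in the photosensitivity literature can be recomputed
directly:

```r
library(ictonet)

bni <- ranksum_from_summary(556, 26, 20, tail = "right")
sprintf("BNI:  z = %.2f, one-sided p = %.2f", bni$z, bni$p)

o1 <- ranksum_from_summary(652, 26, 20, tail = "right")
o2 <- ranksum_from_summary(724, 26, 20, tail = "right")
pc <- holm(c(o1$p, o2$p))
sprintf("NI O1: z = %.2f, corrected p = %.2f", o1$z, pc[1])
sprintf("NI O2: z = %.2f, corrected p = %.3f", o2$z, pc[2])
sprintf("AUC(O2) = %.2f", (724 - 26 * 27 / 2) / (26 * 20))
```

```
BNI:  z = -1.23, one-sided p = 0.89
NI O1: z = 0.90, corrected p = 0.18
NI O2: z = 2.49, corrected p = 0.013
AUC(O2) = 0.72
```

The brain-wide BNI does not separate the groups (p = 0.89), while the NI of
the right occipital channel O2 is significantly higher in the PPR group
(corrected p = 0.013) — occipital, not widespread, hyperexcitability.

## Worked example: end-to-end synthetic cohort

A reduced-scale synthetic cohort (13 "PPR-like" vs 10 control subjects,
3 segments each, occipital coupling boost +0.4 in the PPR-like group,
8-channel posterior montage) pushed through the full pipeline:

```r
cfg <- analysis_config(profile = "fast", n_steps = 1.5e4, n_reps_ni = 3,
                       tol = 0.04, n_boot = 500, seed = 1)
coh <- generate_cohort(reduced_cohort_spec(seed = 1))
run_cohort(coh, cfg, nodes = c("O1", "O2"))
```

```
<cohort_report>
  subjects: 23 (13 PPR, 10 nonPPR)
  BNI (one-sided): W = 221, z = 4.00, p = 3.17e-05
  NI O1 (one-sided): z = -3.26, corrected p = 0.999
  NI O2 (one-sided): z = 4.00, corrected p = 6.33e-05
  ROC (NI of O2): AUC = 1.00, sens = 1.00, spec = 1.00
```

The pipeline recovers the manipulation: NI(O2) is significantly higher in
the boosted group (the boost also raises total coupling, so the synthetic
BNI test is significant here, unlike in clinical data), NI(O1) — whose
integration into the network is identical in both groups — shows nothing,
and NI(O2) separates the groups completely. With the boost set to 0, all
corrected p-values are ≈ 1. Takes a couple of minutes on one core.

A thin command-line wrapper with subcommands (`simulate-cohort`,
`build-networks`, `ictogenicity`, `group-stats`, `run-all`) is installed at
`inst/exec/ictonet`; see its header for usage.

## Further reading

The methods vignette (`vignettes/ictogenicity-pipeline.Rmd`) documents the
models and their assumptions, every tunable parameter with its default and
rationale, the synthetic-data design (what it emulates and what it does
not), the numerical choices, and known limitations.
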