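#' Theta-model simulation parameters
#'
#' Constants of the stochastic theta-neuron network simulator. Each node is
#' a phase oscillator `dtheta = (1 - cos theta) + (1 + cos theta) * I(t)`;
#' with baseline current `I0 < 0` it rests near the stable phase and noise
#' or network input can push it through the saddle-node-on-invariant-circle
#' bifurcation into sustained rotation (the seizure-like state).
#'
#' @param I0 Baseline current (default -1.2). Negative values give a
#'   bistable rest/rotation regime; for `I0 >= 0` no resting state exists
#'   and every node rotates perpetually.
#' @param noise_sd Noise standard deviation sigma (default 0.6). Noise
#'   enters as an additive current `sigma/sqrt(dt) * eta` per step, i.e. as
#'   white noise of intensity sigma per unit sqrt(time).
#' @param K Global coupling scale.
#' @param dt Integration step in model-time units (default 0.01).
#' @param n_steps Total integration steps (default 4e6 at full scale;
#'   analyses at reduced scale pass a smaller value).
#' @param transient_steps Initial steps discarded before classifying states
#'   (default 5% of `n_steps`).
#' @param seed Integer seed.
#' @return An object of class `theta_params`.
#' @export
theta_params <- function(I0 = -1.2, noise_sd = 0.6, K = 1, dt = 0.01,
                         n_steps = 4e6, transient_steps = round(0.05 * n_steps),
                         seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  if (n_steps <= transient_steps || transient_steps < 0)
    stop("need n_steps > transient_steps >= 0")
  structure(list(I0 = I0, noise_sd = noise_sd, K = K, dt = dt,
                 n_steps = as.integer(n_steps),
                 transient_steps = as.integer(transient_steps),
                 seed = as.integer(seed)),
            class = "theta_params")
}

#' Stable resting phase of the theta neuron
#'
#' Solves `(1 - cos theta) + (1 + cos theta) * I0 = 0` for the stable fixed
#' point `theta_s = -acos((1 + I0)/(1 - I0))`; the unstable point is its
#' mirror image `+acos(...)`.
#'
#' @param I0 Baseline current, strictly negative.
#' @return Stable phase in radians (negative).
#' @export
stable_phase <- function(I0) {
  if (!is.numeric(I0) || length(I0) != 1L || I0 >= 0)
    stop("I0 must be a single negative number (no stable fixed point otherwise)")
  -acos((1 + I0) / (1 - I0))
}

#' Unstable fixed point of the theta neuron
#' @inheritParams stable_phase
#' @return Unstable phase in radians (positive).
#' @export
unstable_phase <- function(I0) -stable_phase(I0)

#' Simulate theta-model dynamics on a functional network
#'
#' Euler-Maruyama integration of the coupled theta-neuron network from
#' `theta_i(0) = theta_s`. Node input is
#' `I_i = I0 + sigma/sqrt(dt) * eta_i + (K/N) * sum_j W[j, i] * (1 - cos(theta_j - theta_s))`,
#' where `N` is the current network size. The returned per-node seizure
#' fraction is the share of post-transient samples on the escape arc (see
#' [seizure_classification()]).
#'
#' @param net A `functional_network`, or a plain symmetric weight matrix.
#' @param params A [theta_params()].
#' @param noise Optional pre-drawn standard-normal noise matrix
#'   (nodes x steps); when supplied the seed is ignored. Mainly for
#'   equivariance checks.
#' @return An object of class `simulation_result`: list with
#'   `seizure_fraction` (named per node), `n_nodes`, `params`.
#' @export
simulate_theta <- function(net, params, noise = NULL) {
  w <- if (inherits(net, "functional_network")) net$weights else as.matrix(net)
  labels <- if (inherits(net, "functional_network")) net$channel_labels
            else rownames(w)
  stopifnot(inherits(params, "theta_params"))
  if (is.null(noise)) set.seed(params$seed)
  frac <- theta_sim_cpp(w, params$I0, params$noise_sd, params$K, params$dt,
                        params$n_steps, params$transient_steps, noise)
  if (!is.null(labels)) names(frac) <- labels
  structure(list(seizure_fraction = frac, n_nodes = nrow(w),
                 params = params),
            class = "simulation_result")
}

#' Classify trajectory samples as seizure-like
#'
#' A sample is ictal while the phase is traversing the escape arc: the arc
#' running counterclockwise from the unstable fixed point `theta_u` through
#' pi back to the stable phase `theta_s`. A node enters the ictal state when
#' its counterclockwise offset from `theta_s` crosses `theta_u - theta_s` in
#' a forward step, and leaves it when the offset falls back below that value
#' (falling back into the well, or completing the rotation). The first
#' sample is classified by arc membership alone, so constant trajectories on
#' the escape arc count as ictal throughout. Pointwise arc membership
#' without the crossing bookkeeping would label the sub-`theta_s` half of
#' ordinary resting noise as ictal.
#'
#' @param theta_trajectory Numeric vector of phases (radians, any wrapping).
#' @param I0 Baseline current used in the simulation.
#' @return Logical vector, `TRUE` for seizure-like samples.
#' @export
seizure_classification <- function(theta_trajectory, I0) {
  if (any(!is.finite(theta_trajectory)))
    stop("trajectory contains non-finite phases")
  ts <- if (I0 < 0) stable_phase(I0) else 0
  arc <- if (I0 < 0) unstable_phase(I0) - ts else 0
  d <- (theta_trajectory - ts) %% (2 * pi)
  out <- logical(length(d))
  state <- d[1] > arc
  out[1] <- state
  for (k in seq_along(d)[-1]) {
    dd <- d[k] - d[k - 1]
    if (!state && d[k] > arc && d[k - 1] <= arc && dd > 0 && dd < pi)
      state <- TRUE
    else if (state && d[k] <= arc)
      state <- FALSE
    out[k] <- state
  }
  out
}
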