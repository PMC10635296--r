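# Gate sequences and multi-exponential gated decays.
#
# A time-gated intensified camera samples a fluorescence decay with a
# finite gate: the counts recorded at gate opening time t are the integral
# of the instantaneous decay over [t, t + w]. For a single exponential the
# gate factor tau*(1 - exp(-w/tau)) is independent of t, so tail-fitted
# lifetimes are unaffected by gating; amplitudes pick up the factor, which
# the dual-basis fit models explicitly.

#' Camera gate sequence
#'
#' Describes the gating scheme of a time-gated intensified camera: gates of
#' width `gate_width` opened every `step` starting at `t0`. The default
#' mirrors a typical gated-ICCD acquisition: 500 ps gates, 200 ps steps,
#' 30 gates (~6 ns of decay per laser cycle).
#'
#' @param gate_width gate width in ns (> 0).
#' @param step delay between consecutive gate openings in ns (> 0).
#' @param n_gates number of gates (>= 3).
#' @param t0 opening time of the first gate in ns.
#' @param irf_sigma optional Gaussian instrument-response width in ns;
#'   0 means ideal gating. When > 0, tail fits must start after
#'   `3 * irf_sigma` past the peak.
#' @return an object of class `gate_sequence`.
#' @export
gate_sequence <- function(gate_width = 0.5, step = 0.2, n_gates = 30L,
                          t0 = 0, irf_sigma = 0) {
  stop_if_not_scalar(gate_width, "gate_width", lo = 1e-9)
  stop_if_not_scalar(step, "step", lo = 1e-9)
  stop_if_not_scalar(t0, "t0")
  stop_if_not_scalar(irf_sigma, "irf_sigma", lo = 0)
  if (!is.numeric(n_gates) || length(n_gates) != 1L || n_gates < 3)
    stop("`n_gates` must be >= 3")
  structure(list(gate_width = gate_width, step = step,
                 n_gates = as.integer(n_gates), t0 = t0,
                 irf_sigma = irf_sigma),
            class = "gate_sequence")
}

#' Gate opening times
#' @param gates a [gate_sequence()].
#' @return numeric vector of the `n_gates` opening times (ns), strictly
#'   increasing.
#' @export
gate_times <- function(gates) {
  stopifnot(inherits(gates, "gate_sequence"))
  gates$t0 + gates$step * (seq_len(gates$n_gates) - 1L)
}

#' Decay specification
#'
#' A constant background plus a sum of exponential components,
#' `U(t) = a0 + sum_k a_k exp(-t / tau_k)`. Amplitudes are photon rates
#' (counts per ns of open gate); lifetimes in ns.
#'
#' @param a0 constant offset (counts per ns of open gate, >= 0).
#' @param amplitudes numeric vector of component amplitudes (>= 0); may be
#'   empty for an offset-only decay.
#' @param lifetimes numeric vector of component lifetimes (ns, > 0), same
#'   length as `amplitudes`.
#' @return an object of class `decay_spec`.
#' @export
decay_spec <- function(a0 = 0, amplitudes = numeric(0),
                       lifetimes = numeric(0)) {
  stop_if_not_scalar(a0, "a0", lo = 0)
  stopifnot(length(amplitudes) == length(lifetimes))
  if (length(amplitudes)) {
    stopifnot(all(is.finite(amplitudes)), all(amplitudes >= 0),
              all(is.finite(lifetimes)), all(lifetimes > 0))
  }
  structure(list(a0 = a0, amplitudes = as.numeric(amplitudes),
                 lifetimes = as.numeric(lifetimes)),
            class = "decay_spec")
}

# Expected counts in a gate opened at time t of width w for one exponential
# component of unit amplitude: integral over [t, t+w] of exp(-s/tau),
# = tau * (1 - exp(-w/tau)) * exp(-t/tau).
gate_basis <- function(t, tau, w) {
  tau * (1 - exp(-w / tau)) * exp(-t / tau)
}

# Same with a Gaussian IRF of width sigma: the instantaneous decay becomes
# the exponentially-modified Gaussian; the gate integral is evaluated
# analytically via its antiderivative.
gate_basis_irf <- function(t, tau, w, sigma) {
  # antiderivative of EMG(s) = exp(sigma^2/(2 tau^2) - s/tau) *
  #   Phi((s - sigma^2/tau)/sigma) is
  # F(s) = tau * [Phi(s/sigma) - EMG(s)]
  Femg <- function(s) {
    emg <- exp(sigma^2 / (2 * tau^2) - s / tau) *
      stats::pnorm((s - sigma^2 / tau) / sigma)
    tau * (stats::pnorm(s / sigma) - emg)
  }
  Femg(t + w) - Femg(t)
}

#' Simulate a gated fluorescence decay
#'
#' Expected counts per gate are integrals of the decay model over each gate
#' window (`a0 * gate_width` for the offset plus
#' `a_k tau_k (1 - exp(-w/tau_k)) exp(-t/tau_k)` per component), optionally
#' convolved with a Gaussian IRF and optionally Poisson sampled.
#'
#' @param spec a [decay_spec()].
#' @param gates a [gate_sequence()].
#' @param noise `"none"` (bit-reproducible expectation) or `"poisson"`.
#' @param seed integer seed, required when `noise = "poisson"`.
#' @return numeric vector of length `n_gates` of (expected or sampled)
#'   counts.
#' @examples
#' g <- gate_sequence()
#' simulate_decay(decay_spec(a0 = 5), g)[1]          # 5 * 0.5
#' simulate_decay(decay_spec(0, 1000, 1.0), g)[1]    # 1000*(1 - exp(-0.5))
#' @export
simulate_decay <- function(spec, gates, noise = c("none", "poisson"),
                           seed = NULL) {
  stopifnot(inherits(spec, "decay_spec"), inherits(gates, "gate_sequence"))
  noise <- match.arg(noise)
  mu <- expected_gate_counts(spec, gates)
  if (any(mu < 0)) stop("negative expected counts: invalid decay spec")
  if (noise == "none") return(mu)
  if (is.null(seed)) stop("`seed` is required for poisson noise")
  with_seed(seed, stats::rpois(length(mu), mu))
}

# Expected counts for a whole decay_spec on a gate sequence (vectorised in
# gates). Shared by simulate_decay and the stack generators.
expected_gate_counts <- function(spec, gates) {
  t <- gate_times(gates)
  w <- gates$gate_width
  mu <- rep(spec$a0 * w, length(t))
  for (k in seq_along(spec$amplitudes)) {
    a <- spec$amplitudes[k]; tau <- spec$lifetimes[k]
    if (a == 0) next
    b <- if (gates$irf_sigma > 0)
      gate_basis_irf(t, tau, w, gates$irf_sigma)
    else gate_basis(t, tau, w)
    mu <- mu + a * b
  }
  mu
}
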