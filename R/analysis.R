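# Whole-cell analysis chain: conductance transform, Boltzmann fits,
# decay/recovery kinetics, current density, and the summary arithmetic used
# for reporting condition effects.

#' Sodium conductance from peak transient current
#'
#' `G_Na = I_NaT / (V - V_rev)`. With current in pA and voltages in mV the
#' conductance is in nS; a negative (inward) current below the reversal
#' potential gives a positive conductance.
#'
#' @param I_NaT Peak transient current (pA), vectorised.
#' @param V Step potential (mV).
#' @param V_rev Reversal potential (mV); must differ from every `V`.
#' @return Conductance (nS).
#' @export
conductance <- function(I_NaT, V, V_rev) {
  if (any(V == V_rev))
    stop("V equals V_rev: conductance undefined", call. = FALSE)
  I_NaT / (V - V_rev)
}

#' Reversal potential from an I-V relation
#'
#' Linear interpolation of the zero crossing on the ascending limb of the
#' peak current-voltage relation (voltages above the peak-current voltage).
#' When the protocol stops short of the reversal potential (e.g. steps to
#' +60 mV with E_Na near +68 mV) the quasi-ohmic top of the ascending limb
#' is extrapolated linearly to zero instead; relations with no rising
#' limb are rejected.
#'
#' @param V Step potentials (mV).
#' @param I Peak currents (pA).
#' @return Estimated reversal potential (mV).
#' @export
estimate_reversal <- function(V, I) {
  stopifnot(length(V) == length(I), length(V) >= 3L)
  o <- order(V)
  V <- V[o]; I <- I[o]
  k0 <- which.min(I) # most negative (largest inward) peak
  Va <- V[k0:length(V)]; Ia <- I[k0:length(I)]
  s <- which(Ia[-length(Ia)] < 0 & Ia[-1L] >= 0)
  if (length(s)) {
    j <- s[1L]
    if (Ia[j + 1L] == 0) return(Va[j + 1L])
    return(Va[j] + (0 - Ia[j]) * (Va[j + 1L] - Va[j]) / (Ia[j + 1L] - Ia[j]))
  }
  # no crossing sampled: extrapolate the top of the ascending limb
  if (length(Va) < 3L)
    stop("no reversal: I-V relation has no rising limb crossing zero",
         call. = FALSE)
  m <- min(4L, length(Va))
  Vt <- utils::tail(Va, m); It <- utils::tail(Ia, m)
  fit <- stats::lm(It ~ Vt)
  slope <- stats::coef(fit)[2L]
  if (!is.finite(slope) || slope <= 0)
    stop("no reversal: ascending limb is not rising", call. = FALSE)
  unname(-stats::coef(fit)[1L] / slope)
}

.boltzmann <- function(V, amplitude, V50, k) amplitude / (1 + exp((V50 - V) / k))

# Shared Boltzmann fitting machinery. `direction` +1 fits an ascending curve
# (activation, k > 0), -1 a descending one (availability, k < 0).
.fit_boltzmann <- function(V, y, direction, what) {
  stopifnot(length(V) == length(y))
  if (length(V) < 5L)
    stop("need at least 5 points to fit the ", what, " curve", call. = FALSE)
  o <- order(V)
  V <- V[o]; y <- y[o]
  amp0 <- max(abs(y))
  yn <- y / amp0
  # half-max crossing by linear interpolation for the V50 start value
  target <- 0.5
  cross <- which((yn[-length(yn)] - target) * (yn[-1L] - target) <= 0)
  v50_0 <- if (length(cross)) {
    j <- cross[1L]
    V[j] + (target - yn[j]) * (V[j + 1L] - V[j]) / (yn[j + 1L] - yn[j])
  } else stats::median(V)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ amplitude / (1 + exp((V50 - V) / k)),
      start = list(amplitude = amp0, V50 = v50_0, k = direction * 5),
      lower = c(amplitude = 0, V50 = -Inf,
                k = if (direction > 0) 1e-3 else -Inf),
      upper = c(amplitude = Inf, V50 = Inf,
                k = if (direction > 0) Inf else -1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) stop("Boltzmann ", what, " fit failed: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  structure(list(V50 = unname(cf["V50"]), k = unname(cf["k"]),
                 amplitude = unname(cf["amplitude"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 direction = if (direction > 0) "activation" else "availability",
                 n = length(V)),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann %s fit: V50 = %.2f mV, k = %.2f mV, amplitude = %.4g (n = %d, ||r|| = %.3g)\n",
              x$direction, x$V50, x$k, x$amplitude, x$n, x$residual_norm))
  invisible(x)
}

#' Predict from a Boltzmann fit
#'
#' @param object A `boltzmann_fit`.
#' @param V Voltages (mV) at which to evaluate the fitted curve.
#' @param normalized If `TRUE` (default) the curve is scaled to its fitted
#'   amplitude, so it evaluates to 0.5 at `V = V50`.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.boltzmann_fit <- function(object, V, normalized = TRUE, ...) {
  amp <- if (normalized) 1 else object$amplitude
  .boltzmann(V, amp, object$V50, object$k)
}

#' Boltzmann fit of the conductance-voltage (activation) curve
#'
#' Nonlinear least squares of `G/Gmax = 1/(1 + exp((V50 - V)/k))` with
#' `k > 0` (ascending). The normalised fitted curve evaluates to exactly 0.5
#' at `V = V50`.
#'
#' @param V Step potentials (mV), at least 5 spanning the rise.
#' @param G Conductance values (nS or normalised).
#' @return A `boltzmann_fit` with fields `V50`, `k`, `amplitude`
#'   (`G_max`), `residual_norm`.
#' @export
fit_activation <- function(V, G) .fit_boltzmann(V, G, +1, "activation")

#' Boltzmann fit of the steady-state inactivation (availability) curve
#'
#' Same parameterisation as [fit_activation()] but descending: availability
#' falls with depolarisation, which this package encodes as `k < 0` (the
#' magnitude `|k|` is the slope factor reported by either sign convention).
#'
#' @param V Prepulse potentials (mV), at least 5 spanning the fall.
#' @param avail Normalised available current `I/Imax`.
#' @return A `boltzmann_fit`.
#' @export
fit_inactivation <- function(V, avail) .fit_boltzmann(V, avail, -1, "availability")

#' Biexponential fit of transient-current decay
#'
#' Fits `I(t) = A_f exp(-(t-t0)/tau_fast) + A_s exp(-(t-t0)/tau_slow) + C`
#' to the current trace starting 1.0 ms into the depolarising step (the
#' rising phase is excluded) and ending at the step end. Components are
#' ordered so `tau_fast <= tau_slow` after fitting; if the slow component is
#' not identifiable (a genuinely mono-exponential decay) its amplitude is
#' returned as 0.
#'
#' @param t Sample times (ms) on the sweep time axis.
#' @param I Current samples (pA).
#' @param step_start Time of the depolarising step onset (ms).
#' @param step_end Time of the step end (ms).
#' @param exclude Initial exclusion after step onset (ms), default 1.0.
#' @return List of class `decay_fit`: `tau_fast`, `tau_slow` (ms),
#'   `A_fast`, `A_slow`, `offset` (pA), `residual_norm`.
#' @export
fit_decay <- function(t, I, step_start, step_end, exclude = 1) {
  idx <- which(t >= step_start + exclude - 1e-9 & t <= step_end + 1e-9)
  if (length(idx) < 5L)
    stop("decay window too short: fewer than 5 samples", call. = FALSE)
  tt <- t[idx] - (step_start + exclude)
  y <- I[idx]
  off0 <- mean(y[tt >= max(tt) * 0.9])
  a0 <- y[1L] - off0
  # crude single-exponential time constant from the 1/e point
  dec <- abs(y - off0)
  k_e <- which(dec <= abs(a0) / exp(1))[1L]
  tau0 <- if (!is.na(k_e) && k_e > 1L) max(tt[k_e], 1e-3) else max(tt) / 3
  fit2 <- tryCatch(
    minpack.lm::nlsLM(
      y ~ Af * exp(-tt / tf) + As * exp(-tt / ts) + C,
      start = list(Af = 0.8 * a0, As = 0.2 * a0, tf = tau0 * 0.5,
                   ts = tau0 * 4, C = off0),
      lower = c(Af = -Inf, As = -Inf, tf = 1e-4, ts = 1e-4, C = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit2)) {
    fit1 <- minpack.lm::nlsLM(
      y ~ A * exp(-tt / tau) + C,
      start = list(A = a0, tau = tau0, C = off0),
      lower = c(A = -Inf, tau = 1e-4, C = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 1000))
    cf <- stats::coef(fit1)
    return(structure(list(tau_fast = unname(cf["tau"]),
                          tau_slow = unname(cf["tau"]),
                          A_fast = unname(cf["A"]), A_slow = 0,
                          offset = unname(cf["C"]),
                          residual_norm = sqrt(sum(stats::resid(fit1)^2))),
                     class = "decay_fit"))
  }
  cf <- stats::coef(fit2)
  comp <- if (cf["tf"] <= cf["ts"]) c("tf", "ts", "Af", "As") else c("ts", "tf", "As", "Af")
  structure(list(tau_fast = unname(cf[comp[1L]]),
                 tau_slow = unname(cf[comp[2L]]),
                 A_fast = unname(cf[comp[3L]]),
                 A_slow = unname(cf[comp[4L]]),
                 offset = unname(cf["C"]),
                 residual_norm = sqrt(sum(stats::resid(fit2)^2))),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("biexponential decay: tau_fast = %.3f ms, tau_slow = %.3f ms (A = %.3g / %.3g, offset %.3g)\n",
              x$tau_fast, x$tau_slow, x$A_fast, x$A_slow, x$offset))
  invisible(x)
}

#' Single-exponential fit of recovery from fast inactivation
#'
#' Fits `frac(t) = offset + amplitude * (1 - exp(-t/tau))` to the recovered
#' fraction against the repolarising gap duration.
#'
#' @param gap Gap durations (ms), at least 4.
#' @param frac Recovered fraction (test-pulse peak / conditioning peak).
#' @return List of class `recovery_fit`: `tau` (ms), `amplitude`, `offset`,
#'   `residual_norm`.
#' @export
fit_recovery <- function(gap, frac) {
  stopifnot(length(gap) == length(frac))
  if (length(gap) < 4L)
    stop("need at least 4 gap durations to fit recovery", call. = FALSE)
  half <- min(frac) + 0.5 * (max(frac) - min(frac))
  tau0 <- stats::approx(frac, gap, xout = half, ties = "ordered")$y
  if (!is.finite(tau0)) tau0 <- stats::median(gap)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      frac ~ y0 + A * (1 - exp(-gap / tau)),
      start = list(y0 = min(frac), A = max(frac) - min(frac),
                   tau = max(tau0, 1e-3)),
      lower = c(y0 = -Inf, A = 0, tau = 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("recovery fit failed: ", conditionMessage(e),
                             call. = FALSE))
  cf <- stats::coef(fit)
  structure(list(tau = unname(cf["tau"]), amplitude = unname(cf["A"]),
                 offset = unname(cf["y0"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2))),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf("recovery fit: tau = %.3f ms (amplitude %.3f, offset %.3f)\n",
              x$tau, x$amplitude, x$offset))
  invisible(x)
}

#' Current density
#'
#' Normalises peak currents to the cell capacitance, giving pA/pF.
#'
#' @param peaks Data frame from [measure_peak()] (or any frame with
#'   `command` and `peak`), or a numeric vector of currents (pA).
#' @param capacitance Cell capacitance (pF, > 0).
#' @return Data frame with `V` (mV), `density` (pA/pF) and the capacitance
#'   as an attribute, or a numeric vector if `peaks` was one.
#' @export
current_density <- function(peaks, capacitance) {
  if (is.null(capacitance) || !is.numeric(capacitance) || capacitance <= 0)
    stop("'capacitance' must be a positive number in pF", call. = FALSE)
  if (is.numeric(peaks)) return(peaks / capacitance)
  stopifnot(is.data.frame(peaks), all(c("command", "peak") %in% names(peaks)))
  out <- data.frame(V = peaks$command, density = peaks$peak / capacitance)
  attr(out, "capacitance") <- capacitance
  out
}

#' Percent change in current magnitude between two conditions
#'
#' `100 * (|reference| - |test|) / |reference|`: positive for a reduction in
#' magnitude, negative for an increase. Report rounding follows the
#' convention of rounding half away from zero to integer percent.
#'
#' @param reference Reference measurement (signed, e.g. pA or pA/pF).
#' @param test Test measurement.
#' @param rounded If `TRUE`, round half away from zero to integer percent.
#' @return Percent change (numeric).
#' @examples
#' percent_change(-166.4, -115.4, rounded = TRUE)  # 31
#' @export
percent_change <- function(reference, test, rounded = FALSE) {
  if (any(reference == 0))
    stop("reference magnitude must be non-zero", call. = FALSE)
  pc <- 100 * (abs(reference) - abs(test)) / abs(reference)
  if (rounded) sign(pc) * floor(abs(pc) + 0.5) else pc
}

#' Shift between two Boltzmann midpoints
#'
#' `V50_a - V50_b` in mV; positive means condition `a` is depolarised
#' (right-shifted) relative to `b`.
#'
#' @param fit_a,fit_b `boltzmann_fit` objects or bare V50 values (mV).
#' @return Midpoint shift (mV).
#' @export
midpoint_shift <- function(fit_a, fit_b) {
  v <- function(f) if (inherits(f, "boltzmann_fit")) f$V50 else as.numeric(f)
  v(fit_a) - v(fit_b)
}

# ---------------------------------------------------------------------------
# Protocol-level analysis wrappers
# ---------------------------------------------------------------------------

#' Analyse an I-V sweep family
#'
#' Measures peak transient and persistent currents, estimates the reversal
#' potential from the ascending limb (unless supplied), applies the
#' conductance transform and fits the activation Boltzmann. Current density
#' is included when the sweep set carries a capacitance.
#'
#' @param ss A `sweep_set` from an [iv_protocol()] run.
#' @param V_rev Optional reversal potential (mV); estimated from the data if
#'   `NULL`.
#' @param exclude_near_rev Half-width (mV) of the window around the reversal
#'   potential excluded from the conductance transform; with a vanishing
#'   driving force the division amplifies noise without adding information.
#'   Default 10 mV.
#' @return List: `peaks`, `persistent`, `V_rev`, `conductance` (data frame),
#'   `activation` (`boltzmann_fit`), `density` (or NULL).
#' @export
analyze_iv <- function(ss, V_rev = NULL, exclude_near_rev = 10,
                       peak_avg_ms = 0.2) {
  pk <- measure_peak(ss, avg_ms = peak_avg_ms)
  ps <- measure_persistent(ss)
  if (is.null(V_rev)) V_rev <- estimate_reversal(pk$command, pk$peak)
  keep <- abs(pk$command - V_rev) >= exclude_near_rev
  G <- conductance(pk$peak[keep], pk$command[keep], V_rev)
  gdf <- data.frame(V = pk$command[keep], G = G)
  act <- fit_activation(gdf$V, gdf$G)
  dens <- if (!is.null(ss$capacitance)) current_density(pk, ss$capacitance)
  list(peaks = pk, persistent = ps, V_rev = V_rev, conductance = gdf,
       activation = act, density = dens)
}

#' Analyse a steady-state inactivation sweep family
#'
#' Test-pulse peaks are normalised to the maximum peak magnitude across
#' prepulses and fitted with the descending Boltzmann.
#'
#' @param ss A `sweep_set` from an [ssi_protocol()] run.
#' @return List: `peaks`, `availability` (data frame V/avail),
#'   `inactivation` (`boltzmann_fit`).
#' @export
analyze_ssi <- function(ss, peak_avg_ms = 0.2) {
  pk <- measure_peak(ss, avg_ms = peak_avg_ms)
  avail <- abs(pk$peak) / max(abs(pk$peak))
  fit <- fit_inactivation(pk$command, avail)
  list(peaks = pk, availability = data.frame(V = pk$command, avail = avail),
       inactivation = fit)
}

#' Analyse a recovery-from-inactivation sweep family
#'
#' The recovered fraction is the test-pulse peak normalised to the same
#' sweep's conditioning-pulse peak, fitted with a single exponential.
#'
#' @param ss A `sweep_set` from a [recovery_protocol()] run.
#' @return List: `fractions` (data frame gap/frac), `recovery`
#'   (`recovery_fit`).
#' @export
analyze_recovery <- function(ss, peak_avg_ms = 0.2) {
  test <- measure_peak(ss, avg_ms = peak_avg_ms)
  cond <- measure_peak(ss, segment = ss$protocol$conditioning_segment,
                       avg_ms = peak_avg_ms)
  frac <- abs(test$peak) / abs(cond$peak)
  fit <- fit_recovery(test$command, frac)
  list(fractions = data.frame(gap = test$command, frac = frac),
       recovery = fit)
}
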