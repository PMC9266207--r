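# Single-compartment pacemaking-neuron model.
#
# C dV/dt = -(I_Na + I_K + I_leak [+ I_h]) + I_stim, with the sodium term a
# mixture of Markov-channel components, each at fraction * density_scale of
# the total Na conductance. Heterozygous expression of a mutant allele is
# the composition list(WT = 0.5, MUT = 0.5). The non-sodium complement is a
# minimal pacemaker set: a fast Kv3-like delayed rectifier (n^4), an ohmic
# leak, and an optional h-current; densities were calibrated once so the
# 100% wild-type neuron is a stable spontaneous pacemaker in the tens of Hz
# (Purkinje-like) and are never varied between conditions.

#' Configure a single-compartment neuron
#'
#' @param composition Named list or vector of allele fractions, e.g.
#'   `c(WT = 1)` or `c(WT = 0.5, R639C = 0.5)` (names are condition names
#'   understood by [nav_preset()]); or a list of
#'   `list(rates = nav_rates, fraction = x)` entries for custom conditions.
#'   Fractions must be non-negative and sum to 1. Each component contributes
#'   `fraction * density_scale * gna` of open-channel conductance.
#' @param gna Total Na conductance density before per-condition scaling
#'   (mS/cm^2).
#' @param gk Delayed-rectifier K conductance density (mS/cm^2).
#' @param gl Leak conductance density (mS/cm^2).
#' @param gh h-current conductance density (mS/cm^2); 0 disables it.
#' @param E_Na,E_K,E_leak,E_h Reversal potentials (mV).
#' @param cm Specific membrane capacitance (uF/cm^2).
#' @param v0 Initial membrane potential (mV).
#' @param area Compartment area (cm^2), used only to convert injected
#'   current from nA to uA/cm^2.
#' @param kgate Kv3-like gate parameters: `vhalf`, `slope` (mV) of the
#'   steady-state activation, and `tau_min`, `tau_amp` (ms), `tau_vmid`,
#'   `tau_width` (mV) of the bell-shaped time constant.
#' @return List of class `neuron_config`.
#' @export
neuron_config <- function(composition = c(WT = 1),
                          gna = 16, gk = 35, gl = 0.3, gh = 0,
                          E_Na = 68, E_K = -88, E_leak = -61, E_h = -30,
                          cm = 1, v0 = -65, area = 1e-4,
                          kgate = c(vhalf = -24, slope = 15.4,
                                    tau_min = 0.15, tau_amp = 2.5,
                                    tau_vmid = -50, tau_width = 35)) {
  comp <- .normalize_composition(composition)
  fr <- vapply(comp, function(x) x$fraction, 1)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8)
    stop("composition fractions must be non-negative and sum to 1",
         call. = FALSE)
  stopifnot(gna >= 0, gk >= 0, gl >= 0, gh >= 0, cm > 0, area > 0)
  structure(list(composition = comp, gna = gna, gk = gk, gl = gl, gh = gh,
                 E_Na = E_Na, E_K = E_K, E_leak = E_leak, E_h = E_h,
                 cm = cm, v0 = v0, area = area, kgate = kgate),
            class = "neuron_config")
}

.normalize_composition <- function(composition) {
  if (is.numeric(composition) && !is.null(names(composition))) {
    return(lapply(seq_along(composition), function(i)
      list(name = names(composition)[i],
           rates = nav_preset(names(composition)[i]),
           fraction = unname(composition[i]))))
  }
  if (is.list(composition)) {
    return(lapply(composition, function(x) {
      stopifnot(inherits(x$rates, "nav_rates"), is.numeric(x$fraction))
      list(name = x$name %||% "custom", rates = x$rates,
           fraction = x$fraction)
    }))
  }
  stop("invalid composition", call. = FALSE)
}

#' @export
print.neuron_config <- function(x, ...) {
  comp <- paste(vapply(x$composition, function(c)
    sprintf("%s:%.2f", c$name, c$fraction), ""), collapse = ", ")
  cat(sprintf("<neuron_config> Na %g mS/cm2 [%s], K %g, leak %g (E_leak %g mV)\n",
              x$gna, comp, x$gk, x$gl, x$E_leak))
  invisible(x)
}

# Run the compiled membrane integrator. Occupancies start at the fixed-V
# steady state of v0.
.sim_membrane <- function(config, t_total, dt, stim_amp = 0, stim_start = 0,
                          stim_end = 0, record_dt = 0.1,
                          spike_threshold = -20, spike_lockout = 1) {
  comp <- config$composition
  rate_mat <- do.call(rbind, lapply(comp, function(x) .rates_vec(x$rates)))
  fractions <- vapply(comp, function(x) x$fraction, 1)
  p0 <- do.call(rbind, lapply(comp, function(x)
    unname(steady_state(config$v0, x$rates))))
  kg <- config$kgate
  n0 <- 1 / (1 + exp(-(config$v0 - kg["vhalf"]) / kg["slope"]))
  q0 <- 1 / (1 + exp((config$v0 + 90) / 7))
  res <- .cpp_sim_membrane(rate_mat, fractions, p0,
                           config$gna, config$gk, config$gl, config$gh,
                           config$E_Na, config$E_K, config$E_leak, config$E_h,
                           config$cm, config$v0, unname(n0), unname(q0),
                           dt, t_total, stim_amp, stim_start, stim_end,
                           record_dt, spike_threshold, spike_lockout,
                           unname(kg))
  res
}

#' Detect action potentials in a voltage trace
#'
#' Upward crossings of `threshold` with a refractory lockout.
#'
#' @param v Membrane potential samples (mV), uniformly sampled.
#' @param t Sample times (ms), same length as `v`.
#' @param threshold Detection threshold (mV), default -20.
#' @param lockout Minimum inter-spike interval (ms), default 1.
#' @return Numeric vector of spike times (ms), strictly increasing.
#' @export
detect_spikes <- function(v, t, threshold = -20, lockout = 1) {
  stopifnot(length(v) == length(t), length(v) >= 2L)
  up <- which(v[-1L] >= threshold & v[-length(v)] < threshold) + 1L
  if (!length(up)) return(numeric(0))
  times <- t[up]
  keep <- times[1L]
  for (tt in times[-1L]) if (tt - keep[length(keep)] > lockout) keep <- c(keep, tt)
  keep
}

#' Simulate spontaneous firing
#'
#' Integrates the neuron with zero injected current, discards the settle
#' period, and counts spikes in the analysis window.
#'
#' @param config A [neuron_config()].
#' @param settle Settling time discarded from analysis (ms), default 1000.
#' @param window Analysis window after settle (ms), default 2000.
#' @param dt Integration step (ms), default 0.0025.
#' @param record_dt Voltage recording interval (ms), default 0.1.
#' @return List of class `firing_result`: `spike_times` (ms, within the
#'   window), `frequency` (Hz), `window` (ms), `trace` (data frame time/v).
#' @export
simulate_spontaneous <- function(config, settle = 1000, window = 2000,
                                 dt = 0.0025, record_dt = 0.1) {
  stopifnot(inherits(config, "neuron_config"), window >= 1000)
  res <- .sim_membrane(config, settle + window, dt)
  sp <- res$spikes[res$spikes > settle & res$spikes <= settle + window]
  structure(list(spike_times = sp, frequency = 1000 * length(sp) / window,
                 window = window, settle = settle,
                 trace = data.frame(time = res$time, v = res$v)),
            class = "firing_result")
}

#' @export
print.firing_result <- function(x, ...) {
  cat(sprintf("<firing_result> %d spikes in %g ms -> %.2f Hz\n",
              length(x$spike_times), x$window, x$frequency))
  invisible(x)
}

#' Simulate evoked firing over a stimulus series
#'
#' One integration per stimulus amplitude: a settle period with no injected
#' current followed by a current step; spikes are counted during the step.
#'
#' @param config A [neuron_config()].
#' @param amplitudes Injected current amplitudes (nA).
#' @param baseline Pre-stimulus settling time (ms), default 1000.
#' @param step_dur Stimulus duration (ms), default 1000.
#' @param dt Integration step (ms), default 0.0025.
#' @return List of class `fi_result`: data frame `fi` with `amplitude_nA`
#'   and `frequency_Hz`, plus `results` (per-amplitude `firing_result`s).
#' @export
simulate_evoked <- function(config, amplitudes = seq(0, 1, by = 0.2),
                            baseline = 1000, step_dur = 1000, dt = 0.0025) {
  stopifnot(inherits(config, "neuron_config"), all(is.finite(amplitudes)),
            baseline > 0, step_dur > 0)
  results <- lapply(amplitudes, function(a) {
    res <- .sim_membrane(config, baseline + step_dur, dt,
                         stim_amp = a * 1e-3 / config$area,
                         stim_start = baseline,
                         stim_end = baseline + step_dur)
    sp <- res$spikes[res$spikes > baseline & res$spikes <= baseline + step_dur]
    structure(list(spike_times = sp,
                   frequency = 1000 * length(sp) / step_dur,
                   window = step_dur, settle = baseline,
                   trace = data.frame(time = res$time, v = res$v)),
              class = "firing_result")
  })
  fi <- data.frame(amplitude_nA = amplitudes,
                   frequency_Hz = vapply(results, function(r) r$frequency, 1))
  structure(list(fi = fi, results = results), class = "fi_result")
}

#' @export
print.fi_result <- function(x, ...) {
  print(x$fi)
  invisible(x)
}

#' Heterozygous composition helper
#'
#' Builds the Na composition for a genotype: 100% WT, or 50/50 WT/mutant
#' for heterozygous expression; with `camkii_inhibited = TRUE` both halves
#' switch to their CaMKII-inhibited (+CN21) parameter sets.
#'
#' @param genotype `"WT"`, `"R639C"` or `"R850Q"`.
#' @param camkii_inhibited Apply the +CN21 parameter sets to all components.
#' @return Named fraction vector suitable for [neuron_config()].
#' @examples
#' het_composition("R639C")                  # c(WT = 0.5, R639C = 0.5)
#' het_composition("R850Q", TRUE)  # c(`WT+CN21` = 0.5, `R850Q+CN21` = 0.5)
#' @export
het_composition <- function(genotype = c("WT", "R639C", "R850Q"),
                            camkii_inhibited = FALSE) {
  genotype <- match.arg(genotype)
  suffix <- if (camkii_inhibited) "+CN21" else ""
  if (genotype == "WT")
    return(stats::setNames(1, paste0("WT", suffix)))
  stats::setNames(c(0.5, 0.5),
                  c(paste0("WT", suffix), paste0(genotype, suffix)))
}
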