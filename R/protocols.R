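# Voltage-clamp protocol descriptors and the protocol runner.

#' Construct a voltage protocol
#'
#' A protocol is a family of sweeps, each a sequence of constant-voltage
#' segments, together with the sweep-varying command value (step level or
#' recovery gap duration), the sample interval, and which segment is the
#' measurement window. Sweeps start from the steady state of the holding
#' potential.
#'
#' @param holding Holding potential (mV).
#' @param sweeps List of data frames, one per sweep, with columns `level`
#'   (mV) and `duration` (ms).
#' @param command Numeric vector, one value per sweep (the swept parameter).
#' @param vary What `command` means: the depolarising step level (`"step"`)
#'   or the recovery gap duration (`"gap"`).
#' @param dt Sample interval (ms), default 0.025.
#' @param measure_segment Index of the segment whose current is measured.
#' @param conditioning_segment Optional index of a conditioning pulse
#'   (recovery protocols) used for normalisation.
#' @param name Protocol label carried into outputs.
#' @return An object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(holding, sweeps, command,
                             vary = c("step", "gap"), dt = 0.025,
                             measure_segment = length(sweeps[[1]]$level),
                             conditioning_segment = NULL,
                             name = "custom") {
  vary <- match.arg(vary)
  stopifnot(length(sweeps) >= 1L, length(command) == length(sweeps), dt > 0)
  for (sw in sweeps) {
    stopifnot(is.data.frame(sw), all(c("level", "duration") %in% names(sw)),
              all(sw$duration > 0))
  }
  structure(list(holding = holding, sweeps = sweeps, command = command,
                 vary = vary, dt = dt, measure_segment = measure_segment,
                 conditioning_segment = conditioning_segment, name = name),
            class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("<voltage_protocol '%s'> holding %g mV, %d sweeps, dt %g ms\n",
              x$name, x$holding, length(x$sweeps), x$dt))
  invisible(x)
}

#' Current-voltage (I-V) step protocol
#'
#' Depolarising steps from -80 to +60 mV (5 mV increments) for 50 ms from
#' the holding potential, preceded by a short settled baseline at holding.
#' Holding -100 mV is used for biophysical characterisation and -80 mV for
#' the CaMKII-inhibition comparisons.
#'
#' @param holding Holding potential (mV), typically -100 or -80.
#' @param steps Step levels (mV); default `seq(-80, 60, by = 5)`.
#' @param step_dur Step duration (ms); default 50.
#' @param baseline Pre-step baseline at holding (ms); default 2.
#' @param dt Sample interval (ms).
#' @return A [voltage_protocol()].
#' @export
iv_protocol <- function(holding = -100, steps = seq(-80, 60, by = 5),
                        step_dur = 50, baseline = 2, dt = 0.025) {
  sweeps <- lapply(steps, function(s)
    data.frame(level = c(holding, s), duration = c(baseline, step_dur)))
  voltage_protocol(holding, sweeps, command = steps, vary = "step", dt = dt,
                   measure_segment = 2L, name = "iv")
}

#' Steady-state inactivation (availability) protocol
#'
#' 500 ms conditioning prepulses from -130 to +40 mV (10 mV increments)
#' followed by a 20 ms test pulse at 0 mV; availability is the normalised
#' test-pulse peak current.
#'
#' @param holding Holding potential (mV) before the prepulse.
#' @param prepulses Prepulse levels (mV); default `seq(-130, 40, by = 10)`.
#' @param prepulse_dur Prepulse duration (ms); default 500.
#' @param test_level,test_dur Test pulse (mV, ms); default 0 mV for 20 ms.
#' @param dt Sample interval (ms).
#' @return A [voltage_protocol()].
#' @export
ssi_protocol <- function(holding = -100, prepulses = seq(-130, 40, by = 10),
                         prepulse_dur = 500, test_level = 0, test_dur = 20,
                         dt = 0.025) {
  sweeps <- lapply(prepulses, function(pp)
    data.frame(level = c(pp, test_level), duration = c(prepulse_dur, test_dur)))
  voltage_protocol(holding, sweeps, command = prepulses, vary = "step",
                   dt = dt, measure_segment = 2L, name = "ssi")
}

#' Recovery-from-fast-inactivation paired-pulse protocol
#'
#' A conditioning pulse to 0 mV, a repolarising gap at -80 mV of increasing
#' duration, and a final 20 ms test pulse to 0 mV. The recovered fraction is
#' the test-pulse peak normalised to the conditioning-pulse peak.
#'
#' @param holding Holding potential (mV).
#' @param gaps Gap durations (ms); default 12 log-spaced points from 0.5 to
#'   100 ms.
#' @param gap_level Gap potential (mV); default -80.
#' @param cond_dur Conditioning pulse duration (ms); default 20.
#' @param test_dur Test pulse duration (ms); default 20.
#' @param pulse_level Conditioning/test level (mV); default 0.
#' @param dt Sample interval (ms).
#' @return A [voltage_protocol()].
#' @export
recovery_protocol <- function(holding = -100,
                              gaps = exp(seq(log(0.5), log(100), length.out = 12)),
                              gap_level = -80, cond_dur = 20, test_dur = 20,
                              pulse_level = 0, dt = 0.025) {
  sweeps <- lapply(gaps, function(g)
    data.frame(level = c(pulse_level, gap_level, pulse_level),
               duration = c(cond_dur, g, test_dur)))
  voltage_protocol(holding, sweeps, command = gaps, vary = "gap", dt = dt,
                   measure_segment = 3L, conditioning_segment = 1L,
                   name = "recovery")
}

#' Run a voltage protocol against the Markov channel
#'
#' Initialises each sweep at the steady state of the holding potential,
#' propagates the occupancies through the sweep's segments, and converts the
#' open probability to macroscopic current. Simulated sweeps are
#' artifact-free: no leak, capacitive transient or series-resistance error
#' (see [generate_cell()] for recordings with artifacts).
#'
#' @param protocol A [voltage_protocol()].
#' @param rates A [nav_rates()] object (the condition's `density_scale` is
#'   applied to the current).
#' @param mp [macroscopic_params()] (gbar in nS, E_Na in mV).
#' @param condition Optional condition label carried into metadata.
#' @return A `sweep_set`: list with `time` (list of per-sweep sample times,
#'   ms), `current` (list of per-sweep currents, pA), `popen` (list of open
#'   probabilities), `command`, `protocol`, `dt`, `condition`, `capacitance`
#'   (NULL here), `seed` (NULL here).
#' @export
run_protocol <- function(protocol, rates, mp = macroscopic_params(),
                         condition = NULL) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  p_hold <- steady_state(protocol$holding, rates)
  cur <- vector("list", length(protocol$sweeps))
  tms <- vector("list", length(protocol$sweeps))
  po <- vector("list", length(protocol$sweeps))
  segb <- vector("list", length(protocol$sweeps))
  for (i in seq_along(protocol$sweeps)) {
    seg <- protocol$sweeps[[i]]
    occ <- .propagate_segments(p_hold, seg, rates, protocol$dt)
    popen <- occ$p[, 6L]
    cur[[i]] <- channel_current(pmin(pmax(popen, 0), 1), occ$v, mp,
                                rates$density_scale)
    tms[[i]] <- occ$time
    po[[i]] <- popen
    segb[[i]] <- cumsum(seg$duration)
  }
  structure(list(time = tms, current = cur, popen = po,
                 command = protocol$command, protocol = protocol,
                 dt = protocol$dt, condition = condition,
                 segment_ends = segb, capacitance = NULL, seed = NULL),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps (%s), dt %g ms%s\n",
              length(x$current), x$protocol$name, x$dt,
              if (!is.null(x$condition)) paste0(", condition ", x$condition) else ""))
  invisible(x)
}

# Sample window [t0, t1] of sweep i, referred to the sweep's own time axis.
.sweep_window <- function(ss, i, t0, t1) {
  tm <- ss$time[[i]]
  which(tm >= t0 - 1e-9 & tm <= t1 + 1e-9)
}

.measure_window <- function(ss, i, segment) {
  ends <- ss$segment_ends[[i]]
  if (segment > length(ends))
    stop("protocol mismatch: sweep has no segment ", segment, call. = FALSE)
  c(start = if (segment == 1L) 0 else ends[segment - 1L], end = ends[segment])
}

#' Peak transient current of each sweep
#'
#' Signed extremum of the current within the measurement segment (inward
#' currents are negative and yield negative peaks). The first `blank` ms
#' after the segment edge are excluded to avoid the instantaneous ohmic
#' step.
#'
#' @param ss A `sweep_set` from [run_protocol()] or [generate_cell()].
#' @param segment Segment index to measure; defaults to the protocol's
#'   measurement segment.
#' @param blank Dead time after the segment edge (ms), default 0.05.
#' @param avg_ms Width (ms) of an averaging window centred on the detected
#'   extremum; 0 (default) reports the raw extremum sample. Averaging
#'   suppresses the upward bias that picking the extremum of a noisy trace
#'   introduces, and is used by the analysis wrappers.
#' @return Data frame with `sweep`, `command`, `peak` (pA) and `t_peak` (ms,
#'   on the sweep time axis).
#' @export
measure_peak <- function(ss, segment = NULL, blank = 0.05, avg_ms = 0) {
  stopifnot(inherits(ss, "sweep_set"))
  segment <- segment %||% ss$protocol$measure_segment
  out <- lapply(seq_along(ss$current), function(i) {
    w <- .measure_window(ss, i, segment)
    idx <- .sweep_window(ss, i, w["start"] + blank, w["end"])
    if (!length(idx))
      stop("protocol mismatch: empty measurement window", call. = FALSE)
    cur <- ss$current[[i]][idx]
    k <- which.max(abs(cur))
    val <- if (avg_ms > 0) {
      half <- max(1L, round(avg_ms / 2 / ss$dt))
      mean(cur[max(1L, k - half):min(length(cur), k + half)])
    } else cur[k]
    data.frame(sweep = i, command = ss$command[i], peak = val,
               t_peak = ss$time[[i]][idx[k]])
  })
  do.call(rbind, out)
}

#' Persistent (non-inactivating) current of each sweep
#'
#' Mean signed current over the last 5.0 ms of the depolarising step.
#'
#' @inheritParams measure_peak
#' @param window Averaging window length (ms), default 5.
#' @return Data frame with `sweep`, `command` and `persistent` (pA).
#' @export
measure_persistent <- function(ss, segment = NULL, window = 5) {
  stopifnot(inherits(ss, "sweep_set"))
  segment <- segment %||% ss$protocol$measure_segment
  out <- lapply(seq_along(ss$current), function(i) {
    w <- .measure_window(ss, i, segment)
    if (w["end"] - w["start"] < window - 1e-9)
      stop("protocol mismatch: step shorter than the ", window,
           " ms persistence window", call. = FALSE)
    idx <- .sweep_window(ss, i, w["end"] - window, w["end"])
    data.frame(sweep = i, command = ss$command[i],
               persistent = mean(ss$current[[i]][idx]))
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
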