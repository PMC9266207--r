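# 13-state Markov gating scheme: generator assembly, steady state,
# piecewise-constant-voltage propagation, macroscopic current.
#
# Scheme: five closed states C1..C5 with forward rates 4a,3a,2a,a and
# backward b,2b,3b,4b; C5 <-> O via gamma/delta; O <-> OB via epsilon/zeta(V)
# (open-channel block, disabled in all shipped conditions); an inactivated
# tier I1..I6 lying under C1..C5 and O. Vertical entry Cn -> In scales as
# Con*alfac^(n-1) and exit In -> Cn as Coff*btfac^(n-1), with
# alfac = (Oon/Con)^(1/4) and btfac = (Ooff/Coff)^(1/4); the inactivated tier
# mirrors the closed tier with alpha_i*alfac / beta_i*btfac in place of
# alpha/beta (same multiplicities) and I5 <-> I6 via gamma/delta. The ratio
# alfac/btfac equals the reported allosteric factor a, and the C5-O-I6-I5
# loop is in detailed balance by construction.

#' Generator matrix of the gating scheme at a fixed voltage
#'
#' Evaluates the 13x13 transition-rate matrix Q (1/ms) at membrane potential
#' `V`, under the convention `dp/dt = p %*% Q` (rows sum to zero;
#' `Q[i, j]` is the rate from state i to state j). Voltage enters through
#' `alpha(V) = alpha0*exp(V/k_alpha)`, `beta(V) = beta0*exp(-V/k_beta)` (and
#' likewise for the inactivated-tier rates) and `zeta(V) =
#' zeta0*exp(-V/k_zeta)`; `gamma`, `delta` and the vertical inactivation
#' rates are voltage independent.
#'
#' @param V Membrane potential (mV), finite scalar.
#' @param rates A [nav_rates()] object.
#' @return 13x13 numeric matrix with state dimnames
#'   `C1..C5, O, OB, I1..I6`.
#' @examples
#' Q <- build_generator(0, nav_preset("WT"))
#' Q["C5", "O"]    # opening rate gamma = 150 /ms
#' @export
build_generator <- function(V, rates) {
  if (!is.numeric(V) || length(V) != 1L || !is.finite(V))
    stop("'V' must be a single finite voltage in mV", call. = FALSE)
  stopifnot(inherits(rates, "nav_rates"))
  Q <- .cpp_generator(V, .rates_vec(rates))
  dimnames(Q) <- list(.state_names, .state_names)
  Q
}

#' Stationary occupancy at a fixed voltage
#'
#' Solves `p %*% Q = 0`, `sum(p) = 1`, `p >= 0` for the unique stationary
#' distribution of the gating scheme at voltage `V` (used to initialise
#' holding potentials). Unreachable states (the blocked state OB when
#' `epsilon = 0`) are detected and pinned to zero occupancy before solving,
#' so the reduced system is full rank.
#'
#' @inheritParams build_generator
#' @return Numeric vector of 13 occupancies summing to 1, named by state.
#' @export
steady_state <- function(V, rates) {
  Q <- build_generator(V, rates)
  keep <- rep(TRUE, 13L)
  # states with no inbound edge can never be occupied at stationarity
  repeat {
    inbound <- colSums(Q[keep, keep, drop = FALSE] > 0) > 0
    if (all(inbound)) break
    keep[keep][!inbound] <- FALSE
  }
  Qr <- Q[keep, keep, drop = FALSE]
  n <- nrow(Qr)
  # p Q = 0  <=>  t(Q) t(p) = 0; replace with an overdetermined system
  # carrying the normalisation row.
  M <- rbind(t(Qr), rep(1, n))
  b <- c(rep(0, n), 1)
  if (qr(M)$rank < n)
    stop("generator is numerically defective: stationary distribution is ",
         "not unique (disconnected scheme?)", call. = FALSE)
  p_r <- tryCatch(qr.solve(M, b),
                  error = function(e) stop("generator is numerically defective: ",
                                           conditionMessage(e), call. = FALSE))
  if (any(p_r < -1e-9))
    stop("no non-negative stationary distribution found", call. = FALSE)
  p_r <- pmax(p_r, 0)
  p_r <- p_r / sum(p_r)
  p <- stats::setNames(numeric(13L), .state_names)
  p[keep] <- p_r
  p
}

#' Propagate occupancies through a piecewise-constant voltage schedule
#'
#' Integrates `dp/dt = p %*% Q(V)` across a sequence of constant-voltage
#' segments. Within a segment Q is constant, so the step update uses the
#' matrix exponential `P = expm(Q*dt)` — unconditionally stable and
#' probability-conserving to machine precision.
#'
#' @param p0 Initial occupancy vector (length 13, non-negative, sums to 1
#'   within 1e-6).
#' @param segments Data frame with columns `level` (mV) and `duration` (ms),
#'   one row per constant-voltage segment.
#' @param rates A [nav_rates()] object.
#' @param dt Sample interval (ms, > 0); default 0.025.
#' @return Data frame: `time` (ms, starting at 0), `v` (command voltage at
#'   each sample), and one column per state. Row 1 is `p0` at time 0.
#' @export
integrate_occupancy <- function(p0, segments, rates, dt = 0.025) {
  .check_occupancy(p0)
  stopifnot(is.data.frame(segments), all(c("level", "duration") %in% names(segments)),
            all(segments$duration > 0), dt > 0)
  occ <- .propagate_segments(p0, segments, rates, dt)
  bad <- occ$p < -1e-6 | occ$p > 1 + 1e-6
  if (any(bad))
    stop("integration instability: occupancy left [0, 1]", call. = FALSE)
  out <- data.frame(time = occ$time, v = occ$v)
  out <- cbind(out, as.data.frame(occ$p))
  names(out)[-(1:2)] <- .state_names
  out
}

.check_occupancy <- function(p0) {
  if (length(p0) != 13L || any(!is.finite(p0)) || any(p0 < -1e-8) ||
      abs(sum(p0) - 1) > 1e-6)
    stop("'p0' must be 13 non-negative occupancies summing to 1", call. = FALSE)
}

# Core propagation shared by integrate_occupancy() and run_protocol().
# Returns sample times, command voltage per sample and the occupancy matrix.
# Transition matrices are cached per (level, step) within a call.
.propagate_segments <- function(p0, segments, rates, dt) {
  rv <- .rates_vec(rates)
  cache <- new.env(parent = emptyenv())
  step_mat <- function(V, h) {
    key <- paste0(format(V, digits = 15), "_", format(h, digits = 15))
    P <- cache[[key]]
    if (is.null(P)) {
      P <- .cpp_expm_step(.cpp_generator(V, rv), h)
      cache[[key]] <- P
    }
    P
  }
  times <- list(0)
  vs <- list(segments$level[1L])
  ps <- list(matrix(p0, nrow = 1L))
  t_off <- 0
  p <- matrix(p0, nrow = 1L)
  for (i in seq_len(nrow(segments))) {
    V <- segments$level[i]
    dur <- segments$duration[i]
    n_full <- floor(dur / dt + 1e-9)
    rem <- dur - n_full * dt
    if (n_full > 0) {
      block <- .cpp_propagate(p, step_mat(V, dt), n_full)
      times[[length(times) + 1L]] <- t_off + dt * seq_len(n_full)
      vs[[length(vs) + 1L]] <- rep(V, n_full)
      ps[[length(ps) + 1L]] <- block
      p <- block[n_full, , drop = FALSE]
    }
    if (rem > 1e-9) {
      p <- p %*% step_mat(V, rem)
      times[[length(times) + 1L]] <- t_off + dur
      vs[[length(vs) + 1L]] <- V
      ps[[length(ps) + 1L]] <- p
    }
    t_off <- t_off + dur
  }
  list(time = unlist(times), v = unlist(vs), p = do.call(rbind, ps))
}

#' Macroscopic current from an open-probability time course
#'
#' `I(t) = density_scale * gbar * popen(t) * (V - E_Na)`; with `gbar` in nS
#' and voltages in mV the current is in pA. Inward current is negative for
#' `V < E_Na`.
#'
#' @param popen Open-probability values in `[0, 1]`.
#' @param V Membrane potential (mV) — scalar or vector matching `popen`.
#' @param mp List with `gbar` (nS, > 0) and `E_Na` (mV); see
#'   [macroscopic_params()].
#' @param density_scale Conductance multiplier (default 1).
#' @return Numeric current vector (pA).
#' @export
channel_current <- function(popen, V, mp = macroscopic_params(),
                            density_scale = 1) {
  if (any(popen < -1e-9 | popen > 1 + 1e-9))
    stop("'popen' must lie in [0, 1]", call. = FALSE)
  stopifnot(density_scale > 0)
  density_scale * mp$gbar * popen * (V - mp$E_Na)
}

#' Macroscopic conductance parameters
#'
#' @param gbar Maximal conductance before density scaling (nS, > 0).
#' @param E_Na Sodium reversal potential (mV). The default +68 mV is the
#'   Nernst potential for 140 mM external / 10 mM internal Na+ at 22 C.
#' @return List with class `macroscopic_params`.
#' @export
macroscopic_params <- function(gbar = 100, E_Na = 68) {
  if (!is.numeric(gbar) || gbar <= 0) stop("'gbar' must be > 0", call. = FALSE)
  structure(list(gbar = gbar, E_Na = E_Na), class = "macroscopic_params")
}
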