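# Synthetic whole-cell recordings with known ground truth.
#
# Emulates the idealised content of a voltage-clamp recording: the Markov
# channel scaled by a per-cell maximal conductance, an optional linear leak,
# and additive i.i.d. Gaussian noise. Series-resistance and capacitive
# artifacts are not modelled (experimental compensation removes most of
# them), so passing recovery tests here demonstrates correctness of the
# analysis chain, not robustness to uncompensated recording artifacts.

#' Specification of one synthetic cell
#'
#' @param condition Condition name (see [nav_preset()]) or a [nav_rates()]
#'   object.
#' @param capacitance Cell capacitance (pF, > 0). Cohorts draw it lognormal
#'   with median `cap_median`.
#' @param gbar Maximal conductance (nS, > 0) before density scaling.
#' @param noise_sd Additive Gaussian noise SD (pA, >= 0).
#' @param g_leak Linear leak conductance (nS, >= 0); 0 disables leak.
#' @param E_leak Leak reversal (mV).
#' @param E_Na Sodium reversal potential (mV).
#' @param seed Integer seed; recorded in the output metadata so every
#'   generated dataset is reproducible.
#' @return List of class `synthetic_cell_spec`.
#' @export
synthetic_cell_spec <- function(condition = "WT", capacitance = 12,
                                gbar = 90, noise_sd = 10, g_leak = 0,
                                E_leak = -80, E_Na = 68, seed = 1L) {
  rates <- if (inherits(condition, "nav_rates")) condition else nav_preset(condition)
  name <- if (inherits(condition, "nav_rates")) "custom" else condition
  stopifnot(capacitance > 0, gbar > 0, noise_sd >= 0, g_leak >= 0)
  structure(list(condition = name, rates = rates, capacitance = capacitance,
                 gbar = gbar, noise_sd = noise_sd, g_leak = g_leak,
                 E_leak = E_leak, E_Na = E_Na, seed = as.integer(seed)),
            class = "synthetic_cell_spec")
}

# Evaluate expr with a temporarily seeded RNG, restoring the caller's state.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate one synthetic whole-cell recording
#'
#' Runs the Markov channel for the cell's condition through `protocol`,
#' scales by the cell's `gbar` and the condition's density, adds a linear
#' leak `I_leak = g_leak * (V - E_leak)` if requested, and adds i.i.d.
#' Gaussian noise. Output is a pure function of (spec, protocol): the same
#' seed gives bit-identical sweeps.
#'
#' @param spec A [synthetic_cell_spec()].
#' @param protocol A [voltage_protocol()].
#' @param base Optional noiseless unit-conductance `sweep_set` for the same
#'   (rates, protocol), as produced by `run_protocol(protocol, rates,
#'   macroscopic_params(gbar = 1, E_Na = spec$E_Na))`; supplying it lets
#'   cohorts reuse one channel simulation across cells.
#' @return List with `sweeps` (a `sweep_set` carrying capacitance and seed)
#'   and `truth` (the generating parameters: condition, rates, gbar,
#'   capacitance, noise_sd, leak, seed).
#' @export
generate_cell <- function(spec, protocol, base = NULL) {
  stopifnot(inherits(spec, "synthetic_cell_spec"),
            inherits(protocol, "voltage_protocol"))
  if (is.null(base))
    base <- run_protocol(protocol, spec$rates,
                         macroscopic_params(gbar = 1, E_Na = spec$E_Na),
                         condition = spec$condition)
  ss <- base
  ss$current <- .with_seed(spec$seed, {
    lapply(seq_along(base$current), function(i) {
      cur <- base$current[[i]] * spec$gbar
      if (spec$g_leak > 0) {
        v <- .sweep_voltage(protocol, i)
        cur <- cur + spec$g_leak * (v - spec$E_leak)
      }
      if (spec$noise_sd > 0)
        cur <- cur + stats::rnorm(length(cur), 0, spec$noise_sd)
      cur
    })
  })
  ss$capacitance <- spec$capacitance
  ss$seed <- spec$seed
  ss$condition <- spec$condition
  truth <- list(condition = spec$condition,
                rates = spec$rates[.rate_fields],
                gbar = spec$gbar, capacitance = spec$capacitance,
                noise_sd = spec$noise_sd, g_leak = spec$g_leak,
                E_leak = spec$E_leak, E_Na = spec$E_Na, seed = spec$seed)
  list(sweeps = ss, truth = truth)
}

# Command voltage at every sample of sweep i (matches .propagate_segments
# sample layout: t = 0 carries the first segment's level).
.sweep_voltage <- function(protocol, i) {
  seg <- protocol$sweeps[[i]]
  dt <- protocol$dt
  v <- seg$level[1L]
  for (j in seq_len(nrow(seg))) {
    dur <- seg$duration[j]
    n_full <- floor(dur / dt + 1e-9)
    rem <- dur - n_full * dt
    v <- c(v, rep(seg$level[j], n_full + (rem > 1e-9)))
  }
  v
}

#' Generate a cohort of synthetic cells
#'
#' Draws per-cell capacitance and maximal conductance from lognormal
#' distributions, generates each cell with a seed derived from the cohort
#' seed, writes one sweep CSV (+ JSON sidecar) per cell and protocol, a
#' ground-truth JSON per cell, and a cohort `manifest.json`. Two cohorts
#' generated with the same arguments are file-identical.
#'
#' @param n_cells Number of cells (>= 1).
#' @param condition Condition name or [nav_rates()].
#' @param protocols Named list of [voltage_protocol()] objects.
#' @param out_dir Output directory; must not already contain files unless
#'   `overwrite = TRUE`.
#' @param seed Cohort seed (integer); per-cell seeds are derived from it.
#' @param cap_median,cap_sdlog Lognormal capacitance parameters (pF).
#' @param gbar_median,gbar_sdlog Lognormal maximal-conductance parameters
#'   (nS).
#' @param noise_sd,g_leak,E_leak,E_Na Passed to [synthetic_cell_spec()].
#' @param overwrite Allow writing into a non-empty directory.
#' @return The manifest, invisibly (list with per-cell entries and files).
#' @export
generate_cohort <- function(n_cells, condition, protocols, out_dir,
                            seed = 1L, cap_median = 12, cap_sdlog = 0.25,
                            gbar_median = 90, gbar_sdlog = 0.3,
                            noise_sd = 10, g_leak = 0, E_leak = -80,
                            E_Na = 68, overwrite = FALSE) {
  stopifnot(n_cells >= 1L, is.list(protocols), length(protocols) >= 1L)
  if (is.null(names(protocols)))
    names(protocols) <- vapply(protocols, function(p) p$name, "")
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite)
    stop("output directory '", out_dir,
         "' is not empty; use overwrite = TRUE", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rates <- if (inherits(condition, "nav_rates")) condition else nav_preset(condition)
  cond_name <- if (inherits(condition, "nav_rates")) "custom" else condition

  draws <- .with_seed(as.integer(seed), list(
    cap = stats::rlnorm(n_cells, log(cap_median), cap_sdlog),
    gbar = stats::rlnorm(n_cells, log(gbar_median), gbar_sdlog)))
  cell_seeds <- (as.integer(seed) + 1000L * seq_len(n_cells)) %% .Machine$integer.max

  bases <- lapply(protocols, function(p)
    run_protocol(p, rates, macroscopic_params(gbar = 1, E_Na = E_Na),
                 condition = cond_name))

  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    spec <- synthetic_cell_spec(rates, capacitance = draws$cap[i],
                                gbar = draws$gbar[i], noise_sd = noise_sd,
                                g_leak = g_leak, E_leak = E_leak,
                                E_Na = E_Na, seed = cell_seeds[i])
    spec$condition <- cond_name
    files <- character(0)
    truth <- NULL
    for (pn in names(protocols)) {
      cell <- generate_cell(spec, protocols[[pn]], base = bases[[pn]])
      f <- file.path(out_dir, sprintf("cell%02d_%s.csv", i, pn))
      write_sweep_csv(cell$sweeps, f)
      files <- c(files, basename(f), basename(.sidecar_path(f)))
      truth <- cell$truth
    }
    tf <- file.path(out_dir, sprintf("cell%02d_truth.json", i))
    jsonlite::write_json(truth, tf, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    cells[[i]] <- list(cell = sprintf("cell%02d", i), condition = cond_name,
                       seed = cell_seeds[i], capacitance = draws$cap[i],
                       gbar = draws$gbar[i],
                       files = c(files, basename(tf)))
  }
  manifest <- list(n_cells = n_cells, condition = cond_name,
                   cohort_seed = as.integer(seed),
                   protocols = names(protocols), noise_sd = noise_sd,
                   g_leak = g_leak,
                   package_version = as.character(utils::packageVersion("nav16sim")),
                   cells = cells)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
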