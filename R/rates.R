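# Kinetic parameterisation of the 13-state Nav1.6 gating scheme.

# Field order is shared with the compiled core; do not reorder.
.rate_fields <- c("alpha0", "beta0", "alpha_i0", "beta_i0", "gamma0",
                  "delta0", "epsilon", "zeta0", "Con", "Coff", "Oon", "Ooff",
                  "k_alpha", "k_beta", "k_zeta", "density_scale")

.state_names <- c(paste0("C", 1:5), "O", "OB", paste0("I", 1:6))

#' Kinetic rate constants for one channel condition
#'
#' Bundles the full parameterisation of the 13-state gating scheme: base
#' transition rates at 0 mV (all in 1/ms), voltage e-fold constants (mV), and
#' the dimensionless conductance multiplier `density_scale`. The derived
#' allosteric factor `a = (Oon*Coff / (Ooff*Con))^(1/4)` couples closed-state
#' and open-state inactivation and is recomputed on construction, never set
#' directly.
#'
#' @param alpha0,beta0 Base activation/deactivation rates along the closed
#'   tier at 0 mV (1/ms).
#' @param alpha_i0,beta_i0 Base forward/backward rates along the inactivated
#'   tier (1/ms); independent of `alpha0`/`beta0` so the voltage dependence
#'   of activation and inactivation is partially uncoupled.
#' @param gamma0,delta0 Opening (C5 -> O) and closing (O -> C5) rates (1/ms),
#'   voltage independent.
#' @param epsilon Open-channel block entry rate O -> OB (1/ms); 0 in all
#'   shipped conditions, which removes resurgent current.
#' @param zeta0 Base unblock rate OB -> O at 0 mV (1/ms).
#' @param Con,Coff Closed-state inactivation on/off rates (1/ms).
#' @param Oon,Ooff Open-state inactivation on/off rates (1/ms).
#' @param k_alpha,k_beta,k_zeta Voltage e-fold constants (mV) for the
#'   activation, deactivation and unblock rates.
#' @param density_scale Multiplier on maximal conductance (> 0); expresses a
#'   condition's current-density change relative to wild type.
#' @return An object of class `nav_rates` (named list of the parameters plus
#'   the derived `a`).
#' @examples
#' r <- nav_rates()           # wild-type defaults
#' r$a                        # derived allosteric factor
#' @export
nav_rates <- function(alpha0 = 150, beta0 = 3, alpha_i0 = 150, beta_i0 = 3,
                      gamma0 = 150, delta0 = 40, epsilon = 0, zeta0 = 0.03,
                      Con = 0.005, Coff = 0.5, Oon = 0.75, Ooff = 0.005,
                      k_alpha = 20, k_beta = 20, k_zeta = 25,
                      density_scale = 1) {
  vals <- list(alpha0 = alpha0, beta0 = beta0, alpha_i0 = alpha_i0,
               beta_i0 = beta_i0, gamma0 = gamma0, delta0 = delta0,
               epsilon = epsilon, zeta0 = zeta0, Con = Con, Coff = Coff,
               Oon = Oon, Ooff = Ooff, k_alpha = k_alpha, k_beta = k_beta,
               k_zeta = k_zeta, density_scale = density_scale)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0) stop("'", nm, "' must be non-negative", call. = FALSE)
    vals[[nm]] <- as.numeric(v)
  }
  if (vals$density_scale <= 0)
    stop("'density_scale' must be > 0", call. = FALSE)
  if (vals$k_alpha <= 0 || vals$k_beta <= 0 || vals$k_zeta <= 0)
    stop("voltage e-fold constants must be > 0", call. = FALSE)
  vals$a <- .allosteric_factor(vals)
  structure(vals, class = "nav_rates")
}

.allosteric_factor <- function(r) {
  num <- r$Oon * r$Coff
  den <- r$Ooff * r$Con
  if (den == 0) {
    if (num == 0) return(1)
    return(Inf)
  }
  (num / den)^0.25
}

#' @export
print.nav_rates <- function(x, ...) {
  cat("Nav1.6 Markov rate constants (1/ms at 0 mV)\n")
  v <- unlist(x[.rate_fields])
  print(round(v, 5))
  cat(sprintf("derived allosteric factor a = %.4f\n", x$a))
  invisible(x)
}

# Numeric vector in the fixed field order expected by the compiled core.
.rates_vec <- function(rates) {
  stopifnot(inherits(rates, "nav_rates"))
  unlist(rates[.rate_fields], use.names = FALSE)
}

#' Modify rate constants
#'
#' Returns a new `nav_rates` with the given fields replaced; the allosteric
#' factor is recomputed, so thermodynamic consistency of the scheme's loops
#' is maintained automatically.
#'
#' @param rates A [nav_rates()] object.
#' @param ... Named scalar replacements for any rate field.
#' @return A new `nav_rates` object.
#' @export
update_rates <- function(rates, ...) {
  stopifnot(inherits(rates, "nav_rates"))
  repl <- list(...)
  bad <- setdiff(names(repl), .rate_fields)
  if (length(bad))
    stop("unknown rate field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  args <- rates[.rate_fields]
  args[names(repl)] <- repl
  do.call(nav_rates, args)
}

.preset_cache <- new.env(parent = emptyenv())

#' Built-in channel conditions
#'
#' The six shipped parameter conditions: wild type (`WT`), the epilepsy
#' variants `R639C` and `R850Q`, and each of the three with CaMKII inhibited
#' (`+CN21`). CaMKII-inhibited and mutant conditions differ from wild type in
#' current density and in a subset of rate constants; parameters not listed
#' for a condition keep the wild-type defaults. Conditions are read from the
#' JSON table shipped in `extdata/nav16_conditions.json`, the same format
#' accepted by [read_conditions_json()] for user-defined conditions.
#'
#' @param name Condition name, one of `nav_condition_names()`.
#' @return `nav_preset()`: a [nav_rates()] object. `nav_condition_names()`:
#'   character vector of available names.
#' @examples
#' nav_preset("R639C")$density_scale   # 1.72x wild-type density
#' @export
nav_preset <- function(name) {
  tbl <- .preset_table()
  if (!name %in% names(tbl))
    stop("unknown condition '", name, "'; available: ",
         paste(names(tbl), collapse = ", "), call. = FALSE)
  tbl[[name]]
}

#' @rdname nav_preset
#' @export
nav_condition_names <- function() names(.preset_table())

.preset_table <- function() {
  if (is.null(.preset_cache$tbl)) {
    path <- system.file("extdata", "nav16_conditions.json",
                        package = "nav16sim", mustWork = TRUE)
    .preset_cache$tbl <- read_conditions_json(path)
  }
  .preset_cache$tbl
}

#' Read and write channel-condition JSON tables
#'
#' A condition table is a JSON object mapping condition names to objects with
#' the [nav_rates()] fields; missing fields take the wild-type defaults.
#' These functions round-trip losslessly and let users define their own
#' conditions in the same format as the shipped presets.
#'
#' @param path File path.
#' @param conditions Named list of [nav_rates()] objects.
#' @return `read_conditions_json()`: named list of `nav_rates`.
#'   `write_conditions_json()`: `path`, invisibly.
#' @export
read_conditions_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!length(raw) || is.null(names(raw)))
    stop("condition table must be a named JSON object", call. = FALSE)
  out <- lapply(raw, function(flds) {
    flds <- flds[intersect(names(flds), .rate_fields)]
    do.call(nav_rates, flds)
  })
  out
}

#' @rdname read_conditions_json
#' @export
write_conditions_json <- function(conditions, path) {
  stopifnot(all(vapply(conditions, inherits, TRUE, "nav_rates")))
  tbl <- lapply(conditions, function(r) r[.rate_fields])
  jsonlite::write_json(tbl, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
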