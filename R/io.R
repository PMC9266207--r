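# Sweep-set serialisation: CSV trace table + JSON sidecar with protocol and
# cell metadata. Dialect: comma-separated, '.' decimal, header row, time in
# ms; sweeps of unequal length (recovery protocols) are NA-padded.

#' Write and read sweep sets
#'
#' `write_sweep_csv()` writes the traces as a CSV (column 1 `time_ms`, one
#' `sweep_###` column per sweep, pA) plus a JSON sidecar
#' (`<path-without-ext>.json`) holding dt, command values, the protocol
#' descriptor, condition, capacitance and seed. `read_sweep_csv()` restores
#' a `sweep_set` that round-trips through [measure_peak()] and the analysis
#' chain; if the sidecar is missing the traces are still read (with a
#' warning) but capacitance and protocol metadata are absent.
#'
#' @param ss A `sweep_set`.
#' @param path CSV file path.
#' @return `write_sweep_csv()`: `path` invisibly. `read_sweep_csv()`: a
#'   `sweep_set`.
#' @export
write_sweep_csv <- function(ss, path) {
  stopifnot(inherits(ss, "sweep_set"))
  n <- length(ss$current)
  len <- vapply(ss$current, length, 1L)
  L <- max(len)
  ref <- which.max(len)
  m <- matrix(NA_real_, L, n)
  for (i in seq_len(n)) m[seq_len(len[i]), i] <- ss$current[[i]]
  df <- data.frame(time_ms = ss$time[[ref]], m)
  names(df)[-1L] <- sprintf("sweep_%03d", seq_len(n))
  utils::write.csv(df, path, row.names = FALSE)
  proto <- ss$protocol
  side <- list(
    dt = ss$dt, command = ss$command, vary = proto$vary,
    holding = proto$holding, protocol = proto$name,
    measure_segment = proto$measure_segment,
    conditioning_segment = proto$conditioning_segment,
    segments = lapply(proto$sweeps, function(s) as.list(s)),
    condition = ss$condition, capacitance = ss$capacitance, seed = ss$seed,
    package_version = as.character(utils::packageVersion("nav16sim")))
  jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("cannot parse sweep CSV '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  if (names(df)[1L] != "time_ms")
    stop("malformed sweep CSV: first column must be 'time_ms' (line 1)",
         call. = FALSE)
  if (!all(vapply(df, is.numeric, TRUE)))
    stop("malformed sweep CSV: non-numeric trace values", call. = FALSE)
  side_path <- .sidecar_path(path)
  side <- NULL
  if (file.exists(side_path)) {
    raw <- jsonlite::read_json(side_path, simplifyVector = FALSE)
    side <- list(
      dt = as.numeric(raw$dt), command = as.numeric(unlist(raw$command)),
      vary = raw$vary, holding = as.numeric(raw$holding),
      protocol = raw$protocol,
      measure_segment = as.integer(raw$measure_segment),
      conditioning_segment = if (!is.null(raw$conditioning_segment))
        as.integer(raw$conditioning_segment),
      segments = lapply(raw$segments, function(s)
        data.frame(level = as.numeric(unlist(s$level)),
                   duration = as.numeric(unlist(s$duration)))),
      condition = if (!is.null(raw$condition)) as.character(raw$condition),
      capacitance = if (!is.null(raw$capacitance)) as.numeric(raw$capacitance),
      seed = if (!is.null(raw$seed)) as.integer(raw$seed))
  } else {
    warning("sidecar JSON missing for '", path,
            "': protocol metadata and capacitance unavailable")
  }
  tm <- df$time_ms
  n <- ncol(df) - 1L
  cur <- lapply(seq_len(n), function(i) {
    x <- df[[i + 1L]]
    x[!is.na(x)]
  })
  tms <- lapply(cur, function(x) tm[seq_along(x)])
  if (!is.null(side)) {
    sweeps <- side$segments
    proto <- voltage_protocol(side$holding, sweeps, side$command,
                              vary = side$vary, dt = side$dt,
                              measure_segment = side$measure_segment,
                              conditioning_segment = side$conditioning_segment,
                              name = side$protocol)
    segb <- lapply(sweeps, function(s) cumsum(s$duration))
    structure(list(time = tms, current = cur, popen = NULL,
                   command = side$command, protocol = proto, dt = side$dt,
                   condition = side$condition, segment_ends = segb,
                   capacitance = side$capacitance, seed = side$seed),
              class = "sweep_set")
  } else {
    dt <- if (length(tm) > 1L) tm[2L] - tm[1L] else NA_real_
    segb <- lapply(tms, function(t) max(t))
    proto <- voltage_protocol(NA_real_,
                              lapply(tms, function(t)
                                data.frame(level = NA_real_, duration = max(t))),
                              command = seq_len(n), dt = dt,
                              measure_segment = 1L, name = "unknown")
    structure(list(time = tms, current = cur, popen = NULL,
                   command = seq_len(n), protocol = proto, dt = dt,
                   condition = NULL, segment_ends = segb,
                   capacitance = NULL, seed = NULL),
              class = "sweep_set")
  }
}

#' Write an occupancy time series as CSV
#'
#' Column 1 is time (ms), remaining columns the 13 state occupancies.
#'
#' @param occ Data frame from [integrate_occupancy()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_occupancy_csv <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE)
  invisible(path)
}
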