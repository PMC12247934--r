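RECORDING_HEADER <- c("time_s", "pressure_in_mmhg", "pressure_out_mmhg",
                      "outer_diameter_um", "inner_diameter_um")

#' Write a myography recording to a delimited text table
#'
#' Comma-separated table with the exact header
#' \code{time_s,pressure_in_mmhg,pressure_out_mmhg,outer_diameter_um,inner_diameter_um},
#' missing values as empty fields, numeric fields at 6 significant
#' digits, and metadata as leading \code{# key=value} comment lines
#' (\code{condition}, \code{seed}, \code{sample_rate_hz},
#' \code{rupture_time_s}).
#'
#' @param rec A [myo_recording()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "myo_recording"))
  meta <- c(
    sprintf("# condition=%s", attr(rec, "condition")),
    sprintf("# seed=%s", attr(rec, "seed")),
    sprintf("# sample_rate_hz=%s", format(attr(rec, "sample_rate"),
                                          digits = 10)),
    if (!is.na(attr(rec, "rupture_time_s"))) {
      sprintf("# rupture_time_s=%s", format(attr(rec, "rupture_time_s"),
                                            digits = 10))
    }
  )
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.6g", x))
  rows <- do.call(paste, c(lapply(rec[RECORDING_HEADER], fmt), sep = ","))
  writeLines(c(meta, paste(RECORDING_HEADER, collapse = ","), rows), path)
  invisible(path)
}

#' Read a myography recording table
#'
#' Parses the dialect written by [write_recording()]: leading
#' \code{# key=value} metadata lines, an exact header row, and numeric
#' fields with empty entries as missing. The time column must be
#' strictly increasing; violations are reported with their line number.
#'
#' @param path File path.
#' @return A [myo_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_param("file not found: %s", path)
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  n_meta <- if (any(!is_meta)) which(!is_meta)[1] - 1L else length(lines)
  meta <- list()
  for (ln in lines[seq_len(n_meta)]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substring(kv, eq + 1)
  }
  body <- lines[!is_meta]
  if (length(body) < 1) stop_param("parse error: no header row in %s", path)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (!identical(header, RECORDING_HEADER)) {
    stop_param("parse error at line %d: header must be exactly '%s'",
               n_meta + 1L, paste(RECORDING_HEADER, collapse = ","))
  }
  if (length(body) < 2) stop_param("parse error: no data rows in %s", path)
  cells <- strsplit(body[-1], ",", fixed = TRUE)
  num <- function(i) {
    vapply(cells, function(r) {
      v <- if (length(r) >= i) r[i] else ""
      if (v == "") NA_real_ else suppressWarnings(as.numeric(v))
    }, numeric(1))
  }
  cols <- lapply(seq_along(RECORDING_HEADER), num)
  names(cols) <- RECORDING_HEADER
  bad <- which(is.na(cols$time_s))
  if (length(bad) > 0) {
    stop_param("parse error at line %d: non-numeric or missing time",
               n_meta + 1L + bad[1])
  }
  nonmono <- which(diff(cols$time_s) <= 0)
  if (length(nonmono) > 0) {
    stop_param("parse error at line %d: time not strictly increasing",
               n_meta + 2L + nonmono[1])
  }
  seed <- suppressWarnings(as.integer(meta$seed))
  myo_recording(
    cols$time_s, cols$pressure_in_mmhg, cols$pressure_out_mmhg,
    cols$outer_diameter_um, cols$inner_diameter_um,
    condition = if (is.null(meta$condition)) "unspecified" else meta$condition,
    seed = if (length(seed) == 0 || is.na(seed)) NA_integer_ else seed,
    sample_rate = if (is.null(meta$sample_rate_hz)) {
      1 / median(diff(cols$time_s))
    } else as.numeric(meta$sample_rate_hz),
    rupture_time_s = if (is.null(meta$rupture_time_s)) NA_real_
                     else as.numeric(meta$rupture_time_s)
  )
}

# every key run_config accepts, with package defaults
config_defaults <- function() {
  list(
    seed = 1L,
    preset = "compliant",
    drive = "pulsatile",
    diastolic_pressure = 80, systolic_pressure = 120, beat_rate = 65,
    duration = 60, sample_rate = 100,
    systolic_fraction = 0.35, rise_fraction = 0.3,
    start_pressure = 0, increment = 64.37, hold_time = 20,
    max_pressure = 450, step_sample_rate = 10,
    diameter_sd = 0, pressure_sd = 0,
    sigma_fail = Inf,
    um_per_px = 2, n_scanlines = 15, smoothing_window = 5,
    gradient_threshold = 0.3, outlier_mad_factor = 3,
    min_prominence = NA, min_separation = 0.3,
    fit_axial_stretch = 1, fit_n_multistart = 8, fit_alpha0_deg = 45
  )
}

#' Load a run configuration
#'
#' Reads a YAML key-value file of pipeline settings, fills unset keys
#' with the package defaults, and rejects unknown keys.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return A named list of settings.
#' @export
run_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_param("config file not found: %s", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      stop_param("unknown config key(s): %s", paste(unknown, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  cfg
}
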