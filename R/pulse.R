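# ---- peak finding core ------------------------------------------------

# interior local maxima with plateau handling: returns the middle index of
# each plateau that rises before and falls after (boundary samples never
# count as peaks)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  # carry the last non-zero slope through flat runs
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  filled <- s
  last <- 0
  for (i in seq_len(n - 1)) {
    if (filled[i] == 0) filled[i] <- last else last <- filled[i]
  }
  cand <- which(filled[-(n - 1)] > 0 & filled[-1] < 0) + 1L
  # re-center each peak on the middle of its plateau of equal values
  vapply(cand, function(i) {
    j0 <- i; j1 <- i
    while (j0 > 1 && x[j0 - 1] == x[i]) j0 <- j0 - 1
    while (j1 < n && x[j1 + 1] == x[i]) j1 <- j1 + 1
    as.integer(floor((j0 + j1) / 2))
  }, integer(1))
}

# topographic prominence of peak at index p: height above the higher of
# the two bounding minima, where each side extends to the nearest sample
# exceeding the peak or to the record edge
peak_prominence <- function(x, p) {
  h <- x[p]
  left <- x[seq_len(p - 1)]
  higher_l <- which(left > h)
  lmin <- min(left[seq.int(if (length(higher_l)) max(higher_l) + 1 else 1,
                           p - 1)])
  right <- x[seq.int(p + 1, length(x))]
  higher_r <- which(right > h)
  rmin <- min(right[seq_len(if (length(higher_r)) min(higher_r) - 1
                            else length(right))])
  h - max(lmin, rmin)
}

# ---- public operations ------------------------------------------------

#' Detect diameter pulses and per-pulse distension
#'
#' Finds pulse peaks on a uniformly sampled diameter trace: local maxima
#' (plateaus count once, at their middle) with topographic prominence at
#' least \code{min_prominence}, separated by at least
#' \code{min_separation} seconds (higher peaks win ties). Boundary
#' samples never count, so pulses cut off by the record edges are
#' excluded. The baseline \eqn{D_{min}} is the median of the inter-peak
#' minima — one global baseline, matching the convention of reporting a
#' single baseline diameter per recording — and each per-pulse diameter
#' change is \eqn{D_{max,i} - D_{min}}.
#'
#' @param time Time grid, s (uniform).
#' @param x Diameter series, um (same length).
#' @param min_prominence Minimum peak prominence, um; default
#'   (\code{NULL}) uses 3 x the median absolute deviation of the
#'   detrended trace (trace minus its running median over ~2 s).
#' @param min_separation Minimum peak separation, s (default 0.3,
#'   supporting pulse rates up to 200/min).
#' @return An object of class \code{"pulse_summary"}: a list with
#'   \code{peak_times}, \code{peak_diameters}, \code{baseline_diameter},
#'   \code{per_pulse_delta}, \code{mean_delta}, \code{sd_delta},
#'   \code{n_peaks}. A trace with no qualifying peaks yields
#'   \code{n_peaks = 0} (not an error).
#' @examples
#' t <- seq(0, 10, by = 0.01)
#' d <- 500 - 10 * cos(2 * pi * t)
#' detect_pulses(t, d, min_prominence = 5)
#' @export
detect_pulses <- function(time, x, min_prominence = NULL,
                          min_separation = 0.3) {
  if (length(time) != length(x)) stop_param("time and x must match in length")
  if (length(x) < 3) stop_param("trace must have at least 3 samples")
  if (min_separation <= 0) stop_param("min_separation must be > 0")
  dt <- median(diff(time))
  keep <- !is.na(x)
  if (is.null(min_prominence)) {
    k <- max(3L, 2L * floor(1 / dt) + 1L)  # ~2 s running median
    xs <- x[keep]
    detr <- xs - runmed(xs, min(k, length(xs) - (1 - length(xs) %% 2)))
    min_prominence <- 3 * mad(detr, na.rm = TRUE)
  }
  empty <- structure(
    list(peak_times = numeric(0), peak_diameters = numeric(0),
         baseline_diameter = NA_real_, per_pulse_delta = numeric(0),
         mean_delta = NA_real_, sd_delta = NA_real_, n_peaks = 0L),
    class = "pulse_summary")
  xv <- x; xv[!keep] <- -Inf
  peaks <- local_maxima(xv)
  if (length(peaks) == 0) return(empty)
  prom <- vapply(peaks, function(p) peak_prominence(xv, p), numeric(1))
  peaks <- peaks[prom >= min_prominence & is.finite(prom)]
  if (length(peaks) == 0) return(empty)
  # enforce separation, keeping higher peaks first
  ord <- order(-x[peaks])
  accepted <- integer(0)
  for (p in peaks[ord]) {
    if (all(abs(time[p] - time[accepted]) >= min_separation)) {
      accepted <- c(accepted, p)
    }
  }
  peaks <- sort(accepted)
  if (length(peaks) >= 2) {
    troughs <- vapply(seq_len(length(peaks) - 1), function(i) {
      min(x[peaks[i]:peaks[i + 1]], na.rm = TRUE)
    }, numeric(1))
    d_min <- median(troughs)
  } else {
    d_min <- min(x, na.rm = TRUE)
  }
  delta <- x[peaks] - d_min
  structure(
    list(peak_times = time[peaks], peak_diameters = x[peaks],
         baseline_diameter = d_min, per_pulse_delta = delta,
         mean_delta = mean(delta), sd_delta = sd(delta),
         n_peaks = length(peaks)),
    class = "pulse_summary")
}

#' @export
print.pulse_summary <- function(x, ...) {
  cat(sprintf("Pulse summary: %d peaks, baseline %.6g um, mean delta %.6g um (sd %.3g)\n",
              x$n_peaks, x$baseline_diameter, x$mean_delta, x$sd_delta))
  invisible(x)
}

#' Dominant pulse frequency by FFT
#'
#' Fundamental frequency of a uniformly sampled periodic signal: the
#' mean-subtracted signal is Fourier transformed and, among local
#' spectral peaks within 6 dB of the strongest, the lowest-frequency one
#' is returned. The 6 dB fundamental rule prevents harmonic capture for
#' square-ish pulse shapes whose low harmonics rival the fundamental.
#' Resolution is 1/duration Hz.
#'
#' @param time Time grid, s (uniform).
#' @param x Signal (diameter or pressure series).
#' @return Frequency, Hz.
#' @examples
#' t <- seq(0, 60, by = 0.01)
#' pulse_frequency(t, sin(2 * pi * 2 * t))
#' @export
pulse_frequency <- function(time, x) {
  if (length(time) != length(x)) stop_param("time and x must match in length")
  keep <- !is.na(x)
  time <- time[keep]; x <- x[keep]
  n <- length(x)
  if (n < 8) stop_param("signal too short for spectral analysis")
  dt <- median(diff(time))
  x <- x - mean(x)
  if (max(abs(x)) == 0) {
    stop_param("constant signal: pulse frequency is undefined")
  }
  mag <- Mod(fft(x))[seq(2, floor(n / 2))]
  freq <- (seq_along(mag)) / (n * dt)
  m <- length(mag)
  is_peak <- c(mag[1] > mag[2],
               mag[2:(m - 1)] >= mag[1:(m - 2)] & mag[2:(m - 1)] >= mag[3:m],
               mag[m] > mag[m - 1])
  cand <- which(is_peak & mag >= max(mag) / 2)  # within 6 dB of the max
  if (length(cand) == 0) cand <- which.max(mag)
  freq[min(cand)]
}

#' Dynamic compliance
#'
#' Fractional diameter distension per unit pulse pressure:
#' \deqn{D_c = \frac{(D_{max} - D_{min})/D_{min}}{P_{max} - P_{min}}}
#' in 1/mmHg. Scale-invariant in the diameters and dependent only on the
#' pressure difference.
#'
#' @param d_max Peak diameter, um.
#' @param d_min Baseline diameter, um, > 0.
#' @param p_max Peak (systolic) pressure, mmHg.
#' @param p_min Baseline (diastolic) pressure, mmHg, < \code{p_max}.
#' @return Dynamic compliance, 1/mmHg. Vectorized over \code{d_max}.
#' @examples
#' dynamic_compliance(550, 500, 120, 80)  # 0.0025
#' @export
dynamic_compliance <- function(d_max, d_min, p_max, p_min) {
  if (any(d_min <= 0)) stop_param("d_min must be > 0")
  if (any(p_max <= p_min)) stop_param("p_max must exceed p_min")
  ((d_max - d_min) / d_min) / (p_max - p_min)
}

#' Per-pulse dynamic compliance of a recording
#'
#' Detects pulses on the outer diameter (the diameter used for all
#' compliance calculations) and on the recorded pressure, then evaluates
#' [dynamic_compliance()] per diameter pulse against the recording-level
#' pressure amplitude: \eqn{P_{max}} is the median pressure-peak height
#' and \eqn{P_{min}} the median inter-peak pressure minimum, pairing one
#' pulse-pressure difference with the recording.
#'
#' @param rec A [myo_recording()].
#' @param min_prominence,min_separation Passed to [detect_pulses()] for
#'   the diameter trace.
#' @return An object of class \code{"compliance_result"}: list with
#'   \code{per_pulse_dc}, \code{mean_dc}, \code{sd_dc}, \code{p_max},
#'   \code{p_min}, \code{n_pulses}, and the underlying
#'   \code{pulse_summary}. No pulses yields \code{n_pulses = 0}.
#' @export
recording_compliance <- function(rec, min_prominence = NULL,
                                 min_separation = 0.3) {
  stopifnot(inherits(rec, "myo_recording"))
  ps <- detect_pulses(rec$time_s, rec$outer_diameter_um,
                      min_prominence, min_separation)
  empty <- structure(
    list(per_pulse_dc = numeric(0), mean_dc = NA_real_, sd_dc = NA_real_,
         p_max = NA_real_, p_min = NA_real_, n_pulses = 0L, pulses = ps),
    class = "compliance_result")
  if (ps$n_peaks == 0) return(empty)
  pr <- recording_pressure(rec)
  pp <- detect_pulses(rec$time_s, pr, min_prominence = NULL,
                      min_separation = min_separation)
  if (pp$n_peaks == 0) return(empty)
  p_max <- median(pp$peak_diameters)
  p_min <- pp$baseline_diameter
  dc <- dynamic_compliance(ps$peak_diameters, ps$baseline_diameter,
                           p_max, p_min)
  structure(
    list(per_pulse_dc = dc, mean_dc = mean(dc), sd_dc = sd(dc),
         p_max = p_max, p_min = p_min, n_pulses = ps$n_peaks, pulses = ps),
    class = "compliance_result")
}

#' @export
print.compliance_result <- function(x, ...) {
  cat(sprintf("Dynamic compliance: mean %.4g /mmHg (sd %.3g) over %d pulses; P %.4g/%.4g mmHg\n",
              x$mean_dc, x$sd_dc, x$n_pulses, x$p_max, x$p_min))
  invisible(x)
}

#' Burst pressure of a recording
#'
#' The maximum pressure sustained before wall rupture. If the recording
#' carries a rupture time, the estimate is the maximum of the recorded
#' pressure strictly before it; a short running-median filter (~0.5 s)
#' suppresses sensor noise so the max statistic is not inflated by noise
#' extremes (on a noiseless staircase the filter is a no-op). Without a
#' rupture the protocol completed: the maximum pressure reached is
#' reported but not labeled a burst pressure.
#'
#' @param rec A [myo_recording()].
#' @return A list: \code{burst} (logical: did the vessel rupture),
#'   \code{burst_pressure_mmhg} (NA if no rupture),
#'   \code{max_pressure_mmhg} (max pressure reached either way).
#' @export
burst_pressure <- function(rec) {
  stopifnot(inherits(rec, "myo_recording"))
  if (nrow(rec) == 0) stop_param("empty recording")
  p <- recording_pressure(rec)
  sr <- attr(rec, "sample_rate")
  if (is.na(sr)) sr <- 1 / median(diff(rec$time_s))
  k <- max(3L, as.integer(round(0.5 * sr)))
  if (k %% 2 == 0) k <- k + 1L
  pf <- if (length(p) > k) runmed(p, k) else p
  rt <- attr(rec, "rupture_time_s")
  if (is.na(rt)) {
    return(list(burst = FALSE, burst_pressure_mmhg = NA_real_,
                max_pressure_mmhg = max(pf)))
  }
  pre <- rec$time_s < rt
  if (!any(pre)) stop_param("no samples before rupture")
  list(burst = TRUE, burst_pressure_mmhg = max(pf[pre]),
       max_pressure_mmhg = max(pf[pre]))
}

#' Plateau pressure of a pressure-diameter curve
#'
#' The pressure beyond which the vessel stops distending: the lowest
#' pressure at which the local slope dOD/dP (central differences) falls
#' below \code{slope_fraction} times the maximum slope over the curve and
#' stays below it at every higher pressure. Returns NA when the slope
#' never settles (e.g. a straight line).
#'
#' @param pressure Pressures, mmHg, ascending, >= 4 points.
#' @param outer_diameter Outer diameters, um.
#' @param slope_fraction Plateau threshold as a fraction of the peak
#'   slope (default 0.1).
#' @return Plateau pressure, mmHg, or NA.
#' @export
plateau_pressure <- function(pressure, outer_diameter,
                             slope_fraction = 0.1) {
  n <- length(pressure)
  if (n < 4 || length(outer_diameter) != n) {
    stop_param("need >= 4 ascending pressure points with matching diameters")
  }
  if (any(diff(pressure) <= 0)) stop_param("pressures must be ascending")
  slope <- numeric(n)
  slope[1] <- (outer_diameter[2] - outer_diameter[1]) /
    (pressure[2] - pressure[1])
  slope[n] <- (outer_diameter[n] - outer_diameter[n - 1]) /
    (pressure[n] - pressure[n - 1])
  i <- 2:(n - 1)
  slope[i] <- (outer_diameter[i + 1] - outer_diameter[i - 1]) /
    (pressure[i + 1] - pressure[i - 1])
  smax <- max(slope)
  if (smax <= 0) return(NA_real_)
  below <- slope < slope_fraction * smax
  stays <- rev(cumprod(rev(below))) > 0   # below here and at all higher P
  if (!any(stays)) return(NA_real_)
  pressure[which(stays)[1]]
}

#' Percentage constriction of a constrictor dose-response
#'
#' Min-max normalization of a vasoconstriction series: 0% at the largest
#' observed diameter, 100% at the smallest (the highest degree of
#' constriction), linear in between and invariant to diameter offsets.
#'
#' @param dr A [dose_response()] with \code{agent_type = "constrictor"},
#'   or a bare numeric vector of diameters.
#' @return Percent constriction per concentration, in [0, 100].
#' @examples
#' percent_constriction(c(400, 380, 320, 300))  # 0 20 80 100
#' @export
percent_constriction <- function(dr) {
  d <- if (inherits(dr, "dose_response")) {
    if (attr(dr, "agent_type") != "constrictor") {
      stop_param("percent_constriction needs a constrictor series")
    }
    dr$diameter_um
  } else as.numeric(dr)
  if (length(d) < 2) stop_param("need at least 2 diameters")
  rng <- max(d) - min(d)
  if (rng == 0) stop_param("all diameters equal: constriction undefined")
  100 * (max(d) - d) / rng
}

#' Percentage relaxation of a dilator dose-response
#'
#' 0% at the pre-dose (first) diameter, 100% at the largest diameter
#' observed, linear in between.
#'
#' @param dr A [dose_response()] with \code{agent_type = "dilator"}, or a
#'   bare numeric vector of diameters whose first entry is pre-dose.
#' @return Percent relaxation per concentration.
#' @examples
#' percent_relaxation(c(300, 320, 360, 400))  # 0 20 60 100
#' @export
percent_relaxation <- function(dr) {
  d <- if (inherits(dr, "dose_response")) {
    if (attr(dr, "agent_type") != "dilator") {
      stop_param("percent_relaxation needs a dilator series")
    }
    dr$diameter_um
  } else as.numeric(dr)
  if (length(d) < 2) stop_param("need at least 2 diameters")
  rng <- max(d) - d[1]
  if (rng == 0) stop_param("no dilation beyond the starting diameter")
  100 * (d - d[1]) / rng
}
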