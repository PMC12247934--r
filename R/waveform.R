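#' Pulsatile pressure protocol specification
#'
#' Describes a cyclic diastolic/systolic pressure drive: each cycle of
#' length \code{60/beat_rate} seconds holds the diastolic baseline and ends
#' with a smoothed-square systolic pulse occupying \code{systolic_fraction}
#' of the cycle. The pulse rises and falls with raised-cosine ramps each
#' spanning \code{rise_fraction} of the systolic window, so a
#' \code{rise_fraction} of 0.5 gives a pure raised-cosine bump and smaller
#' values give a flat-topped (square-like) pulse.
#'
#' Traces generated from a spec start at t = 0 at the diastolic baseline;
#' the systolic window sits at the end of each cycle, so a recording that
#' ends mid-cycle truncates an un-started pulse rather than an ongoing one.
#'
#' @param diastolic_pressure Baseline (minimum) pressure, mmHg.
#' @param systolic_pressure Peak pressure, mmHg; must exceed the diastolic.
#' @param beat_rate Pulse rate, beats per minute.
#' @param duration Total trace duration, seconds.
#' @param sample_rate Sampling rate, Hz; at least 10 samples per cycle.
#' @param systolic_fraction Fraction of each cycle spent in the systolic
#'   window, in (0, 1). Default 0.35, a typical arterial systole fraction.
#' @param rise_fraction Fraction of the systolic window used by each
#'   raised-cosine ramp, in (0, 0.5]. Default 0.3.
#' @return An object of class \code{"pulse_spec"}.
#' @seealso [generate_pulsatile_pressure()]
#' @export
pulse_spec <- function(diastolic_pressure, systolic_pressure, beat_rate,
                       duration, sample_rate, systolic_fraction = 0.35,
                       rise_fraction = 0.3) {
  check_scalar(diastolic_pressure, "diastolic_pressure")
  check_scalar(systolic_pressure, "systolic_pressure")
  check_scalar(beat_rate, "beat_rate")
  check_scalar(duration, "duration")
  check_scalar(sample_rate, "sample_rate")
  check_scalar(systolic_fraction, "systolic_fraction")
  check_scalar(rise_fraction, "rise_fraction")
  if (diastolic_pressure < 0) {
    stop_param("invalid pulse spec: diastolic_pressure must be >= 0 (got %g)",
               diastolic_pressure)
  }
  if (systolic_pressure <= diastolic_pressure) {
    stop_param(paste0("invalid pulse spec: systolic_pressure (%g) must ",
                      "exceed diastolic_pressure (%g)"),
               systolic_pressure, diastolic_pressure)
  }
  if (beat_rate <= 0) stop_param("invalid pulse spec: beat_rate must be > 0")
  if (duration <= 0) stop_param("invalid pulse spec: duration must be > 0")
  if (sample_rate < 10 * beat_rate / 60) {
    stop_param(paste0("invalid pulse spec: sample_rate (%g Hz) must be at ",
                      "least 10 x beat_rate/60 (%g Hz)"),
               sample_rate, 10 * beat_rate / 60)
  }
  if (systolic_fraction <= 0 || systolic_fraction >= 1) {
    stop_param("invalid pulse spec: systolic_fraction must be in (0, 1)")
  }
  if (rise_fraction <= 0 || rise_fraction > 0.5) {
    stop_param("invalid pulse spec: rise_fraction must be in (0, 0.5]")
  }
  structure(
    list(diastolic_pressure = diastolic_pressure,
         systolic_pressure = systolic_pressure,
         beat_rate = beat_rate, duration = duration,
         sample_rate = sample_rate, systolic_fraction = systolic_fraction,
         rise_fraction = rise_fraction),
    class = "pulse_spec"
  )
}

#' Stepwise pressure protocol specification
#'
#' Describes a click-quantized staircase: pressure starts at
#' \code{start_pressure} and each "click" raises it by \code{increment},
#' holding every level for \code{hold_time} seconds, until the first level
#' at or above \code{max_pressure}.
#'
#' @param start_pressure Initial pressure level, mmHg.
#' @param increment Pressure rise per click, mmHg; must be positive.
#' @param hold_time Hold duration at each level, seconds.
#' @param max_pressure Target pressure, mmHg; the protocol ends at the
#'   first level at or above it.
#' @param sample_rate Sampling rate, Hz.
#' @return An object of class \code{"step_spec"}.
#' @seealso [generate_step_protocol()]
#' @export
step_spec <- function(start_pressure, increment, hold_time, max_pressure,
                      sample_rate) {
  check_scalar(start_pressure, "start_pressure")
  check_scalar(increment, "increment")
  check_scalar(hold_time, "hold_time")
  check_scalar(max_pressure, "max_pressure")
  check_scalar(sample_rate, "sample_rate")
  if (start_pressure < 0) stop_param("invalid step spec: start_pressure must be >= 0")
  if (increment <= 0) stop_param("invalid step spec: increment must be > 0")
  if (hold_time <= 0) stop_param("invalid step spec: hold_time must be > 0")
  if (max_pressure <= start_pressure) {
    stop_param("invalid step spec: max_pressure must exceed start_pressure")
  }
  if (sample_rate <= 0) stop_param("invalid step spec: sample_rate must be > 0")
  structure(
    list(start_pressure = start_pressure, increment = increment,
         hold_time = hold_time, max_pressure = max_pressure,
         sample_rate = sample_rate),
    class = "step_spec"
  )
}

new_pressure_trace <- function(time, pressure, sample_rate) {
  structure(
    tibble::tibble(time_s = time, pressure_mmhg = pressure),
    sample_rate = sample_rate,
    class = c("pressure_trace", "tbl_df", "tbl", "data.frame")
  )
}

# cycle-phase shape of the pulse: u in [0, 1), returns s in [0, 1]
pulse_shape <- function(u, systolic_fraction, rise_fraction) {
  s <- numeric(length(u))
  u0 <- 1 - systolic_fraction
  inside <- u >= u0
  v <- (u[inside] - u0) / systolic_fraction
  r <- rise_fraction
  sv <- ifelse(v < r, 0.5 * (1 - cos(pi * v / r)),
        ifelse(v <= 1 - r, 1,
               0.5 * (1 - cos(pi * (1 - v) / r))))
  s[inside] <- sv
  s
}

#' Generate a pulsatile pressure trace
#'
#' Evaluates a [pulse_spec()] on a uniform time grid starting at t = 0
#' (endpoint excluded), giving a periodic trace whose minimum is the
#' diastolic and whose maximum is the systolic setpoint, with one pulse
#' per cycle. Setpoints are taken literally; transducer overshoot or lag
#' is not modeled.
#'
#' @param spec A [pulse_spec()].
#' @return A \code{pressure_trace}: a tibble with columns \code{time_s}
#'   and \code{pressure_mmhg} and a \code{sample_rate} attribute.
#' @examples
#' tr <- generate_pulsatile_pressure(pulse_spec(80, 120, 65, 10, 100))
#' range(tr$pressure_mmhg)
#' @export
generate_pulsatile_pressure <- function(spec) {
  if (!inherits(spec, "pulse_spec")) {
    stop_param("`spec` must be a pulse_spec object")
  }
  n <- round(spec$duration * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  period <- 60 / spec$beat_rate
  u <- (t %% period) / period
  s <- pulse_shape(u, spec$systolic_fraction, spec$rise_fraction)
  p <- spec$diastolic_pressure +
    (spec$systolic_pressure - spec$diastolic_pressure) * s
  new_pressure_trace(t, p, spec$sample_rate)
}

#' Generate a stepwise (staircase) pressure trace
#'
#' Evaluates a [step_spec()]: the pressure is constant at
#' \code{start_pressure + k * increment} during hold \code{k}, ending with
#' the first level at or above \code{max_pressure}. The result is a
#' right-continuous step function with exactly
#' \code{hold_time * sample_rate} samples per level.
#'
#' @param spec A [step_spec()].
#' @return A \code{pressure_trace} tibble (see
#'   [generate_pulsatile_pressure()]) with an additional \code{level}
#'   attribute giving the ordered level pressures.
#' @examples
#' tr <- generate_step_protocol(step_spec(0, 64.37, 20, 450, 10))
#' attr(tr, "levels")
#' @export
generate_step_protocol <- function(spec) {
  if (!inherits(spec, "step_spec")) {
    stop_param("`spec` must be a step_spec object")
  }
  n_levels <- ceiling((spec$max_pressure - spec$start_pressure) /
                        spec$increment) + 1
  levels <- spec$start_pressure + (seq_len(n_levels) - 1) * spec$increment
  per_level <- round(spec$hold_time * spec$sample_rate)
  p <- rep(levels, each = per_level)
  t <- (seq_along(p) - 1) / spec$sample_rate
  tr <- new_pressure_trace(t, p, spec$sample_rate)
  attr(tr, "levels") <- levels
  tr
}
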