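#' Construct a myography recording
#'
#' Container pairing a pressure drive with tracked diameters on one
#' uniform time grid, mirroring a dual-pressure-sensor myograph (inlet
#' and outlet transducer columns; analysis uses their mean by default).
#'
#' @param time_s Time grid, s.
#' @param pressure_in_mmhg,pressure_out_mmhg Recorded pressures, mmHg.
#' @param outer_diameter_um,inner_diameter_um Tracked diameters, um
#'   (NA after rupture).
#' @param condition Free-text condition label.
#' @param seed Integer seed the recording was generated with (NA if not
#'   applicable).
#' @param sample_rate Sampling rate, Hz.
#' @param rupture_time_s Time of wall rupture, s, or NA if none.
#' @return An object of class \code{"myo_recording"}: a tibble of the
#'   five series with metadata attributes.
#' @export
myo_recording <- function(time_s, pressure_in_mmhg, pressure_out_mmhg,
                          outer_diameter_um, inner_diameter_um,
                          condition = "unspecified", seed = NA_integer_,
                          sample_rate = NA_real_,
                          rupture_time_s = NA_real_) {
  n <- length(time_s)
  if (length(pressure_in_mmhg) != n || length(pressure_out_mmhg) != n ||
      length(outer_diameter_um) != n || length(inner_diameter_um) != n) {
    stop_param("all recording series must share one time grid")
  }
  if (n > 1 && any(diff(time_s) <= 0)) {
    stop_param("time must be strictly increasing")
  }
  structure(
    tibble::tibble(
      time_s = time_s,
      pressure_in_mmhg = pressure_in_mmhg,
      pressure_out_mmhg = pressure_out_mmhg,
      outer_diameter_um = outer_diameter_um,
      inner_diameter_um = inner_diameter_um
    ),
    condition = condition, seed = seed, sample_rate = sample_rate,
    rupture_time_s = rupture_time_s,
    class = c("myo_recording", "tbl_df", "tbl", "data.frame")
  )
}

#' Recorded luminal pressure of a recording
#'
#' Mean of the inlet and outlet transducer columns (the default pressure
#' used by every analysis); falls back to whichever column is present
#' when one is entirely missing.
#'
#' @param rec A [myo_recording()].
#' @return Numeric vector of pressures, mmHg.
#' @export
recording_pressure <- function(rec) {
  stopifnot(inherits(rec, "myo_recording"))
  pin <- rec$pressure_in_mmhg
  pout <- rec$pressure_out_mmhg
  if (all(is.na(pout))) return(pin)
  if (all(is.na(pin))) return(pout)
  (pin + pout) / 2
}

#' Simulate a myography recording from the digital vessel
#'
#' Drives the four-fiber-family wall model with a pressure trace: at each
#' sample the loaded diameters come from the equilibrium
#' pressure-diameter map, then independent Gaussian measurement noise is
#' added (diameter noise independently on OD and ID; pressure noise
#' independently on each of the two recorded sensor columns). With zero
#' noise the simulation is deterministic and seed-independent.
#'
#' @param params A [four_fiber_params()].
#' @param geom A [vessel_geometry()].
#' @param drive A \code{pressure_trace} from
#'   [generate_pulsatile_pressure()] or [generate_step_protocol()].
#' @param diameter_sd Gaussian noise SD on each diameter series, um.
#' @param pressure_sd Gaussian noise SD on each pressure sensor, mmHg.
#' @param seed Integer seed for the noise draws (NULL uses the ambient
#'   RNG state).
#' @param condition Condition label stored in the recording.
#' @return A [myo_recording()].
#' @examples
#' pre <- vessel_preset("compliant")
#' drv <- generate_pulsatile_pressure(pulse_spec(80, 120, 65, 5, 50))
#' rec <- simulate_recording(pre$params, pre$geometry, drv, seed = 1)
#' @export
simulate_recording <- function(params, geom, drive, diameter_sd = 0,
                               pressure_sd = 0, seed = NULL,
                               condition = "synthetic") {
  stopifnot(inherits(drive, "pressure_trace"))
  if (diameter_sd < 0 || pressure_sd < 0) stop_param("noise SDs must be >= 0")
  p <- drive$pressure_mmhg
  ord <- order(p)
  lt <- numeric(length(p))
  lt[ord] <- solve_circ_stretch(params, geom, p[ord])
  def <- deformed_geometry(geom, lt)
  n <- length(p)
  noise <- with_seed_if(seed, list(
    od = rnorm(n, 0, diameter_sd), id = rnorm(n, 0, diameter_sd),
    pin = rnorm(n, 0, pressure_sd), pout = rnorm(n, 0, pressure_sd)
  ))
  myo_recording(
    time_s = drive$time_s,
    pressure_in_mmhg = p + noise$pin,
    pressure_out_mmhg = p + noise$pout,
    outer_diameter_um = 2 * def$b + noise$od,
    inner_diameter_um = 2 * def$a + noise$id,
    condition = condition,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    sample_rate = attr(drive, "sample_rate")
  )
}

#' Simulate a stepwise inflation to burst
#'
#' Applies a staircase protocol to the digital vessel until the
#' circumferential wall stress first reaches the failure stress. The wall
#' sustains the failing level for \code{rupture_delay} seconds (so the
#' failing level itself is recorded) and then ruptures: recorded pressure
#' drops to 0 and diameters are missing thereafter. If the failure stress
#' is never reached the full staircase is recorded and
#' \code{rupture_time_s} stays NA.
#'
#' @inheritParams simulate_recording
#' @param step A [step_spec()].
#' @param sigma_fail Failure stress of the wall, kPa (use \code{Inf} for
#'   an unbreakable vessel).
#' @param rupture_delay Sustained time at the failing level before
#'   rupture, s (default 1).
#' @return A [myo_recording()] whose \code{rupture_time_s} attribute is
#'   set if rupture occurred.
#' @export
simulate_burst_experiment <- function(params, geom, step, sigma_fail,
                                      diameter_sd = 0, pressure_sd = 0,
                                      seed = NULL, condition = "burst",
                                      rupture_delay = 1) {
  stopifnot(inherits(step, "step_spec"))
  drive <- generate_step_protocol(step)
  rec <- simulate_recording(params, geom, drive, diameter_sd, pressure_sd,
                            seed = seed, condition = condition)
  # noiseless model stress decides rupture, not the noisy record
  lt <- numeric(nrow(rec))
  ordp <- order(drive$pressure_mmhg)
  lt[ordp] <- solve_circ_stretch(params, geom, drive$pressure_mmhg[ordp])
  stress <- circ_stress(params, lt, geom$axial_stretch)
  fails <- which(stress >= sigma_fail)
  if (length(fails) == 0) return(rec)
  t_fail <- rec$time_s[fails[1]] + rupture_delay
  post <- rec$time_s >= t_fail
  rec$pressure_in_mmhg[post] <- 0
  rec$pressure_out_mmhg[post] <- 0
  rec$outer_diameter_um[post] <- NA_real_
  rec$inner_diameter_um[post] <- NA_real_
  attr(rec, "rupture_time_s") <- t_fail
  rec
}

#' Dose-response container
#'
#' Diameter of a vessel exposed to ascending concentrations of a
#' vasoactive agent.
#'
#' @param concentrations Agent concentrations, mol/L, strictly ascending,
#'   at least 2.
#' @param diameters Observed (outer) diameters, um.
#' @param baseline_diameter Pre-dose diameter, um.
#' @param agent_type \code{"constrictor"} or \code{"dilator"}.
#' @return An object of class \code{"dose_response"}.
#' @export
dose_response <- function(concentrations, diameters, baseline_diameter,
                          agent_type = c("constrictor", "dilator")) {
  agent_type <- match.arg(agent_type)
  if (length(concentrations) < 2 || any(diff(concentrations) <= 0) ||
      any(concentrations <= 0)) {
    stop_param("concentrations must be >= 2 values, positive, strictly ascending")
  }
  if (length(diameters) != length(concentrations)) {
    stop_param("diameters and concentrations must have equal length")
  }
  structure(
    tibble::tibble(concentration_m = concentrations, diameter_um = diameters),
    baseline_diameter = baseline_diameter, agent_type = agent_type,
    class = c("dose_response", "tbl_df", "tbl", "data.frame")
  )
}

#' Simulate a vasoreactivity dose-response series
#'
#' Hill-type pharmacodynamic model of slow active diameter change:
#' \deqn{\Delta D(c) = \pm D_0\, E_{max}\, \frac{c^h}{c^h + EC_{50}^h}}
#' negative for a constrictor, positive for a dilator, plus Gaussian
#' noise. Noiseless output is monotone in concentration.
#'
#' @param baseline_diameter Pre-dose diameter D0, um.
#' @param emax_fraction Maximal fractional diameter change, in (0, 1).
#' @param ec50 Half-maximal concentration, mol/L, > 0.
#' @param hill Hill coefficient, > 0.
#' @param concentrations Ascending concentrations, mol/L.
#' @param agent_type \code{"constrictor"} or \code{"dilator"}.
#' @param noise_sd Gaussian noise SD on diameters, um.
#' @param seed Integer seed (NULL uses the ambient RNG).
#' @return A [dose_response()].
#' @examples
#' simulate_dose_response(400, 0.4, 1e-6, 1.2,
#'                        10^seq(-7, -4, by = 0.5), "constrictor")
#' @export
simulate_dose_response <- function(baseline_diameter, emax_fraction, ec50,
                                   hill, concentrations,
                                   agent_type = c("constrictor", "dilator"),
                                   noise_sd = 0, seed = NULL) {
  agent_type <- match.arg(agent_type)
  check_scalar(ec50, "ec50"); check_scalar(hill, "hill")
  check_scalar(emax_fraction, "emax_fraction")
  if (ec50 <= 0) stop_param("ec50 must be > 0")
  if (hill <= 0) stop_param("hill must be > 0")
  if (emax_fraction <= 0 || emax_fraction >= 1) {
    stop_param("emax_fraction must be in (0, 1)")
  }
  sign <- if (agent_type == "constrictor") -1 else 1
  frac <- concentrations^hill / (concentrations^hill + ec50^hill)
  delta <- sign * baseline_diameter * emax_fraction * frac
  noise <- with_seed_if(seed, rnorm(length(concentrations), 0, noise_sd))
  dose_response(concentrations, baseline_diameter + delta + noise,
                baseline_diameter, agent_type)
}
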