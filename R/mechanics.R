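#' Unloaded vessel geometry
#'
#' Reference (traction-free) configuration of a cylindrical vessel
#' segment: inner radius, wall thickness, and the constant axial stretch
#' imposed during testing.
#'
#' @param inner_radius Unloaded inner radius A, micrometres.
#' @param thickness Unloaded wall thickness H, micrometres.
#' @param axial_stretch Axial stretch lambda_z held during inflation
#'   (dimensionless, default 1).
#' @return An object of class \code{"vessel_geometry"}.
#' @export
vessel_geometry <- function(inner_radius, thickness, axial_stretch = 1) {
  check_scalar(inner_radius, "inner_radius")
  check_scalar(thickness, "thickness")
  check_scalar(axial_stretch, "axial_stretch")
  if (inner_radius <= 0) stop_param("inner_radius must be > 0")
  if (thickness <= 0) stop_param("thickness must be > 0")
  if (axial_stretch <= 0) stop_param("axial_stretch must be > 0")
  structure(
    list(inner_radius = inner_radius, thickness = thickness,
         axial_stretch = axial_stretch),
    class = "vessel_geometry"
  )
}

#' Four-fiber-family constitutive parameters
#'
#' Hyperelastic strain-energy function widely used for arterial wall
#' phenotyping: an isotropic neo-Hookean ground matrix of modulus
#' \code{c_iso} plus four exponential fiber families — axial (0 degrees),
#' circumferential (90 degrees) and a symmetric diagonal pair at
#' \code{+/- alpha0} from the axial direction. The diagonal pair shares
#' one modulus and one exponent, so three \code{c1}/\code{c2} values
#' parameterize the four families:
#'
#' \deqn{W = \frac{c}{2}(\lambda_\theta^2 + \lambda_z^2 + \lambda_r^2 - 3)
#'   + \sum_k \frac{c_{1k}}{4 c_{2k}}
#'     \left[e^{c_{2k}(\lambda_k^2 - 1)^2} - 1\right]}
#'
#' with \eqn{\lambda_r = 1/(\lambda_\theta \lambda_z)} by
#' incompressibility and
#' \eqn{\lambda_k^2 = \lambda_\theta^2 \sin^2\alpha_k +
#' \lambda_z^2 \cos^2\alpha_k}. A family with \code{c2 = 0} degenerates
#' continuously to the quadratic \eqn{(c_1/4)(\lambda_k^2-1)^2}.
#'
#' @param c_iso Isotropic matrix modulus c, kPa.
#' @param c1 Fiber moduli, kPa: named or positional vector of length 3,
#'   order \code{(axial, circ, diag)}; the diagonal value applies to both
#'   diagonal families.
#' @param c2 Dimensionless fiber exponents, same layout as \code{c1}.
#' @param alpha0_deg Diagonal fiber angle from the axial direction,
#'   degrees, in (0, 90). Default 45.
#' @return An object of class \code{"four_fiber_params"}.
#' @seealso [strain_energy()], [circ_stress()], [vessel_preset()]
#' @export
four_fiber_params <- function(c_iso, c1 = c(0, 0, 0), c2 = c(0, 0, 0),
                              alpha0_deg = 45) {
  check_scalar(c_iso, "c_iso")
  check_scalar(alpha0_deg, "alpha0_deg")
  if (length(c1) != 3L || length(c2) != 3L) {
    stop_param("`c1` and `c2` must each have length 3 (axial, circ, diag)")
  }
  c1 <- as.numeric(c1); c2 <- as.numeric(c2)
  if (c_iso < 0 || any(c1 < 0) || any(c2 < 0)) {
    stop_param("all moduli and exponents must be >= 0")
  }
  if (alpha0_deg <= 0 || alpha0_deg >= 90) {
    stop_param("alpha0_deg must be in (0, 90)")
  }
  names(c1) <- names(c2) <- c("axial", "circ", "diag")
  structure(
    list(c_iso = c_iso, c1 = c1, c2 = c2, alpha0_deg = alpha0_deg),
    class = "four_fiber_params"
  )
}

# per-family sin^2(alpha) and multiplicity; diagonal pair counted twice
fiber_layout <- function(params) {
  a0 <- params$alpha0_deg * pi / 180
  list(sin2 = c(axial = 0, circ = 1, diag = sin(a0)^2),
       cos2 = c(axial = 1, circ = 0, diag = cos(a0)^2),
       mult = c(axial = 1, circ = 1, diag = 2))
}

#' Strain energy density of the four-fiber-family model
#'
#' Evaluates W (kPa) at circumferential stretch \code{lambda_theta} and
#' axial stretch \code{lambda_z}, with the radial stretch eliminated by
#' incompressibility. Zero at the reference state
#' \code{lambda_theta = lambda_z = 1}. Vectorized over
#' \code{lambda_theta}.
#'
#' @param params A [four_fiber_params()].
#' @param lambda_theta Circumferential stretch(es), > 0.
#' @param lambda_z Axial stretch, > 0.
#' @return Strain energy density, kPa.
#' @export
strain_energy <- function(params, lambda_theta, lambda_z = 1) {
  stopifnot(inherits(params, "four_fiber_params"))
  if (any(lambda_theta <= 0) || lambda_z <= 0) {
    stop_param("stretches must be > 0")
  }
  lt2 <- lambda_theta^2
  lz2 <- lambda_z^2
  w <- params$c_iso / 2 * (lt2 + lz2 + 1 / (lt2 * lz2) - 3)
  lay <- fiber_layout(params)
  for (k in c("axial", "circ", "diag")) {
    c1 <- params$c1[[k]]; c2 <- params$c2[[k]]
    if (c1 == 0) next
    e <- lt2 * lay$sin2[[k]] + lz2 * lay$cos2[[k]] - 1
    term <- if (c2 > 0) c1 / (4 * c2) * (exp(c2 * e^2) - 1) else c1 / 4 * e^2
    w <- w + lay$mult[[k]] * term
  }
  w
}

#' Circumferential Cauchy stress from the constitutive model
#'
#' \eqn{\sigma_\theta = \lambda_\theta \,\partial \hat W/\partial
#' \lambda_\theta} where \eqn{\hat W(\lambda_\theta, \lambda_z)} is the
#' strain energy with the radial stretch eliminated by incompressibility.
#' Analytic form:
#' \deqn{\sigma_\theta = c(\lambda_\theta^2 -
#'   \lambda_\theta^{-2}\lambda_z^{-2}) + \sum_k c_{1k}
#'   (\lambda_k^2 - 1) e^{c_{2k}(\lambda_k^2-1)^2}
#'   \lambda_\theta^2 \sin^2\alpha_k}
#' Zero at the reference state. Vectorized over \code{lambda_theta}.
#'
#' @inheritParams strain_energy
#' @return Circumferential Cauchy stress, kPa.
#' @export
circ_stress <- function(params, lambda_theta, lambda_z = 1) {
  stopifnot(inherits(params, "four_fiber_params"))
  if (any(lambda_theta <= 0) || lambda_z <= 0) {
    stop_param("stretches must be > 0")
  }
  lt2 <- lambda_theta^2
  lz2 <- lambda_z^2
  s <- params$c_iso * (lt2 - 1 / (lt2 * lz2))
  lay <- fiber_layout(params)
  for (k in c("axial", "circ", "diag")) {
    c1 <- params$c1[[k]]; c2 <- params$c2[[k]]; s2 <- lay$sin2[[k]]
    if (c1 == 0 || s2 == 0) next
    e <- lt2 * s2 + lz2 * lay$cos2[[k]] - 1
    s <- s + lay$mult[[k]] * c1 * e * exp(c2 * e^2) * lt2 * s2
  }
  s
}

# d(sigma_theta)/d(lambda_theta) at fixed lambda_z; analytic, vectorized
circ_stress_deriv <- function(params, lambda_theta, lambda_z = 1) {
  lt <- lambda_theta
  lt2 <- lt^2
  lz2 <- lambda_z^2
  d <- params$c_iso * (2 * lt + 2 / (lt^3 * lz2))
  lay <- fiber_layout(params)
  for (k in c("axial", "circ", "diag")) {
    c1 <- params$c1[[k]]; c2 <- params$c2[[k]]; s2 <- lay$sin2[[k]]
    if (c1 == 0 || s2 == 0) next
    e <- lt2 * s2 + lz2 * lay$cos2[[k]] - 1
    ex <- exp(c2 * e^2)
    d <- d + lay$mult[[k]] * c1 * s2 * ex *
      (2 * lt * e + 2 * lt^3 * s2 * (1 + 2 * c2 * e^2))
  }
  d
}

#' Deformed wall geometry under incompressible membrane kinematics
#'
#' Maps the mid-wall circumferential stretch to the loaded inner radius
#' and wall thickness, conserving wall cross-sectional area exactly:
#' with reference mid-wall radius \eqn{R_m = A + H/2} and outer radius
#' \eqn{B = A + H}, the loaded mid-wall radius is
#' \eqn{r_m = \lambda_\theta R_m}, and
#' \eqn{a = \sqrt{r_m^2 - (R_m^2 - A^2)/\lambda_z}},
#' \eqn{b = \sqrt{a^2 + (B^2 - A^2)/\lambda_z}}, \eqn{h = b - a}, so that
#' \eqn{(b^2 - a^2)\lambda_z = B^2 - A^2}.
#'
#' @param geom A [vessel_geometry()].
#' @param lambda_theta Mid-wall circumferential stretch(es).
#' @return A list with numeric elements \code{a} (inner radius, um),
#'   \code{b} (outer radius, um) and \code{h} (thickness, um), each the
#'   length of \code{lambda_theta}.
#' @export
deformed_geometry <- function(geom, lambda_theta) {
  stopifnot(inherits(geom, "vessel_geometry"))
  A <- geom$inner_radius
  B <- A + geom$thickness
  Rm <- A + geom$thickness / 2
  lz <- geom$axial_stretch
  a2 <- (lambda_theta * Rm)^2 - (Rm^2 - A^2) / lz
  if (any(a2 <= 0)) {
    stop_param(paste0("lambda_theta = %g is too small for a real inner ",
                      "radius (requires lambda_theta > %g)"),
               min(lambda_theta), sqrt((Rm^2 - A^2) / lz) / Rm)
  }
  a <- sqrt(a2)
  b <- sqrt(a2 + (B^2 - A^2) / lz)
  list(a = a, b = b, h = b - a)
}

#' Luminal pressure balancing a given circumferential stretch
#'
#' Thin-wall (Laplace) equilibrium closure: \eqn{P = \sigma_\theta h / a},
#' converted from kPa to mmHg (1 mmHg = 0.133322 kPa). Zero at the
#' reference state. Vectorized over \code{lambda_theta}.
#'
#' @param params A [four_fiber_params()].
#' @param geom A [vessel_geometry()].
#' @param lambda_theta Mid-wall circumferential stretch(es).
#' @return Equilibrium pressure(s), mmHg.
#' @export
equilibrium_pressure <- function(params, geom, lambda_theta) {
  def <- deformed_geometry(geom, lambda_theta)
  s <- circ_stress(params, lambda_theta, geom$axial_stretch)
  kpa_to_mmhg(s * def$h / def$a)
}

# dP/d(lambda_theta) in mmHg per unit stretch; analytic, vectorized
equilibrium_pressure_deriv <- function(params, geom, lambda_theta) {
  A <- geom$inner_radius
  Rm <- A + geom$thickness / 2
  lz <- geom$axial_stretch
  def <- deformed_geometry(geom, lambda_theta)
  a <- def$a; b <- def$b; h <- def$h
  s <- circ_stress(params, lambda_theta, lz)
  ds <- circ_stress_deriv(params, lambda_theta, lz)
  da <- lambda_theta * Rm^2 / a
  db <- (a / b) * da
  dh <- db - da
  kpa_to_mmhg(ds * h / a + s * (dh * a - h * da) / a^2)
}

# Vectorized safeguarded-Newton solve of equilibrium_pressure(l) = p for
# each target pressure. Relies on P being increasing in lambda_theta over
# the bracket; a bisection fallback keeps every iterate inside a sign-
# changing bracket so convergence is guaranteed for reachable pressures.
solve_circ_stretch <- function(params, geom, pressures,
                               lambda_max = 2.5, tol = 1e-10) {
  A <- geom$inner_radius
  Rm <- A + geom$thickness / 2
  lz <- geom$axial_stretch
  lo_bound <- sqrt(max((Rm^2 - A^2) / lz, 0)) / Rm
  lo0 <- max(lo_bound * (1 + 1e-9) + 1e-12, 1e-6)

  p_hi <- equilibrium_pressure(params, geom, lambda_max)
  if (any(pressures > p_hi)) {
    bad <- which(pressures > p_hi)[1]
    stop_param(paste0("pressure %.6g mmHg exceeds the model's reachable ",
                      "range (%.6g mmHg at lambda_theta = %g); ",
                      "no root in bracket [%g, %g]"),
               pressures[bad], p_hi, lambda_max, lo0, lambda_max)
  }

  n <- length(pressures)
  lo <- rep(lo0, n)
  hi <- rep(lambda_max, n)
  x <- pmin(pmax(rep(1.05, n), lo), hi)
  f <- equilibrium_pressure(params, geom, x) - pressures
  dxold <- hi - lo
  active <- rep(TRUE, n)
  for (iter in seq_len(200)) {
    if (!any(active)) break
    xa <- x[active]
    fa <- f[active]
    dfa <- equilibrium_pressure_deriv(params, geom, xa)
    step <- fa / dfa
    xn <- xa - step
    # bisect where Newton leaves the bracket or fails to halve the
    # previous step (guards against crawling down steep exponentials)
    bad <- !is.finite(xn) | xn <= lo[active] | xn >= hi[active] |
      abs(step) > 0.5 * abs(dxold[active])
    xn[bad] <- (lo[active][bad] + hi[active][bad]) / 2
    fn <- equilibrium_pressure(params, geom, xn) - pressures[active]
    below <- fn < 0
    lo[active][below] <- xn[below]
    hi[active][!below] <- xn[!below]
    conv <- abs(xn - xa) < tol | abs(fn) < 1e-9
    dxold[active] <- abs(xn - xa)
    x[active] <- xn
    f[active] <- fn
    active[active] <- !conv
  }
  if (any(active)) {
    stop_param("stretch solve failed to converge for %d pressure(s)",
               sum(active))
  }
  x
}

#' Loaded states along the pressure-diameter curve
#'
#' For each pressure, solves the thin-wall equilibrium
#' \eqn{P(\lambda_\theta) = P} for the mid-wall stretch by safeguarded
#' Newton iteration on \eqn{[\lambda_{lo}, \lambda_{max}]} (tolerance
#' 1e-10 on the stretch; residual below 1e-6 mmHg), then reports the full
#' loaded state.
#'
#' @param params A [four_fiber_params()].
#' @param geom A [vessel_geometry()].
#' @param pressures Target pressures, mmHg, non-negative and sorted
#'   non-decreasing.
#' @param lambda_max Upper stretch bracket (default 2.5); pressures whose
#'   equilibrium lies beyond it raise a convergence error naming the
#'   bracket.
#' @return A tibble with one row per pressure: \code{pressure_mmhg},
#'   \code{lambda_theta}, \code{inner_radius_um}, \code{thickness_um},
#'   \code{outer_diameter_um}, \code{inner_diameter_um},
#'   \code{circ_stress_kpa}.
#' @examples
#' pre <- vessel_preset("compliant")
#' pressure_diameter_curve(pre$params, pre$geometry, c(0, 40, 80, 120))
#' @export
pressure_diameter_curve <- function(params, geom, pressures,
                                    lambda_max = 2.5) {
  stopifnot(inherits(params, "four_fiber_params"),
            inherits(geom, "vessel_geometry"))
  pressures <- as.numeric(pressures)
  if (any(pressures < 0)) stop_param("pressures must be >= 0")
  if (is.unsorted(pressures)) stop_param("pressures must be sorted ascending")
  lt <- solve_circ_stretch(params, geom, pressures, lambda_max)
  def <- deformed_geometry(geom, lt)
  tibble::tibble(
    pressure_mmhg = pressures,
    lambda_theta = lt,
    inner_radius_um = def$a,
    thickness_um = def$h,
    outer_diameter_um = 2 * def$b,
    inner_diameter_um = 2 * def$a,
    circ_stress_kpa = circ_stress(params, lt, geom$axial_stretch)
  )
}

#' Rupture criterion
#'
#' A loaded state ruptures when its circumferential wall stress reaches
#' the failure stress; the boundary is inclusive
#' (\code{stress == sigma_fail} ruptures).
#'
#' @param circ_stress_kpa Circumferential wall stress(es), kPa.
#' @param sigma_fail Failure stress, kPa, > 0.
#' @return Logical vector, \code{TRUE} where the wall fails.
#' @export
rupture_check <- function(circ_stress_kpa, sigma_fail) {
  check_scalar(sigma_fail, "sigma_fail")
  if (sigma_fail <= 0) stop_param("sigma_fail must be > 0")
  circ_stress_kpa >= sigma_fail
}
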