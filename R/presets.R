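#' Shipped vessel parameter presets
#'
#' Two documented calibration presets for the four-fiber-family wall
#' model, sharing one carotid-like unloaded geometry (inner radius 200 um,
#' wall 40 um, axial stretch 1):
#'
#' \describe{
#'   \item{\code{"compliant"}}{normotensive-like wall: low fiber
#'     exponents give an extended elastin-dominated toe region, large
#'     distension over the 80-120 mmHg physiological band, and a
#'     pressure-diameter curve that plateaus near 200 mmHg.}
#'   \item{\code{"stiff"}}{remodeled/crosslinked-like wall: high fiber
#'     exponents engage collagen early, so the curve plateaus near
#'     125 mmHg with much smaller pulsatile distension.}
#' }
#'
#' The parameter values are calibration choices of this package (tuned to
#' those qualitative plateau/compliance contrasts), not measurements of
#' any particular vessel.
#'
#' @param name \code{"compliant"} or \code{"stiff"}.
#' @return A list with elements \code{params} ([four_fiber_params()]) and
#'   \code{geometry} ([vessel_geometry()]).
#' @examples
#' pre <- vessel_preset("stiff")
#' pressure_diameter_curve(pre$params, pre$geometry, c(0, 80, 120))
#' @export
vessel_preset <- function(name = c("compliant", "stiff")) {
  name <- match.arg(name)
  geom <- vessel_geometry(inner_radius = 200, thickness = 40,
                          axial_stretch = 1)
  params <- switch(
    name,
    compliant = four_fiber_params(
      c_iso = 30,
      c1 = c(axial = 5, circ = 5, diag = 5),
      c2 = c(axial = 0.1, circ = 0.1, diag = 0.1),
      alpha0_deg = 45
    ),
    stiff = four_fiber_params(
      c_iso = 40,
      c1 = c(axial = 20, circ = 20, diag = 20),
      c2 = c(axial = 16, circ = 16, diag = 16),
      alpha0_deg = 45
    )
  )
  list(params = params, geometry = geom)
}
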