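#' Render a synthetic vessel frame
#'
#' Draws an idealized grayscale frame of a cannulated vessel lying
#' horizontally and centered vertically: two dark wall bands of width
#' (OD - ID)/2 separated by a brighter lumen band of width ID, on a
#' bright background, plus additive Gaussian pixel noise. Used as ground
#' truth for validating the diameter tracker.
#'
#' @param od_um,id_um True outer and inner diameter, um (OD > ID > 0).
#' @param um_per_px Spatial calibration, micrometres per pixel.
#' @param image_size Frame size in pixels as \code{c(height, width)}
#'   (rows, columns); the vessel must fit inside the height.
#' @param wall_intensity,lumen_intensity,background_intensity Gray levels
#'   in [0, 1]; walls dark, lumen intermediate, background bright.
#' @param noise_sd Gaussian pixel-noise SD (intensity units).
#' @param seed Integer seed for the noise (NULL uses the ambient RNG).
#' @return A numeric matrix in [0, 1] (rows = image height, origin at the
#'   top-left), suitable for [track_frame()] or \code{png::writePNG}.
#' @examples
#' img <- render_vessel_frame(800, 400, um_per_px = 2,
#'                            image_size = c(512, 128))
#' @export
render_vessel_frame <- function(od_um, id_um, um_per_px,
                                image_size = c(512, 256),
                                wall_intensity = 0.15,
                                lumen_intensity = 0.65,
                                background_intensity = 0.9,
                                noise_sd = 0, seed = NULL) {
  check_scalar(od_um, "od_um"); check_scalar(id_um, "id_um")
  check_scalar(um_per_px, "um_per_px")
  if (!(od_um > id_um && id_um > 0)) stop_param("need od_um > id_um > 0")
  if (um_per_px <= 0) stop_param("um_per_px must be > 0")
  if (length(image_size) != 2 || any(image_size < 4)) {
    stop_param("image_size must be c(height, width) in pixels")
  }
  h <- as.integer(image_size[1]); w <- as.integer(image_size[2])
  if (od_um / um_per_px >= h) {
    stop_param("vessel (%g um = %g px) does not fit in frame height %d px",
               od_um, od_um / um_per_px, h)
  }
  yc <- (h + 1) / 2
  od2 <- od_um / um_per_px / 2
  id2 <- id_um / um_per_px / 2
  # analytic anti-aliasing: each pixel row integrates the piecewise-
  # constant intensity over its 1-px extent, so band edges land at their
  # exact sub-pixel positions
  y <- seq_len(h)
  band_cover <- function(r) {
    pmax(0, pmin(y + 0.5, yc + r) - pmax(y - 0.5, yc - r))
  }
  cover_od <- band_cover(od2)
  cover_id <- band_cover(id2)
  col_profile <- background_intensity * (1 - cover_od) +
    wall_intensity * (cover_od - cover_id) +
    lumen_intensity * cover_id
  img <- matrix(col_profile, nrow = h, ncol = w)
  if (noise_sd > 0) {
    img <- img + with_seed_if(seed, matrix(rnorm(h * w, 0, noise_sd), h, w))
  }
  pmin(pmax(img, 0), 1)
}
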