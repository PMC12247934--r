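#' Diameter-tracking configuration
#'
#' Settings for scanline intensity-profile edge tracking of a roughly
#' horizontal vessel in a grayscale frame.
#'
#' @param um_per_px Spatial calibration, micrometres per pixel (required;
#'   optical calibration is a user input).
#' @param n_scanlines Number of equally spaced vertical scanlines
#'   (>= 1, default 15).
#' @param smoothing_window Moving-average window applied to each profile,
#'   px, odd, >= 1 (default 5).
#' @param gradient_threshold Minimum edge strength as a fraction of the
#'   strongest gradient on the profile, in (0, 1] (default 0.3).
#' @param outlier_mad_factor Scanlines whose outer-diameter estimate
#'   deviates from the cross-scanline median by more than this many MADs
#'   are excluded (default 3).
#' @return An object of class \code{"tracking_config"}.
#' @export
tracking_config <- function(um_per_px, n_scanlines = 15,
                            smoothing_window = 5, gradient_threshold = 0.3,
                            outlier_mad_factor = 3) {
  check_scalar(um_per_px, "um_per_px")
  if (um_per_px <= 0) stop_param("um_per_px must be > 0")
  if (n_scanlines < 1) stop_param("n_scanlines must be >= 1")
  if (smoothing_window < 1 || smoothing_window %% 2 != 1) {
    stop_param("smoothing_window must be odd and >= 1")
  }
  if (gradient_threshold <= 0 || gradient_threshold > 1) {
    stop_param("gradient_threshold must be in (0, 1]")
  }
  structure(
    list(um_per_px = um_per_px, n_scanlines = as.integer(n_scanlines),
         smoothing_window = as.integer(smoothing_window),
         gradient_threshold = gradient_threshold,
         outlier_mad_factor = outlier_mad_factor),
    class = "tracking_config"
  )
}

# sub-pixel gradient extremum location by parabolic fit over 3 samples;
# i indexes diff(profile), whose sample i sits at pixel coordinate i + 0.5
refine_extremum <- function(g, i) {
  if (i <= 1 || i >= length(g)) return(i + 0.5)
  denom <- g[i - 1] - 2 * g[i] + g[i + 1]
  delta <- if (abs(denom) > 1e-12) 0.5 * (g[i - 1] - g[i + 1]) / denom else 0
  i + 0.5 + max(min(delta, 0.5), -0.5)
}

# locate the 4 wall edges on one vertical intensity profile; returns
# c(outer_top, inner_top, inner_bottom, outer_bottom) in px or NULL
scan_profile_edges <- function(profile, cfg) {
  w <- cfg$smoothing_window
  sm <- if (w > 1) {
    as.numeric(stats::filter(profile, rep(1 / w, w), sides = 2))
  } else profile
  g <- diff(sm)
  ok <- which(!is.na(g))
  if (length(ok) < 5) return(NULL)
  gmax <- max(abs(g[ok]))
  if (gmax <= 0) return(NULL)
  thr <- cfg$gradient_threshold * gmax
  # threshold-exceeding samples clustered by proximity (one cluster per
  # edge); each cluster's candidate is the centroid of its |g|-weighted
  # span, robust to near-flat gradient plateaus from boxcar smoothing
  cluster <- function(ii) {
    if (length(ii) == 0) return(integer(0))
    run <- cumsum(c(1, diff(ii) > cfg$smoothing_window))
    as.integer(round(tapply(ii, run, function(x) {
      wgt <- abs(g[x])
      sum(x * wgt) / sum(wgt)
    })))
  }
  pos_i <- cluster(ok[g[ok] >= thr])
  neg_i <- cluster(ok[g[ok] <= -thr])
  if (length(pos_i) < 2 || length(neg_i) < 2) return(NULL)
  neg2 <- neg_i[order(g[neg_i])][1:2]              # strongest dark-going
  pos2 <- pos_i[order(-g[pos_i])][1:2]             # strongest bright-going
  cand <- sort(c(neg2, pos2))
  signs <- sign(g[cand])
  # top-to-bottom a bright->dark->brighter->dark->bright tube: -, +, -, +
  if (!identical(signs, c(-1, 1, -1, 1))) return(NULL)
  vapply(cand, function(i) refine_extremum(g, i), numeric(1))
}

#' Track vessel diameters on a single frame
#'
#' Estimates outer and inner diameter by scanline edge detection: on each
#' of \code{n_scanlines} equally spaced vertical intensity profiles, the
#' profile is smoothed, differenced, and the four strongest
#' alternating-sign gradient extrema (ordered top to bottom:
#' outer-top, inner-top, inner-bottom, outer-bottom) are located with
#' sub-pixel parabolic refinement. The frame estimate is the median
#' across scanlines after MAD-based outlier exclusion. If more than half
#' the scanlines fail to produce a valid edge set the frame is flagged as
#' a tracking failure and no value is fabricated.
#'
#' @param image Numeric matrix (grayscale, rows = image height, vessel
#'   roughly horizontal).
#' @param cfg A [tracking_config()].
#' @return A list: \code{od_um}, \code{id_um} (NA on failure), \code{ok}
#'   (logical), \code{n_scanlines_used}.
#' @examples
#' img <- render_vessel_frame(800, 400, 2, c(512, 128))
#' track_frame(img, tracking_config(um_per_px = 2))
#' @export
track_frame <- function(image, cfg) {
  stopifnot(inherits(cfg, "tracking_config"))
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_param("`image` must be a 2-D numeric grayscale matrix")
  }
  cols <- unique(round(seq(1, ncol(image), length.out = cfg$n_scanlines + 2)))
  cols <- cols[cols > 0]
  if (length(cols) > 2) cols <- cols[-c(1, length(cols))]
  edges <- lapply(cols, function(j) scan_profile_edges(image[, j], cfg))
  valid <- !vapply(edges, is.null, logical(1))
  if (sum(valid) < length(cols) / 2 || sum(valid) == 0) {
    return(list(od_um = NA_real_, id_um = NA_real_, ok = FALSE,
                n_scanlines_used = 0L))
  }
  e <- do.call(rbind, edges[valid])
  od_px <- e[, 4] - e[, 1]
  id_px <- e[, 3] - e[, 2]
  med <- median(od_px)
  dev <- abs(od_px - med)
  madv <- mad(od_px)
  keep <- if (madv > 0) dev <= cfg$outlier_mad_factor * madv else rep(TRUE, length(od_px))
  list(od_um = median(od_px[keep]) * cfg$um_per_px,
       id_um = median(id_px[keep]) * cfg$um_per_px,
       ok = TRUE, n_scanlines_used = sum(keep))
}

#' Track vessel diameters across a video
#'
#' Applies [track_frame()] independently to each frame (no temporal
#' smoothing), assembling a diameter trace on the grid
#' \code{time = (frame index - 1) / frame_rate}. Failed frames carry
#' \code{ok = FALSE} with missing diameters and should be excluded from
#' downstream statistics.
#'
#' @param frames A list of grayscale matrices (or a single matrix).
#' @param frame_rate Acquisition rate, frames per second.
#' @param cfg A [tracking_config()].
#' @return A tibble with columns \code{time_s}, \code{outer_diameter_um},
#'   \code{inner_diameter_um}, \code{ok}.
#' @export
track_video <- function(frames, frame_rate, cfg) {
  if (is.matrix(frames)) frames <- list(frames)
  if (length(frames) < 1) stop_param("need at least one frame")
  check_scalar(frame_rate, "frame_rate")
  if (frame_rate <= 0) stop_param("frame_rate must be > 0")
  res <- lapply(frames, track_frame, cfg = cfg)
  out <- tibble::tibble(
    time_s = (seq_along(frames) - 1) / frame_rate,
    outer_diameter_um = vapply(res, `[[`, numeric(1), "od_um"),
    inner_diameter_um = vapply(res, `[[`, numeric(1), "id_um"),
    ok = vapply(res, `[[`, logical(1), "ok")
  )
  if (!any(out$ok)) {
    stop_param("tracking failed on every frame; no usable trace")
  }
  out
}

#' Read a directory of numbered PNG frames
#'
#' Loads \code{*.png} files in lexicographic order and converts each to a
#' grayscale matrix (averaging channels if RGB).
#'
#' @param dir Directory containing the frames.
#' @return A list of numeric matrices.
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop_param("no .png frames found in %s", dir)
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
    img
  })
}
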