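#' Micromanipulator travel calibration table
#'
#' Reported per-axis linear travel of the 3D-printed three-axis
#' micromanipulator used to cannulate vessels: mean travel per full and
#' per quarter turn of each M6 leadscrew (1 mm nominal pitch), as shipped
#' in \code{inst/extdata/micromanipulator_travel.csv}.
#'
#' @return A tibble with columns \code{axis}, \code{full_turn_mm},
#'   \code{quarter_turn_mm}.
#' @examples
#' mean(micromanipulator_travel()$full_turn_mm)
#' @export
micromanipulator_travel <- function() {
  path <- system.file("extdata", "micromanipulator_travel.csv",
                      package = "vasomyo", mustWork = TRUE)
  tibble::as_tibble(read.csv(path))
}
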