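#' Screen and sampling configuration
#'
#' Describes the presentation display and the eye tracker's nominal sampling
#' rate. The default mirrors the experimental setup the package targets: a
#' 1920 x 1080 display sampled at 60 Hz, with 37 pixels per degree of visual
#' angle.
#'
#' @param width_px,height_px screen size in pixels.
#' @param sampling_rate_hz nominal gaze sampling rate (samples per second).
#' @param px_per_degree pixels subtending one degree of visual angle.
#' @return An object of class `screen_config`.
#' @export
#' @examples
#' screen_config()
screen_config <- function(width_px = 1920L, height_px = 1080L,
                          sampling_rate_hz = 60, px_per_degree = 37) {
  stopifnot(width_px > 0, height_px > 0, sampling_rate_hz > 0,
            px_per_degree > 0)
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         px_per_degree = as.numeric(px_per_degree)),
    class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat(sprintf("<screen_config> %d x %d px, %.6g Hz, %.6g px/degree\n",
              x$width_px, x$height_px, x$sampling_rate_hz, x$px_per_degree))
  invisible(x)
}

#' Fixation detector configuration
#'
#' Parameters of the lead-sample dispersion detector: a fixation is a maximal
#' run of consecutive retained samples each no farther than `dispersion_px`
#' (Euclidean, inclusive) from the run's first sample (the *lead*), with at
#' least `min_samples` members. At the default 60 Hz and `min_samples = 3`
#' the minimal fixation duration is 50 ms.
#'
#' `max_gap_ms` closes a run when the time between consecutive retained
#' samples exceeds it; the default of two nominal sampling intervals means a
#' single dropped sample does not break a fixation but two or more do.
#'
#' @param dispersion_px inclusive distance threshold to the lead sample, px.
#' @param min_samples minimal number of samples per fixation.
#' @param sampling_rate_hz nominal sampling rate used to convert sample
#'   counts to durations.
#' @param max_gap_ms largest tolerated time gap (ms) between consecutive
#'   retained samples within one fixation.
#' @return An object of class `detector_config`.
#' @export
#' @examples
#' detector_config()
detector_config <- function(dispersion_px = 37, min_samples = 3L,
                            sampling_rate_hz = 60,
                            max_gap_ms = 2 * 1000 / sampling_rate_hz) {
  stopifnot(dispersion_px > 0, min_samples >= 1, sampling_rate_hz > 0,
            max_gap_ms > 0)
  structure(
    list(dispersion_px = as.numeric(dispersion_px),
         min_samples = as.integer(min_samples),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         max_gap_ms = as.numeric(max_gap_ms)),
    class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  cat(sprintf(
    "<detector_config> dispersion %.6g px, min %d samples @ %.6g Hz (min duration %.4g ms)\n",
    x$dispersion_px, x$min_samples, x$sampling_rate_hz,
    x$min_samples * 1000 / x$sampling_rate_hz))
  invisible(x)
}

#' Areas of interest
#'
#' An AOI set is a data frame with columns `name, x0, y0, x1, y1`; rectangles
#' are half-open (`x0 <= x < x1`, `y0 <= y < y1`), must lie within the screen
#' and must be pairwise disjoint. Overlap is an error at configuration time
#' because downstream metrics assume a gaze sample belongs to at most one
#' AOI.
#'
#' @param rects data frame with columns `name, x0, y0, x1, y1` (pixels).
#' @param screen a [screen_config()] used for the bounds check.
#' @return The validated data frame with class `aoi_set` prepended.
#' @export
#' @examples
#' default_aois()
aoi_set <- function(rects, screen = screen_config()) {
  stopifnot(is.data.frame(rects),
            all(c("name", "x0", "y0", "x1", "y1") %in% names(rects)))
  if (anyDuplicated(rects$name)) stop("duplicated AOI names")
  if (any(rects$x0 >= rects$x1) || any(rects$y0 >= rects$y1))
    stop("degenerate AOI rectangle (x0 >= x1 or y0 >= y1)")
  if (any(rects$x0 < 0) || any(rects$y0 < 0) ||
      any(rects$x1 > screen$width_px) || any(rects$y1 > screen$height_px))
    stop("AOI rectangle outside screen bounds")
  n <- nrow(rects)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (rects$x0[i] < rects$x1[j] && rects$x0[j] < rects$x1[i] &&
          rects$y0[i] < rects$y1[j] && rects$y0[j] < rects$y1[i])
        stop(sprintf("AOIs '%s' and '%s' overlap", rects$name[i],
                     rects$name[j]))
    }
  }
  class(rects) <- c("aoi_set", "data.frame")
  rects
}

#' @rdname aoi_set
#' @details `default_aois()` returns the package default geometry: the left
#' and right stimulus halves (860 px wide each) separated by a 200 px central
#' column that contains the fixation-cross AOI (200 x 200 px around the
#' screen centre). The three rectangles are disjoint by construction; the
#' narrow bands above and below the cross belong to no AOI.
#' @export
default_aois <- function(screen = screen_config()) {
  w <- screen$width_px; h <- screen$height_px
  cw <- 200; ch <- 200                     # central column / cross extent
  xl <- (w - cw) / 2                       # 860 on a 1920 px screen
  aoi_set(data.frame(
    name = c("left", "right", "cross"),
    x0 = c(0, xl + cw, xl),
    y0 = c(0, 0, (h - ch) / 2),
    x1 = c(xl, w, xl + cw),
    y1 = c(h, h, (h + ch) / 2),
    stringsAsFactors = FALSE), screen = screen)
}

# canonical factor levels used throughout
.animal_levels <- c("spider", "scorpion", "grasshopper")
.pair_type_levels <- c("spider-grasshopper", "scorpion-grasshopper",
                       "scorpion-spider")
.nationality_levels <- c("Somali", "Czech")
.gender_levels <- c("woman", "man")

# first/second-named animal of a pair type (difference sign convention:
# first minus second, i.e. spider-grasshopper, scorpion-grasshopper,
# scorpion-spider)
.pair_first <- c("spider-grasshopper" = "spider",
                 "scorpion-grasshopper" = "scorpion",
                 "scorpion-spider" = "scorpion")
.pair_second <- c("spider-grasshopper" = "grasshopper",
                  "scorpion-grasshopper" = "grasshopper",
                  "scorpion-spider" = "spider")

.pair_type_of <- function(cat_a, cat_b) {
  key <- paste(sort(c(cat_a, cat_b)), collapse = "+")
  switch(key,
         "grasshopper+spider" = "spider-grasshopper",
         "grasshopper+scorpion" = "scorpion-grasshopper",
         "scorpion+spider" = "scorpion-spider",
         stop("images of categories '", cat_a, "' and '", cat_b,
              "' do not form a valid pair"))
}
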