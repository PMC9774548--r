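#' Assign fixations to areas of interest
#'
#' A fixation is assigned to every AOI that contains at least one of its
#' member samples (half-open rectangles). A fixation whose samples straddle
#' an AOI border therefore accrues its full duration to each touched AOI —
#' which is why combined per-AOI fixation time can exceed the slide duration
#' and is screened downstream by the curation rules. Samples outside all
#' AOIs contribute no assignment.
#'
#' @param fixations a `fixations` data frame from [detect_fixations()].
#' @param aois an [aoi_set()].
#' @param stream the retained sample stream the fixation indices refer to
#'   (list/data frame with `x`, `y`).
#' @return A list (one element per fixation) of character vectors of AOI
#'   names; possibly empty.
#' @export
assign_fixation_aois <- function(fixations, aois, stream) {
  stopifnot(inherits(aois, "aoi_set"))
  gx <- as.numeric(stream$x); gy <- as.numeric(stream$y)
  lapply(seq_len(nrow(fixations)), function(k) {
    idx <- fixations$start_index[k]:fixations$end_index[k]
    hit <- vapply(seq_len(nrow(aois)), function(a)
      any(gx[idx] >= aois$x0[a] & gx[idx] < aois$x1[a] &
            gy[idx] >= aois$y0[a] & gy[idx] < aois$y1[a]), TRUE)
    aois$name[hit]
  })
}

#' Compute per-trial AOI metrics
#'
#' Runs fixation detection on the mean-binocular stream of a recording and
#' aggregates the exported variables per AOI: number of fixations, total
#' fixation time, and the durations of the first, second and third fixation
#' assigned to that AOI (in time order, `NA` when fewer exist).
#' `n_sample_measurements` is the number of retained samples in the whole
#' trial and is repeated on each AOI row.
#'
#' @param rec a `trial_recording`.
#' @param detector a [detector_config()].
#' @param aois an [aoi_set()].
#' @return A data frame with one row per AOI, columns
#'   `participant_id, slide_id, aoi, n_fixations, fixation_time_ms,
#'   first_ms, second_ms, third_ms, n_sample_measurements`.
#' @export
#' @examples
#' t <- (0:299) * 1000 / 60
#' rec <- trial_recording("p1", "s1", t, rep(1400, 300), rep(540, 300),
#'                        rep(1402, 300), rep(540, 300))
#' compute_trial_metrics(rec)
compute_trial_metrics <- function(rec, detector = detector_config(),
                                  aois = default_aois()) {
  keep <- !is.na(rec$samples$mx)
  stream <- list(t = rec$samples$t[keep], x = rec$samples$mx[keep],
                 y = rec$samples$my[keep])
  fx <- detect_fixations(stream, detector)
  n_aoi <- nrow(aois)
  nf <- nrow(fx)
  n_fix <- integer(n_aoi); tot <- numeric(n_aoi)
  f1 <- rep(NA_real_, n_aoi); f2 <- f1; f3 <- f1
  if (nf) {
    # per-sample AOI membership, then per-fixation "any member inside"
    # via cumulative counts over the member index range
    gx <- stream$x; gy <- stream$y
    for (a in seq_len(n_aoi)) {
      inside <- gx >= aois$x0[a] & gx < aois$x1[a] &
        gy >= aois$y0[a] & gy < aois$y1[a]
      cs <- c(0, cumsum(inside))
      hit <- cs[fx$end_index + 1L] - cs[fx$start_index] > 0
      d <- fx$duration_ms[hit]
      n_fix[a] <- length(d)
      if (length(d)) {
        tot[a] <- sum(d)
        f1[a] <- d[1L]
        if (length(d) >= 2L) f2[a] <- d[2L]
        if (length(d) >= 3L) f3[a] <- d[3L]
      }
    }
  }
  .fast_df(list(
    participant_id = rep(rec$participant_id, n_aoi),
    slide_id = rep(rec$slide_id, n_aoi),
    aoi = aois$name, n_fixations = n_fix, fixation_time_ms = tot,
    first_ms = f1, second_ms = f2, third_ms = f3,
    n_sample_measurements = rep(sum(keep), n_aoi)))
}

#' Compute AOI metrics for a whole cohort
#'
#' Applies [compute_trial_metrics()] to each recording and binds the rows.
#'
#' @param recordings list of `trial_recording` objects.
#' @inheritParams compute_trial_metrics
#' @return The stacked metrics data frame (one row per trial x AOI).
#' @export
compute_cohort_metrics <- function(recordings, detector = detector_config(),
                                   aois = default_aois()) {
  parts <- lapply(recordings, compute_trial_metrics, detector = detector,
                  aois = aois)
  .fast_df(lapply(setNames(nm = names(parts[[1]])), function(col)
    unlist(lapply(parts, `[[`, col), use.names = FALSE)))
}
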