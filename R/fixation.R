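#' Detect fixations with the lead-sample dispersion rule
#'
#' Segments a time-ordered gaze sample stream into fixations using a greedy
#' single pass. The first sample is the *lead* of the first candidate run;
#' each subsequent sample joins the current run if and only if its Euclidean
#' distance to the current lead is at most `cfg$dispersion_px` (inclusive)
#' and the time gap to the previous retained sample does not exceed
#' `cfg$max_gap_ms`. A sample that fails either condition always becomes the
#' new lead; the closed run is emitted as a fixation when it has at least
#' `cfg$min_samples` members, and discarded otherwise (its samples are not
#' revisited). Fixation duration is `n_samples * 1000 / sampling_rate_hz`,
#' so at 60 Hz the minimal 3-sample fixation lasts 50 ms.
#'
#' Unlike classical dispersion (I-DT) detection, the distance criterion is
#' referenced to the lead sample, not to the pairwise spread of the run.
#'
#' @param x a `trial_recording` (its mean-binocular stream is used, missing
#'   samples dropped), or a data frame / list with numeric elements `t`, `x`,
#'   `y` already free of missing samples.
#' @param cfg a [detector_config()].
#' @return A data frame of class `fixations` with one row per fixation:
#'   `fix_index, lead_index, start_index, end_index, start_t, end_t,
#'   n_samples, duration_ms, cx, cy`. Indices refer to the retained stream
#'   passed in. An empty stream yields zero rows.
#' @export
#' @examples
#' t <- (0:299) * 1000 / 60
#' detect_fixations(list(t = t, x = rep(960, 300), y = rep(540, 300)))
detect_fixations <- function(x, cfg = detector_config()) {
  s <- .as_stream(x)
  t <- s$t; gx <- s$x; gy <- s$y
  n <- length(t)
  empty <- data.frame(fix_index = integer(), lead_index = integer(),
                      start_index = integer(), end_index = integer(),
                      start_t = numeric(), end_t = numeric(),
                      n_samples = integer(), duration_ms = numeric(),
                      cx = numeric(), cy = numeric())
  class(empty) <- c("fixations", "data.frame")
  if (n == 0L) return(empty)
  if (anyNA(t) || anyNA(gx) || anyNA(gy))
    stop("missing values in gaze stream; drop missing samples upstream")
  if (n > 1L && any(diff(t) <= 0))
    stop("gaze stream is not strictly increasing in time")

  disp2 <- cfg$dispersion_px^2
  max_gap <- cfg$max_gap_ms * (1 + 1e-9)
  dur_per_sample <- 1000 / cfg$sampling_rate_hz

  leads <- integer(n); ends <- integer(n); nfix <- 0L
  lead <- 1L; lx <- gx[1L]; ly <- gy[1L]
  if (n > 1L) for (i in 2:n) {
    dx <- gx[i] - lx; dy <- gy[i] - ly
    if (t[i] - t[i - 1L] > max_gap || dx * dx + dy * dy > disp2) {
      if (i - lead >= cfg$min_samples) {
        nfix <- nfix + 1L; leads[nfix] <- lead; ends[nfix] <- i - 1L
      }
      lead <- i; lx <- gx[i]; ly <- gy[i]
    }
  }
  if (n - lead + 1L >= cfg$min_samples) {
    nfix <- nfix + 1L; leads[nfix] <- lead; ends[nfix] <- n
  }
  if (nfix == 0L) return(empty)
  leads <- leads[seq_len(nfix)]; ends <- ends[seq_len(nfix)]
  ns <- ends - leads + 1L
  cx <- vapply(seq_len(nfix), function(k) mean(gx[leads[k]:ends[k]]), 0)
  cy <- vapply(seq_len(nfix), function(k) mean(gy[leads[k]:ends[k]]), 0)
  out <- data.frame(fix_index = seq_len(nfix), lead_index = leads,
                    start_index = leads, end_index = ends,
                    start_t = t[leads], end_t = t[ends], n_samples = ns,
                    duration_ms = ns * dur_per_sample, cx = cx, cy = cy)
  class(out) <- c("fixations", "data.frame")
  out
}

.as_stream <- function(x) {
  if (inherits(x, "trial_recording")) {
    keep <- !is.na(x$samples$mx)
    return(list(t = x$samples$t[keep], x = x$samples$mx[keep],
                y = x$samples$my[keep]))
  }
  if (is.list(x) && all(c("t", "x", "y") %in% names(x)))
    return(list(t = as.numeric(x$t), x = as.numeric(x$x),
                y = as.numeric(x$y)))
  stop("cannot interpret 'x' as a gaze stream (need t, x, y)")
}

#' Summarise an ordered fixation sequence
#'
#' Returns the trial-level fixation variables: number of fixations, total
#' fixation time, and the durations of the first, second and third fixation
#' (`NA` when fewer exist).
#'
#' @param fixations a `fixations` data frame from [detect_fixations()] (or
#'   any data frame with a `duration_ms` column in time order).
#' @return A list with elements `n_fixations`, `total_duration_ms`,
#'   `first_ms`, `second_ms`, `third_ms`.
#' @export
fixation_sequence_summary <- function(fixations) {
  d <- fixations$duration_ms
  nth <- function(k) if (length(d) >= k) d[k] else NA_real_
  list(n_fixations = length(d),
       total_duration_ms = if (length(d)) sum(d) else 0,
       first_ms = nth(1L), second_ms = nth(2L), third_ms = nth(3L))
}
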