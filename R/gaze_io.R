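#' Construct a trial recording
#'
#' A trial recording is the gaze sample stream of one participant viewing
#' one slide: per sample the time from slide onset (ms), the left- and
#' right-eye screen coordinates (px, top-left origin, x rightward, y
#' downward; `NA` = eye not tracked) and the derived mean-binocular
#' coordinate. When only one eye is present the mean falls back to that eye;
#' when neither is present the sample is retained as missing.
#'
#' @param participant_id,slide_id identifiers.
#' @param t numeric times in ms from slide onset, strictly increasing.
#' @param lx,ly,rx,ry per-eye coordinates (px), `NA` where untracked.
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(participant_id, slide_id, t, lx, ly, rx, ry) {
  n <- length(t)
  stopifnot(length(lx) == n, length(ly) == n, length(rx) == n,
            length(ry) == n)
  if (n && any(t < 0)) stop("negative timestamps")
  if (n > 1 && any(diff(t) <= 0))
    stop("timestamps must be strictly increasing within a trial")
  if (any(is.na(lx) != is.na(ly)) || any(is.na(rx) != is.na(ry)))
    stop("x/y of one eye must be both present or both missing")
  mx <- ifelse(!is.na(lx) & !is.na(rx), (lx + rx) / 2,
               ifelse(!is.na(lx), lx, rx))
  my <- ifelse(!is.na(ly) & !is.na(ry), (ly + ry) / 2,
               ifelse(!is.na(ly), ly, ry))
  structure(list(
    participant_id = as.character(participant_id),
    slide_id = as.character(slide_id),
    samples = .fast_df(list(t = as.numeric(t), lx = as.numeric(lx),
                            ly = as.numeric(ly), rx = as.numeric(rx),
                            ry = as.numeric(ry), mx = as.numeric(mx),
                            my = as.numeric(my)))),
    class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf(
    "<trial_recording> participant %s, slide %s: %d samples (%d retained), %.0f ms span\n",
    x$participant_id, x$slide_id, n, sum(!is.na(x$samples$mx)),
    if (n) max(x$samples$t) - min(x$samples$t) else 0))
  invisible(x)
}

#' Read a gaze sample log
#'
#' Reads a delimited gaze log (comma or tab separated, autodetected) with
#' columns `participant_id, slide_id, t_ms, lx, ly, rx, ry` (blank = eye not
#' tracked) into one [trial_recording()] per participant x slide. Rows are
#' sorted by time within each trial; rows with no eye data at all are kept
#' as missing samples. Timestamps in seconds are converted to ms when
#' `time_unit = "auto"` detects a sub-10 maximum.
#'
#' @param path file path.
#' @param screen a [screen_config()] (carried along for downstream checks).
#' @param schedule optional `presentation_schedule`; when given, slide ids
#'   not present in it raise an error.
#' @param time_unit `"auto"`, `"ms"` or `"s"`.
#' @return A list of `trial_recording` objects, ordered by participant then
#'   slide.
#' @export
read_gaze_table <- function(path, screen = screen_config(), schedule = NULL,
                            time_unit = c("auto", "ms", "s")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("gaze file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("participant_id", "slide_id", "t_ms", "lx", "ly", "rx", "ry")
  if (!all(need %in% names(df)))
    stop("gaze file lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  for (col in c("t_ms", "lx", "ly", "rx", "ry")) {
    v <- df[[col]]
    if (is.character(v)) v[!nzchar(trimws(v))] <- NA
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(vn) & v != "")
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at data row %d: '%s'",
                   col, bad[1], v[bad[1]]))
    df[[col]] <- vn
  }
  if (anyNA(df$t_ms)) stop("missing timestamps in gaze file")
  if (time_unit == "s" ||
      (time_unit == "auto" && max(df$t_ms, na.rm = TRUE) <= 10))
    df$t_ms <- df$t_ms * 1000
  if (!is.null(schedule)) {
    unknown <- setdiff(unique(df$slide_id), schedule$slides$pair_id)
    if (length(unknown))
      stop("unknown slide ids in gaze file: ",
           paste(unknown, collapse = ", "))
  }
  key <- paste(df$participant_id, df$slide_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), key)[unique(key)], function(idx) {
    sub <- df[idx, , drop = FALSE]
    sub <- sub[order(sub$t_ms), , drop = FALSE]
    trial_recording(sub$participant_id[1], sub$slide_id[1], sub$t_ms,
                    sub$lx, sub$ly, sub$rx, sub$ry)
  })
  names(out) <- NULL
  ord <- order(vapply(out, function(r) r$participant_id, ""),
               vapply(out, function(r) r$slide_id, ""))
  out[ord]
}

#' Write recordings as a gaze sample log
#'
#' Inverse of [read_gaze_table()]: emits the neutral CSV interchange format
#' with per-eye coordinates (blank = missing).
#'
#' @param recordings list of `trial_recording` objects.
#' @param path file path.
#' @export
write_gaze_table <- function(recordings, path) {
  rows <- lapply(recordings, function(r)
    data.frame(participant_id = r$participant_id, slide_id = r$slide_id,
               t_ms = r$samples$t, lx = r$samples$lx, ly = r$samples$ly,
               rx = r$samples$rx, ry = r$samples$ry))
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a trial recording
#'
#' Reports (never fixes) anomalies: mean-binocular coordinates outside the
#' screen, non-monotone timestamps, and trial durations exceeding the
#' nominal slide length.
#'
#' @param rec a `trial_recording`.
#' @param screen a [screen_config()].
#' @param slide_ms nominal slide duration (ms).
#' @return Character vector of issues; empty when clean.
#' @export
validate_recording <- function(rec, screen = screen_config(),
                               slide_ms = 5000) {
  issues <- character(0)
  s <- rec$samples
  oob <- which(!is.na(s$mx) &
                 (s$mx < 0 | s$mx >= screen$width_px |
                    s$my < 0 | s$my >= screen$height_px))
  if (length(oob))
    issues <- c(issues, sprintf(
      "%d sample(s) out of screen bounds (first at t=%.1f ms)",
      length(oob), s$t[oob[1]]))
  if (nrow(s) > 1 && any(diff(s$t) <= 0))
    issues <- c(issues, "non-monotone timestamps")
  if (nrow(s) && max(s$t) > slide_ms)
    issues <- c(issues, sprintf(
      "samples span %.0f ms, beyond the %g ms slide", max(s$t), slide_ms))
  issues
}

#' Read / write a participant roster
#'
#' Roster CSV: `participant_id, nationality, gender, age`. Nationality and
#' gender are validated against the design's categories.
#'
#' @param path file path.
#' @export
read_roster <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "nationality", "gender", "age")
  if (!all(need %in% names(df)))
    stop("roster lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  bad_nat <- setdiff(unique(df$nationality), .nationality_levels)
  if (length(bad_nat))
    stop("unknown nationality value(s): ", paste(bad_nat, collapse = ", "))
  bad_gen <- setdiff(unique(df$gender), .gender_levels)
  if (length(bad_gen))
    stop("unknown gender value(s): ", paste(bad_gen, collapse = ", "))
  if (anyDuplicated(df$participant_id)) stop("duplicated participant ids")
  df
}

#' @rdname read_roster
#' @param roster roster data frame.
#' @export
write_roster <- function(roster, path) {
  write.csv(roster, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a trial metrics table
#'
#' Tidy delimited interchange for per-trial AOI metrics: one row per
#' participant x slide x AOI, stable column order, full double precision so
#' that `read_metrics_table(write_metrics_table(x))` round-trips exactly.
#'
#' @param metrics metrics data frame from [compute_cohort_metrics()].
#' @param path file path.
#' @export
write_metrics_table <- function(metrics, path) {
  stopifnot(is.data.frame(metrics))
  cols <- .metric_cols
  if (!all(cols %in% names(metrics)))
    stop("metrics table lacks columns: ",
         paste(setdiff(cols, names(metrics)), collapse = ", "))
  out <- metrics[, cols, drop = FALSE]
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA
      out[[col]] <- v
    }
  }
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(.metric_cols %in% names(df)))
    stop("not a metrics table: ", path)
  for (col in c("fixation_time_ms", "first_ms", "second_ms", "third_ms"))
    df[[col]] <- as.numeric(df[[col]])
  for (col in c("n_fixations", "n_sample_measurements"))
    df[[col]] <- as.integer(df[[col]])
  df
}

.metric_cols <- c("participant_id", "slide_id", "aoi", "n_fixations",
                  "fixation_time_ms", "first_ms", "second_ms", "third_ms",
                  "n_sample_measurements")
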