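#' Run the full attentional-bias analysis pipeline
#'
#' End-to-end analysis of a set of trial recordings: fixation detection and
#' AOI metrics, position-effect pre-check, curation (exclusion rules and
#' mirror-pair averaging with observation weights), difference responses,
#' and the mixed-effects models — total fixation time (gaussian, weighted
#' heteroscedastic), total fixation count (Poisson on full-pair sums) and
#' the two difference-response models — each optionally reduced backward by
#' LRT/AIC, with Tukey post hoc contrasts and cell tests against zero.
#'
#' @param recordings list of `trial_recording` objects (or a `gaze_cohort`,
#'   in which case roster and schedule default to its own).
#' @param roster participant roster data frame.
#' @param schedule `presentation_schedule` with side categories.
#' @param detector,aois detection configuration.
#' @param reduce apply [reduce_model()] to every fitted model.
#' @param models subset of
#'   `c("total_time", "count", "diff_time", "diff_count")` to fit.
#' @return A list of class `gazebias_analysis`: `metrics`, `curation`
#'   (exclusions), `position_check`, `curated`, `differences`, `fits`
#'   (named list of `gazefit`s), `posthoc` (for the total-time model),
#'   `zero_tests` (per difference model) and `counts` (bookkeeping:
#'   total/kept/excluded trials, curated observations, full-pair subset
#'   size).
#' @export
run_gaze_pipeline <- function(recordings, roster = NULL, schedule = NULL,
                              detector = detector_config(),
                              aois = default_aois(), reduce = TRUE,
                              models = c("total_time", "count",
                                         "diff_time", "diff_count")) {
  if (inherits(recordings, "gaze_cohort")) {
    cohort <- recordings
    if (is.null(roster)) roster <- cohort$roster
    if (is.null(schedule)) schedule <- cohort$schedule
    detector <- cohort$config$detector
    aois <- cohort$config$aois
    recordings <- cohort$recordings
  }
  stopifnot(!is.null(roster), !is.null(schedule))
  models <- match.arg(models, several.ok = TRUE)

  metrics <- compute_cohort_metrics(recordings, detector, aois)
  split <- apply_exclusions(metrics)
  pos_check <- tryCatch(position_effect_check(split$kept, schedule),
                        error = function(e) NULL)
  curated <- average_mirror_pairs(split$kept, schedule, roster)
  diffs <- compute_differences(curated)

  fits <- list(); posthoc <- list(); zero_tests <- list()
  if ("total_time" %in% models) {
    f <- fit_total_metric_model(curated)
    if (reduce) f <- reduce_model(f)
    fits$total_time <- f
    posthoc$by_nationality <- tryCatch(
      posthoc_contrasts(f, "animal", by = "nationality"),
      error = function(e) NULL)
    posthoc$by_gender <- tryCatch(
      posthoc_contrasts(f, "animal", by = "gender"),
      error = function(e) NULL)
  }
  if ("count" %in% models) {
    f <- tryCatch(fit_count_model(curated), error = function(e) NULL)
    if (!is.null(f) && reduce) f <- reduce_model(f)
    fits$count <- f
  }
  if ("diff_time" %in% models) {
    f <- fit_difference_model(diffs, "d_fix_time_ms")
    if (reduce) f <- reduce_model(f)
    fits$diff_time <- f
    zero_tests$diff_time <- test_differences_against_zero(f)
  }
  if ("diff_count" %in% models) {
    f <- fit_difference_model(diffs, "d_fix_count")
    if (reduce) f <- reduce_model(f)
    fits$diff_count <- f
    zero_tests$diff_count <- test_differences_against_zero(f)
  }
  n_trials <- length(unique(paste(metrics$participant_id,
                                  metrics$slide_id)))
  structure(list(
    metrics = metrics, curation = split, position_check = pos_check,
    curated = curated, differences = diffs, fits = fits,
    posthoc = posthoc, zero_tests = zero_tests,
    counts = list(
      n_trials = n_trials,
      n_expected = count_cohort_measurements(roster, schedule),
      n_excluded_a = sum(split$excluded$reason == "a"),
      n_excluded_b = sum(split$excluded$reason == "b"),
      n_kept = n_trials - nrow(split$excluded),
      n_curated_obs = nrow(diffs),
      n_full_pair = sum(diffs$weight == 1),
      n_half_pair = sum(diffs$weight == 0.5))),
    class = "gazebias_analysis")
}

#' @export
print.gazebias_analysis <- function(x, ...) {
  ct <- x$counts
  cat("<gazebias_analysis>\n")
  cat(sprintf("  trials: %d of %d expected; excluded a=%d, b=%d; kept %d\n",
              ct$n_trials, ct$n_expected, ct$n_excluded_a, ct$n_excluded_b,
              ct$n_kept))
  cat(sprintf("  curated observations: %d (%d full pairs, %d half weight)\n",
              ct$n_curated_obs, ct$n_full_pair, ct$n_half_pair))
  if (!is.null(x$position_check))
    cat(sprintf("  position effect: p = %.3g (interaction p = %.3g)\n",
                x$position_check$p_position,
                x$position_check$p_interaction))
  for (nm in names(x$fits)) if (!is.null(x$fits[[nm]])) {
    cat(sprintf("  model %s: %s ~ %s\n", nm, x$fits[[nm]]$response,
                x$fits[[nm]]$rhs))
  }
  invisible(x)
}
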