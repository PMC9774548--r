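#' Apply trial exclusion criteria
#'
#' Screens per-trial AOI metrics with the two curation rules:
#' \describe{
#'   \item{(a)}{combined fixation time over all AOIs strictly greater than
#'     `total_ms_max` (default 5500 ms) — failed measurements and trials
#'     where gaze hugged AOI borders so fixations accrued to several AOIs;}
#'   \item{(b)}{zero fixations on the left or the right AOI — the
#'     participant attended only one stimulus. The cross AOI is never
#'     considered by this rule.}
#' }
#' A trial meeting both rules is labelled `"a"`. Kept and excluded trials
#' partition the input.
#'
#' @param metrics long metrics data frame from [compute_cohort_metrics()].
#' @param total_ms_max exclusion threshold for criterion (a), ms (strict
#'   inequality).
#' @return A list of class `curation_split` with `kept` (long metrics rows
#'   of retained trials) and `excluded` (one row per excluded trial:
#'   `participant_id, slide_id, reason, total_fixation_time_ms,
#'   left_n_fixations, right_n_fixations`).
#' @export
apply_exclusions <- function(metrics, total_ms_max = 5500) {
  wide <- .metrics_wide(metrics)
  crit_a <- wide$total_fixation_time_ms > total_ms_max
  crit_b <- wide$left_n_fixations == 0L | wide$right_n_fixations == 0L
  reason <- ifelse(crit_a, "a", ifelse(crit_b, "b", NA_character_))
  excluded <- wide[!is.na(reason),
                   c("participant_id", "slide_id", "total_fixation_time_ms",
                     "left_n_fixations", "right_n_fixations")]
  excluded$reason <- reason[!is.na(reason)]
  excluded <- excluded[, c("participant_id", "slide_id", "reason",
                           "total_fixation_time_ms", "left_n_fixations",
                           "right_n_fixations")]
  rownames(excluded) <- NULL
  bad_key <- paste(excluded$participant_id, excluded$slide_id, sep = "\r")
  keep_rows <- !(paste(metrics$participant_id, metrics$slide_id,
                       sep = "\r") %in% bad_key)
  structure(list(kept = metrics[keep_rows, , drop = FALSE],
                 excluded = excluded),
            class = "curation_split")
}

#' @export
print.curation_split <- function(x, ...) {
  n_kept <- length(unique(paste(x$kept$participant_id, x$kept$slide_id)))
  cat(sprintf(
    "<curation_split> %d trials kept, %d excluded (a: %d, b: %d)\n",
    n_kept, nrow(x$excluded), sum(x$excluded$reason == "a"),
    sum(x$excluded$reason == "b")))
  invisible(x)
}

#' Write the curation report
#'
#' CSV of excluded trials with reason codes (`a` = combined AOI fixation
#' time over threshold, `b` = zero fixations on the left or right AOI).
#'
#' @param split a `curation_split` from [apply_exclusions()].
#' @param path file path.
#' @export
write_curation_report <- function(split, path) {
  write.csv(split$excluded, path, row.names = FALSE)
  invisible(path)
}

#' Total number of cohort measurements
#'
#' Bookkeeping helper: valid participants times slides per participant
#' (e.g. 132 x 36 = 4752).
#'
#' @param participants a roster data frame or a participant count.
#' @param schedule a `presentation_schedule` or a slide count.
#' @return Integer.
#' @export
count_cohort_measurements <- function(participants, schedule) {
  n_p <- if (is.data.frame(participants)) nrow(participants)
         else as.integer(participants)
  n_s <- if (inherits(schedule, "presentation_schedule"))
           nrow(schedule$slides) else as.integer(schedule)
  n_p * n_s
}

#' Average metrics over mirror pairs
#'
#' Collapses the two side-swapped presentations of each stimulus pair into
#' one observation per participant x base pair. The left/right AOI metrics
#' of each slide are first re-keyed to the *animal categories* shown on
#' those sides (using the schedule), so that a pair and its mirror aggregate
#' per animal rather than per screen side. When both mirror slides survived
#' curation the observation is their arithmetic mean with weight 1.0; when
#' only one survived, its values are used with weight 0.5; pairs with no
#' surviving slide are absent.
#'
#' @param kept long metrics data frame of retained trials (the `kept`
#'   element of [apply_exclusions()]'s result).
#' @param schedule the `presentation_schedule` mapping slides to base pairs
#'   and side categories (columns `left_category`, `right_category`).
#' @param roster optional roster; when given, `nationality`, `gender` and
#'   `age` are joined onto the output and coded as factors.
#' @return A data frame with one row per participant x base pair x animal:
#'   `participant_id, base_pair_id, pair_type, animal, role` (`"first"` /
#'   `"second"` by the difference sign convention), `n_fixations` and
#'   `fixation_time_ms` (means over surviving slides), `n_fix_sum` (integer
#'   sum over surviving slides, for count models), `n_slides`, `weight`,
#'   `w_inv`.
#' @export
average_mirror_pairs <- function(kept, schedule, roster = NULL) {
  wide <- .metrics_wide(kept)
  sl <- schedule$slides
  need <- c("left_category", "right_category")
  if (!all(need %in% names(sl)))
    stop("schedule lacks side category columns; ",
         "build it from build_pairs()/mirror_pairs() output")
  idx <- match(wide$slide_id, sl$pair_id)
  if (anyNA(idx))
    stop("slide id(s) without schedule entry: ",
         paste(unique(wide$slide_id[is.na(idx)]), collapse = ", "))
  wide$base_pair_id <- sl$base_pair_id[idx]
  wide$pair_type <- sl$pair_type[idx]
  per_side <- rbind(
    data.frame(participant_id = wide$participant_id,
               base_pair_id = wide$base_pair_id, pair_type = wide$pair_type,
               animal = sl$left_category[idx],
               n_fixations = wide$left_n_fixations,
               fixation_time_ms = wide$left_fixation_time_ms,
               stringsAsFactors = FALSE),
    data.frame(participant_id = wide$participant_id,
               base_pair_id = wide$base_pair_id, pair_type = wide$pair_type,
               animal = sl$right_category[idx],
               n_fixations = wide$right_n_fixations,
               fixation_time_ms = wide$right_fixation_time_ms,
               stringsAsFactors = FALSE))
  key <- interaction(per_side$participant_id, per_side$base_pair_id,
                     per_side$animal, drop = TRUE, lex.order = TRUE)
  first <- !duplicated(key)
  agg <- per_side[first, c("participant_id", "base_pair_id", "pair_type",
                           "animal")]
  agg$n_fixations <- as.numeric(tapply(per_side$n_fixations, key,
                                       mean)[as.character(key[first])])
  agg$fixation_time_ms <- as.numeric(
    tapply(per_side$fixation_time_ms, key, mean)[as.character(key[first])])
  agg$n_fix_sum <- as.integer(
    tapply(per_side$n_fixations, key, sum)[as.character(key[first])])
  agg$n_slides <- as.integer(
    tapply(per_side$n_fixations, key, length)[as.character(key[first])])
  if (any(agg$n_slides > 2L))
    stop("more than two slides share a base pair for one participant")
  agg$weight <- ifelse(agg$n_slides == 2L, 1, 0.5)
  agg$w_inv <- 1 / agg$weight
  agg$role <- ifelse(agg$animal == .pair_first[agg$pair_type], "first",
                     "second")
  agg$pair_type <- factor(agg$pair_type, .pair_type_levels)
  agg$animal <- factor(agg$animal, .animal_levels)
  if (!is.null(roster)) {
    ri <- match(agg$participant_id, roster$participant_id)
    if (anyNA(ri))
      stop("participants missing from roster: ",
           paste(unique(agg$participant_id[is.na(ri)]), collapse = ", "))
    agg$nationality <- factor(roster$nationality[ri], .nationality_levels)
    agg$gender <- factor(roster$gender[ri], .gender_levels)
    agg$age <- roster$age[ri]
  }
  rownames(agg) <- NULL
  agg
}

#' Check for a stimulus position effect
#'
#' Before collapsing mirror pairs, fits a linear mixed model of the
#' per-slide fixation-time difference (first-named animal minus the other)
#' on the screen position of the first-named (focal) animal, the pair type
#' and their interaction, with a participant random intercept. A
#' non-significant position main effect and interaction justify averaging
#' the two side-swapped presentations.
#'
#' @param kept long metrics of retained trials.
#' @param schedule the `presentation_schedule` with side categories.
#' @param response `"fixation_time_ms"` or `"n_fixations"`.
#' @return A list of class `position_check`: the `nlme::lme` fit, its
#'   marginal ANOVA table, and the p-values for the position main effect and
#'   the position x pair-type interaction. A singular or non-converging fit
#'   is flagged in `$singular` rather than raising an error.
#' @export
position_effect_check <- function(kept, schedule,
                                  response = c("fixation_time_ms",
                                               "n_fixations")) {
  response <- match.arg(response)
  wide <- .metrics_wide(kept)
  if (length(unique(wide$participant_id)) < 2L)
    stop("position effect check needs at least 2 participants")
  sl <- schedule$slides
  idx <- match(wide$slide_id, sl$pair_id)
  if (anyNA(idx)) stop("slide id(s) without schedule entry")
  focal <- .pair_first[sl$pair_type[idx]]
  pos <- ifelse(sl$left_category[idx] == focal, "left", "right")
  lcol <- paste0("left_", response); rcol <- paste0("right_", response)
  d <- ifelse(pos == "left", wide[[lcol]] - wide[[rcol]],
              wide[[rcol]] - wide[[lcol]])
  dat <- data.frame(d = d, position = factor(pos, c("left", "right")),
                    pair_type = factor(sl$pair_type[idx],
                                       .pair_type_levels),
                    participant_id = wide$participant_id)
  fit <- NULL; singular <- FALSE
  fit <- tryCatch(
    nlme::lme(d ~ position * pair_type, random = ~ 1 | participant_id,
              data = dat, method = "REML"),
    error = function(e) { singular <<- TRUE; NULL })
  if (is.null(fit))
    return(structure(list(fit = NULL, anova = NULL,
                          p_position = NA_real_, p_interaction = NA_real_,
                          singular = TRUE), class = "position_check"))
  an <- anova(fit, type = "marginal")
  structure(list(
    fit = fit, anova = an,
    p_position = an["position", "p-value"],
    p_interaction = an["position:pair_type", "p-value"],
    singular = singular), class = "position_check")
}

#' @export
print.position_check <- function(x, ...) {
  cat("<position_check> focal-stimulus position model\n")
  if (is.null(x$fit)) {
    cat("  fit failed / singular\n")
  } else {
    cat(sprintf("  position main effect: p = %.4g\n", x$p_position))
    cat(sprintf("  position x pair type: p = %.4g\n", x$p_interaction))
  }
  invisible(x)
}

# long (one row per trial x AOI) -> wide (one row per trial)
.metrics_wide <- function(metrics) {
  stopifnot(all(c("participant_id", "slide_id", "aoi") %in% names(metrics)))
  key <- paste(metrics$participant_id, metrics$slide_id, sep = "\r")
  ukey <- unique(key)
  first <- match(ukey, key)
  out <- data.frame(participant_id = metrics$participant_id[first],
                    slide_id = metrics$slide_id[first],
                    stringsAsFactors = FALSE)
  for (side in c("left", "right", "cross")) {
    rows <- which(metrics$aoi == side)
    m <- match(ukey, key[rows])
    out[[paste0(side, "_n_fixations")]] <-
      ifelse(is.na(m), 0L, metrics$n_fixations[rows][m])
    out[[paste0(side, "_fixation_time_ms")]] <-
      ifelse(is.na(m), 0, metrics$fixation_time_ms[rows][m])
  }
  tot <- tapply(metrics$fixation_time_ms, key, sum)
  out$total_fixation_time_ms <- as.numeric(tot[ukey])
  ns <- tapply(metrics$n_sample_measurements, key, function(v) v[1])
  out$n_sample_measurements <- as.integer(ns[ukey])
  out
}
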