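# build a long metrics table directly (participant x slide x AOI rows)
mk_metrics <- function(trials) {
  do.call(rbind, lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    data.frame(participant_id = tr$participant_id, slide_id = tr$slide_id,
               aoi = c("left", "right", "cross"),
               n_fixations = c(tr$left_n, tr$right_n, tr$cross_n),
               fixation_time_ms = c(tr$left_t, tr$right_t, tr$cross_t),
               first_ms = NA_real_, second_ms = NA_real_,
               third_ms = NA_real_, n_sample_measurements = 300L,
               stringsAsFactors = FALSE)
  }))
}

test_that("the exclusion rules implement the 5500 ms and zero-fixation
          criteria exactly", {
  trials <- data.frame(
    participant_id = "p1", slide_id = c("s1", "s2", "s3", "s4"),
    left_n = c(3L, 2L, 0L, 3L), right_n = c(4L, 0L, 2L, 3L),
    cross_n = 1L,
    left_t = c(2600, 2000, 0, 2500), right_t = c(2600, 0, 2000, 2500),
    cross_t = c(400, 300, 300, 500), stringsAsFactors = FALSE)
  sp <- apply_exclusions(mk_metrics(trials))
  # s1: 5600 ms total -> (a); s2/s3: a side with zero fixations -> (b);
  # s4: exactly 5500 ms total is kept (strict inequality)
  expect_equal(sp$excluded$slide_id, c("s1", "s2", "s3"))
  expect_equal(sp$excluded$reason, c("a", "b", "b"))
  kept_ids <- unique(sp$kept$slide_id)
  expect_equal(kept_ids, "s4")
})

test_that("exclusion is idempotent, order independent and monotone in the
          threshold", {
  set.seed(12)
  trials <- data.frame(
    participant_id = rep(sprintf("p%d", 1:6), each = 8),
    slide_id = rep(sprintf("s%d", 1:8), times = 6),
    left_n = rpois(48, 4), right_n = rpois(48, 4), cross_n = rpois(48, 1),
    left_t = runif(48, 0, 3000), right_t = runif(48, 0, 3000),
    cross_t = runif(48, 0, 600), stringsAsFactors = FALSE)
  m <- mk_metrics(trials)
  sp <- apply_exclusions(m)
  # matches the brute-force recount
  expect_setequal(paste(sp$excluded$participant_id, sp$excluded$slide_id,
                        sep = "\r"),
                  oracle_excluded_trials(m))
  # idempotent: re-curating the kept set excludes nothing
  expect_equal(nrow(apply_exclusions(sp$kept)$excluded), 0L)
  # order independent
  sp2 <- apply_exclusions(m[sample(nrow(m)), ])
  expect_setequal(paste(sp2$excluded$participant_id,
                        sp2$excluded$slide_id),
                  paste(sp$excluded$participant_id,
                        sp$excluded$slide_id))
  # relaxing the threshold upward never shrinks the kept set
  sp_hi <- apply_exclusions(m, total_ms_max = 7000)
  expect_true(all(unique(paste(sp$kept$participant_id,
                               sp$kept$slide_id)) %in%
                    unique(paste(sp_hi$kept$participant_id,
                                 sp_hi$kept$slide_id))))
})

test_that("cohort bookkeeping multiplies participants by slides", {
  expect_equal(count_cohort_measurements(132, 36), 4752L)
  expect_equal(count_cohort_measurements(1, 36), 36L)
  expect_equal(count_cohort_measurements(0, 36), 0L)
  sched <- make_schedule(mirror_pairs(build_pairs(stimulus_images())),
                         seed = 1)
  roster <- data.frame(participant_id = "p1")
  expect_equal(count_cohort_measurements(roster, sched), 36L)
})

test_that("mirror-pair averaging re-keys metrics by animal, averages the
          two slides and assigns half weight to lone slides", {
  sched <- make_schedule(mirror_pairs(build_pairs(stimulus_images())),
                         seed = 2)
  sl <- sched$slides
  bp <- sl$base_pair_id[sl$pair_type == "scorpion-spider"][1]
  mates <- sl[sl$base_pair_id == bp, ]
  orig <- mates[mates$orientation == "original", ]
  mirr <- mates[mates$orientation == "mirrored", ]
  sc_side_orig <- if (orig$left_category == "scorpion") "left" else "right"
  sc_side_mirr <- if (mirr$left_category == "scorpion") "left" else "right"
  expect_false(sc_side_orig == sc_side_mirr)  # mirror swaps sides
  mk_trial <- function(slide_id, left_t, right_t)
    data.frame(participant_id = "p1", slide_id = slide_id,
               left_n = 3L, right_n = 4L, cross_n = 1L,
               left_t = left_t, right_t = right_t, cross_t = 200,
               stringsAsFactors = FALSE)
  # scorpion gets 2000 ms in the original slide and 2400 in the mirror
  t_orig <- if (sc_side_orig == "left") c(2000, 1000) else c(1000, 2000)
  t_mirr <- if (sc_side_mirr == "left") c(2400, 1100) else c(1100, 2400)
  m <- mk_metrics(rbind(mk_trial(orig$pair_id, t_orig[1], t_orig[2]),
                        mk_trial(mirr$pair_id, t_mirr[1], t_mirr[2])))
  cu <- average_mirror_pairs(m, sched)
  sc <- cu[cu$animal == "scorpion", ]
  expect_equal(sc$fixation_time_ms, 2200)
  expect_equal(sc$weight, 1)
  expect_equal(sc$n_fix_sum, 7L)
  expect_equal(cu$fixation_time_ms[cu$animal == "spider"], 1050)
  # lone slide: its own values at half weight
  m1 <- mk_metrics(mk_trial(orig$pair_id, t_orig[1], t_orig[2]))
  cu1 <- average_mirror_pairs(m1, sched)
  expect_equal(cu1$fixation_time_ms[cu1$animal == "scorpion"], 2000)
  expect_equal(unique(cu1$weight), 0.5)
  expect_error(average_mirror_pairs(
    mk_metrics(mk_trial("nonexistent_slide", 1, 1)), sched),
    "without schedule entry")
})

test_that("averaging conserves per-participant per-pair means over kept
          slides on random cohorts", {
  set.seed(77)
  sched <- make_schedule(mirror_pairs(build_pairs(stimulus_images())),
                         seed = 3)
  sl <- sched$slides
  trials <- do.call(rbind, lapply(c("p1", "p2"), function(p)
    data.frame(participant_id = p, slide_id = sl$pair_id,
               left_n = rpois(36, 5) + 1L, right_n = rpois(36, 5) + 1L,
               cross_n = 1L, left_t = runif(36, 500, 2500),
               right_t = runif(36, 500, 2500),
               cross_t = runif(36, 0, 400), stringsAsFactors = FALSE)))
  m <- mk_metrics(trials)
  cu <- average_mirror_pairs(m, sched)
  # weighted observation count equals kept-slide count / 2 exactly when all
  # slides are kept in full pairs
  expect_equal(sum(cu$weight[cu$role == "first"]), 2 * 36 / 2)
  # conservation: re-derive one cell by hand
  for (i in sample(nrow(cu), 10)) {
    row <- cu[i, ]
    mates <- sl$pair_id[sl$base_pair_id == row$base_pair_id]
    vals <- vapply(mates, function(sid) {
      side <- if (sl$left_category[sl$pair_id == sid] ==
                  as.character(row$animal)) "left" else "right"
      tr <- trials[trials$participant_id == row$participant_id &
                     trials$slide_id == sid, ]
      if (side == "left") tr$left_t else tr$right_t
    }, 0)
    expect_equal(row$fixation_time_ms, mean(vals))
  }
})

test_that("the position-effect pre-check needs two participants and reports
          no effect on position-balanced data", {
  sched <- make_schedule(mirror_pairs(build_pairs(stimulus_images())),
                         seed = 4)
  sl <- sched$slides
  mk <- function(pids, pos_effect = 0) {
    set.seed(101)
    do.call(rbind, lapply(pids, function(p) {
      focal <- c("spider-grasshopper" = "spider",
                 "scorpion-grasshopper" = "scorpion",
                 "scorpion-spider" = "scorpion")[sl$pair_type]
      # a position effect favours one side of the screen regardless of
      # which animal sits there
      base_l <- runif(36, 800, 1200) + pos_effect
      base_r <- runif(36, 800, 1200)
      data.frame(participant_id = p, slide_id = sl$pair_id,
                 left_n = 3L, right_n = 3L, cross_n = 1L,
                 left_t = base_l, right_t = base_r, cross_t = 100,
                 stringsAsFactors = FALSE)
    }))
  }
  expect_error(position_effect_check(mk_metrics(mk("p1")), sched),
               "at least 2 participants")
  pc <- position_effect_check(mk_metrics(mk(sprintf("p%d", 1:8))), sched)
  expect_s3_class(pc, "position_check")
  expect_false(pc$singular)
  expect_gt(pc$p_position, 0.05)
  # a strong planted position effect is detected
  pc2 <- position_effect_check(
    mk_metrics(mk(sprintf("p%d", 1:8), pos_effect = 600)), sched)
  expect_lt(pc2$p_position, 0.001)
})
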