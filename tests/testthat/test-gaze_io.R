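write_toy_gaze <- function(path, rows) {
  writeLines(c("participant_id,slide_id,t_ms,lx,ly,rx,ry", rows), path)
}

test_that("a toy file yields one recording per participant x slide with
          mean-binocular coordinates", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- c()
  for (p in c("p1", "p2")) for (s in c("s1", "s2"))
    rows <- c(rows, sprintf("%s,%s,%g,%g,%g,%g,%g", p, s,
                            (0:2) * 1000 / 60, 100, 200, 110, 210))
  write_toy_gaze(path, rows)
  recs <- read_gaze_table(path)
  expect_length(recs, 4L)
  expect_equal(recs[[1]]$samples$mx, rep(105, 3))
  expect_equal(recs[[1]]$samples$my, rep(205, 3))
})

test_that("single-eye samples fall back to the available eye and empty rows
          stay missing", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_gaze(path, c("p1,s1,0,100,200,,",
                         "p1,s1,16.7,,,300,400",
                         "p1,s1,33.3,,,,"))
  rec <- read_gaze_table(path)[[1]]
  expect_equal(rec$samples$mx, c(100, 300, NA))
  expect_equal(rec$samples$my, c(200, 400, NA))
  expect_equal(nrow(rec$samples), 3L)
})

test_that("shuffled rows are sorted by time to match a pre-sorted file", {
  t <- (0:9) * 1000 / 60
  mk_rows <- function(ord) sprintf("p1,s1,%.6f,%g,%g,%g,%g", t[ord],
                                   100 + ord, 200, 100 + ord, 200)
  sorted <- withr::local_tempfile(fileext = ".csv")
  shuffled <- withr::local_tempfile(fileext = ".csv")
  write_toy_gaze(sorted, mk_rows(1:10))
  set.seed(3)
  write_toy_gaze(shuffled, mk_rows(sample(10)))
  expect_equal(read_gaze_table(shuffled)[[1]]$samples,
               read_gaze_table(sorted)[[1]]$samples)
})

test_that("malformed rows and unknown slide ids are rejected by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_gaze(path, c("p1,s1,0,100,200,110,210",
                         "p1,s1,16.7,oops,200,110,210"))
  expect_error(read_gaze_table(path), "malformed.*lx")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_toy_gaze(path2, "p1,not_a_slide,0,100,200,110,210")
  sched <- make_schedule(mirror_pairs(build_pairs(stimulus_images())),
                         seed = 1)
  expect_error(read_gaze_table(path2, schedule = sched), "not_a_slide")
})

test_that("timestamps in seconds are converted on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_gaze(path, sprintf("p1,s1,%.6f,100,200,110,210",
                               (0:5) / 60))
  rec <- read_gaze_table(path)[[1]]
  expect_equal(rec$samples$t, (0:5) * 1000 / 60, tolerance = 1e-4)
})

test_that("gaze tables round-trip through write_gaze_table", {
  set.seed(1)
  s <- rw_stream(50)
  rec <- rec_from_stream(s)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gaze_table(list(rec), path)
  back <- read_gaze_table(path)[[1]]
  expect_equal(back$samples$mx, rec$samples$mx, tolerance = 1e-5)
})

test_that("validate_recording reports out-of-bounds, non-monotone and
          overlong recordings without mutating", {
  t <- (0:299) * 1000 / 60
  clean <- rec_from_stream(list(t = t, x = rep(400, 300),
                                y = rep(400, 300)))
  expect_length(validate_recording(clean), 0)
  oob <- rec_from_stream(list(t = t, x = c(2500, rep(400, 299)),
                              y = rep(400, 300)))
  expect_match(validate_recording(oob), "out of screen", all = FALSE)
  # concatenating two streams makes a 9000+ ms recording
  long <- rec_from_stream(list(t = c(t, t + 5000), x = rep(400, 600),
                               y = rep(400, 600)))
  expect_match(validate_recording(long), "beyond", all = FALSE)
})

test_that("trial_recording enforces its invariants", {
  expect_error(trial_recording("p", "s", c(1, 1), 1:2, 1:2, 1:2, 1:2),
               "strictly increasing")
  expect_error(trial_recording("p", "s", 0, 1, NA, 1, 1),
               "both present or both missing")
  expect_error(trial_recording("p", "s", -1, 1, 1, 1, 1), "negative")
})

test_that("metrics tables round-trip losslessly and cohort-scale tables
          have the expected shape", {
  set.seed(4)
  recs <- lapply(1:3, function(i)
    rec_from_stream(rw_stream(120), pid = paste0("p", i)))
  m <- compute_cohort_metrics(recs)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_table(m, path)
  back <- read_metrics_table(path)
  expect_equal(back$fixation_time_ms, m$fixation_time_ms)
  expect_equal(back$n_fixations, m$n_fixations)
  expect_identical(back$first_ms, m$first_ms)
  # empty metrics: header-only file
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_metrics_table(m[0, ], path2)
  expect_length(readLines(path2), 1L)
  expect_equal(nrow(read_metrics_table(path2)), 0L)
  # a 132-participant x 36-slide x 3-AOI table has 14256 rows
  big <- data.frame(
    participant_id = rep(sprintf("p%03d", 1:132), each = 36 * 3),
    slide_id = rep(rep(sprintf("s%02d", 1:36), each = 3), times = 132),
    aoi = rep(c("left", "right", "cross"), times = 132 * 36),
    n_fixations = 1L, fixation_time_ms = 100, first_ms = 100,
    second_ms = NA_real_, third_ms = NA_real_,
    n_sample_measurements = 300L)
  expect_equal(nrow(big), 14256L)
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_metrics_table(big, path3)
  expect_equal(nrow(read_metrics_table(path3)), 14256L)
})

test_that("roster files are validated on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_roster(data.frame(participant_id = c("a", "b"),
                          nationality = c("Somali", "Czech"),
                          gender = c("woman", "man"), age = c(20, 30)),
               path)
  r <- read_roster(path)
  expect_equal(nrow(r), 2L)
  write_roster(data.frame(participant_id = "a", nationality = "Other",
                          gender = "man", age = 20), path)
  expect_error(read_roster(path), "nationality")
})
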