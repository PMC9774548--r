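# Independent oracles and small fixtures used across the test files.
# The oracles re-derive results by literal rule application, separately from
# the package's implementations.

# literal lead-sample rule: scan forward collecting members while each next
# sample is within the dispersion radius of the run's lead AND within the
# gap tolerance of its predecessor; emit runs of at least min_n samples
oracle_detect <- function(t, x, y, disp = 37, min_n = 3, rate = 60,
                          max_gap = 2 * 1000 / rate) {
  n <- length(t)
  fix <- list()
  i <- 1L
  while (i <= n) {
    lead <- i
    j <- i + 1L
    while (j <= n) {
      dist_ok <- sqrt((x[j] - x[lead])^2 + (y[j] - y[lead])^2) <= disp
      gap_ok <- (t[j] - t[j - 1L]) <= max_gap * (1 + 1e-9)
      if (dist_ok && gap_ok) j <- j + 1L else break
    }
    if (j - i >= min_n)
      fix[[length(fix) + 1L]] <- list(
        lead = lead, members = i:(j - 1L), n = j - i,
        duration = (j - i) * 1000 / rate,
        cx = mean(x[i:(j - 1L)]), cy = mean(y[i:(j - 1L)]))
    i <- j
  }
  fix
}

# encode a segmentation (from either implementation) as a string
seg_string <- function(leads, ns) paste(leads, ns, sep = ":", collapse = ";")

seg_string_pkg <- function(fx) seg_string(fx$lead_index, fx$n_samples)

seg_string_oracle <- function(fx) {
  seg_string(vapply(fx, `[[`, 0L, "lead"), vapply(fx, `[[`, 0L, "n"))
}

# per-sample AOI tally oracle: whole-fixation accrual to every AOI that
# contains at least one member sample, recomputed point by point
oracle_aoi_tally <- function(t, x, y, aois, disp = 37, min_n = 3,
                             rate = 60) {
  fx <- oracle_detect(t, x, y, disp, min_n, rate)
  out <- list()
  for (a in seq_len(nrow(aois))) {
    nm <- aois$name[a]
    n_fix <- 0L; tot <- 0
    durs <- numeric(0)
    for (f in fx) {
      inside <- FALSE
      for (k in f$members) {
        if (x[k] >= aois$x0[a] && x[k] < aois$x1[a] &&
            y[k] >= aois$y0[a] && y[k] < aois$y1[a]) {
          inside <- TRUE
          break
        }
      }
      if (inside) {
        n_fix <- n_fix + 1L
        tot <- tot + f$duration
        durs <- c(durs, f$duration)
      }
    }
    out[[nm]] <- list(n_fixations = n_fix, fixation_time_ms = tot,
                      durations = durs)
  }
  out
}

# brute-force recount of the exclusion rules on a long metrics table
oracle_excluded_trials <- function(metrics, total_max = 5500) {
  key <- unique(paste(metrics$participant_id, metrics$slide_id,
                      sep = "\r"))
  bad <- character(0)
  for (k in key) {
    rows <- metrics[paste(metrics$participant_id, metrics$slide_id,
                          sep = "\r") == k, ]
    tot <- sum(rows$fixation_time_ms)
    ln <- rows$n_fixations[rows$aoi == "left"]
    rn <- rows$n_fixations[rows$aoi == "right"]
    if (tot > total_max || ln == 0 || rn == 0) bad <- c(bad, k)
  }
  bad
}

# independent interlacing-constraint checker
oracle_schedule_ok <- function(slides, min_sep = 3) {
  for (bp in unique(slides$base_pair_id)) {
    pos <- which(slides$base_pair_id == bp)
    if (length(pos) > 1 && min(diff(sort(pos))) < min_sep) return(FALSE)
  }
  TRUE
}

# a seeded 2-D random-walk gaze stream on the default screen
rw_stream <- function(n = 300, step_sd = 25, jump_p = 0.1,
                      rate = 60, start = c(960, 540)) {
  dx <- rnorm(n, 0, step_sd) + ifelse(runif(n) < jump_p,
                                      rnorm(n, 0, 400), 0)
  dy <- rnorm(n, 0, step_sd) + ifelse(runif(n) < jump_p,
                                      rnorm(n, 0, 200), 0)
  list(t = (seq_len(n) - 1) * 1000 / rate,
       x = pmin(pmax(start[1] + cumsum(dx), 0), 1919),
       y = pmin(pmax(start[2] + cumsum(dy), 0), 1079))
}

# build a trial_recording from a plain mean-gaze stream (both eyes equal)
rec_from_stream <- function(s, pid = "p1", slide = "s1") {
  trial_recording(pid, slide, s$t, s$x, s$y, s$x, s$y)
}

# memoized calibrated generator configs (calibration is deterministic and
# expensive; share it across test files)
.cal_cache <- new.env(parent = emptyenv())
cached_cfg <- function(key, builder) {
  if (!exists(key, envir = .cal_cache))
    assign(key, calibrate_generator(builder()), envir = .cal_cache)
  get(key, envir = .cal_cache)
}

default_cal_cfg <- function() cached_cfg("default", generator_config)

small_counts <- function(n) data.frame(
  nationality = c("Somali", "Somali", "Czech", "Czech"),
  gender = c("woman", "man", "woman", "man"), n = rep(n, 4),
  stringsAsFactors = FALSE)

zero_bias_table <- function(value = 0) {
  g <- expand.grid(pair_type = c("spider-grasshopper",
                                 "scorpion-grasshopper",
                                 "scorpion-spider"),
                   nationality = c("Somali", "Czech"),
                   gender = c("woman", "man"),
                   stringsAsFactors = FALSE)
  g$value <- value
  g
}

zero_bias_cfg <- function() cached_cfg("zero_bias", function()
  generator_config(participant_counts = small_counts(2),
                   bias_time_ms = zero_bias_table(0),
                   bias_count = zero_bias_table(0),
                   participant_sd_ms = 0, resid_sd_ms = 1200))
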