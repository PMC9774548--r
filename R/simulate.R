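#' Default cohort composition and attentional-bias tables
#'
#' The generator's default study conditions: a cohort of 132 valid
#' participants (24 Somali women, 41 Somali men, 35 Czech women, 32 Czech
#' men) and per-cell expected attentional-bias differences (first-named
#' animal minus second-named) for fixation time (ms) and fixation counts,
#' at the magnitudes characteristic of the spontaneous gaze preference
#' paradigm with threatening arthropod stimuli: strong scorpion bias in
#' Somali participants, weaker in Czech participants, and weaker in women
#' than in men.
#'
#' @return Data frames (`default_participant_counts`: `nationality, gender,
#'   n`; `default_bias_time` / `default_bias_count`: `pair_type,
#'   nationality, gender, value`).
#' @export
default_participant_counts <- function() {
  data.frame(nationality = c("Somali", "Somali", "Czech", "Czech"),
             gender = c("woman", "man", "woman", "man"),
             n = c(24L, 41L, 35L, 32L), stringsAsFactors = FALSE)
}

#' @rdname default_participant_counts
#' @export
default_bias_time <- function() {
  .bias_table(c(
    # Somali women, Somali men, Czech women, Czech men per pair type
    "spider-grasshopper" = list(c(414.54, 709.93, 92.39, 387.77)),
    "scorpion-grasshopper" = list(c(741.86, 1037.25, 419.71, 715.09)),
    "scorpion-spider" = list(c(322.81, 618.20, 0.66, 296.04))))
}

#' @rdname default_participant_counts
#' @export
default_bias_count <- function() {
  .bias_table(c(
    "spider-grasshopper" = list(c(1.23, 2.49, 0.23, 1.48)),
    "scorpion-grasshopper" = list(c(3.40, 4.65, 2.39, 3.65)),
    "scorpion-spider" = list(c(1.28, 2.54, 0.28, 1.53))))
}

.bias_table <- function(vals) {
  cells <- data.frame(
    nationality = c("Somali", "Somali", "Czech", "Czech"),
    gender = c("woman", "man", "woman", "man"), stringsAsFactors = FALSE)
  do.call(rbind, lapply(names(vals), function(pt)
    cbind(pair_type = pt, cells, value = vals[[pt]])))
}

#' Synthetic gaze generator configuration
#'
#' Collects every knob of the synthetic cohort generator. A simulated trial
#' is an alternating sequence of fixations and saccade gaps on a 5 s slide
#' sampled at the screen's nominal rate (about 300 samples): an initial
#' dwell on the fixation cross, then fixations whose target side is drawn
#' with a bias-dependent probability and whose log-normal durations are
#' scaled on the threat side, with Gaussian within-fixation jitter around an
#' AOI-interior anchor, dropped samples during saccades, and random track
#' loss. Per-cell expected differences are imposed by a deterministic
#' calibration (see [calibrate_generator()]).
#'
#' @param participant_counts data frame `nationality, gender, n`
#'   (default [default_participant_counts()]).
#' @param bias_time_ms,bias_count per-cell expected differences
#'   (first-named animal minus second-named) in fixation time (ms) and
#'   fixation count; data frames `pair_type, nationality, gender, value`.
#' @param participant_sd_ms SD of the participant-level random shift of the
#'   fixation-time difference (ms).
#' @param resid_sd_ms target total trial-level residual SD of the
#'   fixation-time difference (ms) for a nationality with multiplier 1.
#'   Must be at least the intrinsic SD of the stochastic fixation process
#'   itself (about 1000-1100 ms at the default fixation parameters); the
#'   default of 1600 ms is of the order implied by the cell confidence
#'   intervals typical of this paradigm.
#' @param nat_resid_mult named per-nationality multipliers of
#'   `resid_sd_ms` (the generator adds noise so the *total* per-trial
#'   residual SD, including the intrinsic fixation-process noise, matches
#'   `resid_sd_ms * multiplier`).
#' @param fix_median_ms,fix_sdlog log-normal fixation duration parameters
#'   (median in ms, SD on the log scale).
#' @param jitter_sd_px within-fixation Gaussian jitter SD (px).
#' @param saccade_gap_samples dropped samples between fixations; the
#'   default 3 exceeds the detector's gap tolerance so planted fixations
#'   stay separated.
#' @param track_loss_p per-sample probability of losing both eyes.
#' @param eye_loss_p per-sample probability of losing one random eye.
#' @param eye_offset_px horizontal half-distance between the two eyes'
#'   reported positions.
#' @param cross_dwell_ms initial dwell on the fixation cross (ms).
#' @param inject_a_rate,inject_b_rate per-trial probabilities of planting a
#'   trial violating curation criterion (a) (border-straddling gaze whose
#'   combined AOI time exceeds the threshold) or (b) (all fixations on one
#'   side). Defaults reproduce the curation rates of the cohort the
#'   defaults emulate (19 and 346 out of 4752 trials).
#' @param straddle_p per-fixation probability of anchoring an ordinary
#'   fixation on the stimulus/cross border.
#' @param interior_margin_px anchors stay at least this far inside an AOI.
#' @param slide_ms slide duration (ms).
#' @param screen,detector,aois configuration objects.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(participant_counts = default_participant_counts(),
                             bias_time_ms = default_bias_time(),
                             bias_count = default_bias_count(),
                             participant_sd_ms = 300,
                             resid_sd_ms = 1600,
                             nat_resid_mult = c(Somali = 1, Czech = 1),
                             fix_median_ms = 250, fix_sdlog = 0.4,
                             jitter_sd_px = 4,
                             saccade_gap_samples = 3L,
                             track_loss_p = 0.02,
                             eye_loss_p = 0.01,
                             eye_offset_px = 1.5,
                             cross_dwell_ms = 400,
                             inject_a_rate = 19 / 4752,
                             inject_b_rate = 346 / 4752,
                             straddle_p = 0,
                             interior_margin_px = 30,
                             slide_ms = 5000,
                             screen = screen_config(),
                             detector = detector_config(),
                             aois = default_aois(screen)) {
  stopifnot(participant_sd_ms >= 0, resid_sd_ms >= 0,
            all(nat_resid_mult > 0), fix_median_ms > 0, fix_sdlog >= 0,
            jitter_sd_px >= 0, saccade_gap_samples >= 1,
            track_loss_p >= 0, track_loss_p <= 1,
            eye_loss_p >= 0, eye_loss_p <= 1,
            inject_a_rate >= 0, inject_b_rate >= 0,
            inject_a_rate + inject_b_rate <= 1,
            straddle_p >= 0, straddle_p <= 1, slide_ms > 0)
  for (a in c("left", "right"))
    .check_aoi_fits(aois, a, interior_margin_px)
  structure(list(
    participant_counts = participant_counts,
    bias_time_ms = bias_time_ms, bias_count = bias_count,
    participant_sd_ms = participant_sd_ms, resid_sd_ms = resid_sd_ms,
    nat_resid_mult = nat_resid_mult, fix_median_ms = fix_median_ms,
    fix_sdlog = fix_sdlog, jitter_sd_px = jitter_sd_px,
    saccade_gap_samples = as.integer(saccade_gap_samples),
    track_loss_p = track_loss_p, eye_loss_p = eye_loss_p,
    eye_offset_px = eye_offset_px, cross_dwell_ms = cross_dwell_ms,
    inject_a_rate = inject_a_rate, inject_b_rate = inject_b_rate,
    straddle_p = straddle_p, interior_margin_px = interior_margin_px,
    slide_ms = slide_ms, screen = screen, detector = detector,
    aois = aois, calibration = NULL), class = "generator_config")
}

.check_aoi_fits <- function(aois, name, margin) {
  r <- aois[aois$name == name, ]
  if (!nrow(r)) stop("AOI '", name, "' missing from AOI set")
  if (r$x1 - r$x0 <= 2 * margin || r$y1 - r$y0 <= 2 * margin)
    stop("AOI '", name, "' too small for the interior margin of ", margin,
         " px")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> %d participants x 36 slides, %g ms slides @ %g Hz\n",
    sum(x$participant_counts$n), x$slide_ms,
    x$screen$sampling_rate_hz))
  cat(sprintf("  fixations: lognormal(median %g ms, sdlog %g), jitter %g px, gap %d samples\n",
              x$fix_median_ms, x$fix_sdlog, x$jitter_sd_px,
              x$saccade_gap_samples))
  cat(sprintf("  residual SD %g ms (multipliers: %s); participant SD %g ms\n",
              x$resid_sd_ms,
              paste(sprintf("%s=%g", names(x$nat_resid_mult),
                            x$nat_resid_mult), collapse = ", "),
              x$participant_sd_ms))
  cat(sprintf("  calibrated: %s\n", !is.null(x$calibration)))
  invisible(x)
}

# expected realized duration (ms) of a fixation drawn with multiplier mult,
# after rounding to samples and flooring at min_samples
.mean_real_dur <- function(mult, cfg, n_grid = 4096L) {
  dt <- 1000 / cfg$screen$sampling_rate_hz
  p <- (seq_len(n_grid) - 0.5) / n_grid
  d <- qlnorm(p, meanlog = log(cfg$fix_median_ms) + log(mult),
              sdlog = cfg$fix_sdlog)
  mean(pmax(cfg$detector$min_samples, round(d / dt))) * dt
}

# closed-form per-trial targets -> (p_threat, duration multiplier m)
# Let mu_c be the mean realized control-fixation duration, g the saccade
# gap, T the usable trial time, tau / cnt the target time / count
# differences. With n fixations total, n*p threat fixations of mean
# duration mu_t and n*(1-p) control fixations of mean mu_c:
#   n (p mu_t + (1-p) mu_c + g) = T,  n (p mu_t - (1-p) mu_c) = tau,
#   n (2p - 1) = cnt
# which solves to n = (T - tau + mu_c cnt) / (mu_c + g),
# p = (cnt/n + 1)/2, mu_t = (T - n g + tau) / (2 n p); m follows by
# inverting the realized-duration map.
.trial_params <- function(tau, cnt, cfg, cal) {
  dt <- 1000 / cfg$screen$sampling_rate_hz
  g <- cfg$saccade_gap_samples * dt
  cross <- if (cfg$cross_dwell_ms > 0)
    round(cfg$cross_dwell_ms / dt) * dt + g else 0
  T_eff <- cfg$slide_ms - cross
  mu_c <- cal$mu_control
  n <- (T_eff - tau + mu_c * cnt) / (mu_c + g)
  n <- max(n, 1.5)
  p <- min(max((cnt / n + 1) / 2, 0.02), 0.98)
  mu_t <- (T_eff - n * g + tau) / (2 * n * p)
  mu_t <- min(max(mu_t, cal$mu_range[1]), cal$mu_range[2])
  m <- cal$inv_mu(mu_t)
  list(p = p, m = m, n_expected = n)
}

# simulate the raw sample stream of one trial; returns samples + latent plan
.sim_trial_core <- function(cfg, cal, p, m, threat_side, inject = "none") {
  dt <- 1000 / cfg$screen$sampling_rate_hz
  n_total <- round(cfg$slide_ms / dt)
  gap <- cfg$saccade_gap_samples
  min_s <- cfg$detector$min_samples
  mg <- cfg$interior_margin_px
  jit <- cfg$jitter_sd_px
  a <- cfg$aois
  rects <- lapply(setNames(nm = a$name), function(nm) {
    i <- which(a$name == nm)
    c(a$x0[i], a$y0[i], a$x1[i], a$y1[i])
  })
  x <- rep(NA_real_, n_total); y <- rep(NA_real_, n_total)
  cap <- ceiling(n_total / (min_s + gap)) + 2L
  lat_target <- character(cap); lat_start <- integer(cap)
  lat_ns <- integer(cap); nl <- 0L
  pos <- 1L
  if (cfg$cross_dwell_ms > 0) {
    r <- rects[["cross"]]
    ns0 <- min(max(min_s, round(cfg$cross_dwell_ms / dt)), n_total)
    idx <- pos:(pos + ns0 - 1L)
    x[idx] <- (r[1] + r[3]) / 2 + rnorm(ns0, 0, jit)
    y[idx] <- (r[2] + r[4]) / 2 + rnorm(ns0, 0, jit)
    nl <- nl + 1L
    lat_target[nl] <- "cross"; lat_start[nl] <- pos; lat_ns[nl] <- ns0
    pos <- pos + ns0 + gap
  }
  other_side <- if (threat_side == "left") "right" else "left"
  cross_r <- rects[["cross"]]
  lmed <- log(cfg$fix_median_ms); lm_mult <- log(m)
  while (n_total - pos + 1L >= min_s) {
    threat <- if (inject == "b") TRUE else runif(1) < p
    dur <- rlnorm(1, if (threat) lmed + lm_mult else lmed, cfg$fix_sdlog)
    ns <- max(min_s, round(dur / dt))
    ns <- min(ns, n_total - pos + 1L)
    side <- if (threat) threat_side else other_side
    straddle <- inject == "a" ||
      (cfg$straddle_p > 0 && runif(1) < cfg$straddle_p)
    if (straddle) {
      ax <- if (side == "left") cross_r[1] else cross_r[3]
      ay <- runif(1, cross_r[2] + mg, cross_r[4] - mg)
      target <- paste0(side, "+cross")
    } else {
      r <- rects[[side]]
      ax <- runif(1, r[1] + mg, r[3] - mg)
      ay <- runif(1, r[2] + mg, r[4] - mg)
      target <- side
    }
    idx <- pos:(pos + ns - 1L)
    x[idx] <- ax + rnorm(ns, 0, jit)
    y[idx] <- ay + rnorm(ns, 0, jit)
    nl <- nl + 1L
    lat_target[nl] <- target; lat_start[nl] <- pos; lat_ns[nl] <- ns
    pos <- pos + ns + gap
  }
  if (cfg$track_loss_p > 0) {
    lost <- runif(n_total) < cfg$track_loss_p
    x[lost] <- NA; y[lost] <- NA
  }
  keep <- seq_len(nl)
  list(t = (seq_len(n_total) - 1L) * dt, x = x, y = y,
       latent = .fast_df(list(target = lat_target[keep],
                              start = lat_start[keep],
                              n_samples = lat_ns[keep])))
}

.recording_from_stream <- function(cfg, participant_id, slide_id, s) {
  n <- length(s$t)
  lx <- s$x - cfg$eye_offset_px; rx <- s$x + cfg$eye_offset_px
  ly <- s$y; ry <- s$y
  if (cfg$eye_loss_p > 0) {
    drop1 <- runif(n) < cfg$eye_loss_p & !is.na(s$x)
    which_eye <- runif(n) < 0.5
    lx[drop1 & which_eye] <- NA; ly[drop1 & which_eye] <- NA
    rx[drop1 & !which_eye] <- NA; ry[drop1 & !which_eye] <- NA
  }
  trial_recording(participant_id, slide_id, s$t, lx, ly, rx, ry)
}

# left/right fixation counts and times of one recording (fast path used by
# calibration and tests)
.trial_side_stats <- function(rec, detector, aois) {
  keep <- !is.na(rec$samples$mx)
  stream <- list(t = rec$samples$t[keep], x = rec$samples$mx[keep],
                 y = rec$samples$my[keep])
  fx <- detect_fixations(stream, detector)
  out <- c(left_n = 0, left_t = 0, right_n = 0, right_t = 0)
  if (!nrow(fx)) return(out)
  for (side in c("left", "right")) {
    i <- which(aois$name == side)
    inside <- stream$x >= aois$x0[i] & stream$x < aois$x1[i] &
      stream$y >= aois$y0[i] & stream$y < aois$y1[i]
    cs <- c(0, cumsum(inside))
    hit <- cs[fx$end_index + 1L] - cs[fx$start_index] > 0
    out[paste0(side, "_n")] <- sum(hit)
    out[paste0(side, "_t")] <- sum(fx$duration_ms[hit])
  }
  out
}

#' Calibrate the synthetic generator
#'
#' Deterministic calibration run once per configuration. The per-trial
#' target differences are first translated into a threat-side choice
#' probability and a threat dwell-duration multiplier by a closed-form
#' occupancy argument (see the package vignette); because that translation
#' is approximate (duration rounding, trial-end truncation, saturation at
#' extreme targets) it is then corrected empirically in two pre-run passes
#' per design cell:
#' \enumerate{
#'   \item a noise-free pass measures the intrinsic SD of the
#'     fixation-process noise (`sigma0`) and the first-order mean bias;
#'   \item the extra trial-level noise is sized so the *total* residual SD
#'     of the time difference equals
#'     `resid_sd_ms * nat_resid_mult[nationality]`, and a second pass run
#'     *with* that noise absorbs the remaining (nonlinearity-induced) mean
#'     bias into additive target corrections and rescales the added noise
#'     for response saturation.
#' }
#'
#' @param cfg a [generator_config()].
#' @param n_prerun trials per cell in the noise-free pass (the noisy pass
#'   uses three times as many to pin the mean corrections down).
#' @param seed internal seed of the pre-runs (independent of cohort seeds).
#' @return `cfg` with a `calibration` element attached.
#' @export
calibrate_generator <- function(cfg, n_prerun = 200L, seed = 760321L) {
  stopifnot(inherits(cfg, "generator_config"))
  m_grid <- exp(seq(log(0.05), log(12), length.out = 181))
  mu_grid <- vapply(m_grid, .mean_real_dur, 0, cfg = cfg)
  keep <- !duplicated(mu_grid)
  inv_mu <- stats::approxfun(mu_grid[keep], m_grid[keep], rule = 2)
  cal <- list(mu_control = .mean_real_dur(1, cfg),
              mu_range = range(mu_grid), inv_mu = inv_mu)
  combos <- merge(cfg$bias_time_ms, cfg$bias_count,
                  by = c("pair_type", "nationality", "gender"),
                  suffixes = c("_time", "_count"))
  names(combos)[names(combos) == "value_time"] <- "tau"
  names(combos)[names(combos) == "value_count"] <- "cnt"
  combos <- combos[order(combos$pair_type, combos$nationality,
                         combos$gender), ]

  # per-trial differences among trials that survive the curation rules --
  # the pipeline estimates post-curation cell means, and rule (b)
  # preferentially removes one-sided trials, so targets are matched on the
  # surviving distribution
  measure <- function(tau_c, cnt_c, noise_sd, n_rep) {
    d_time <- numeric(n_rep); d_count <- numeric(n_rep); kept <- 0L
    for (r in seq_len(n_rep)) {
      tau_r <- tau_c + if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
      pr <- .trial_params(tau_r, cnt_c, cfg, cal)
      side <- if (r %% 2L == 0L) "left" else "right"
      s <- .sim_trial_core(cfg, cal, pr$p, pr$m, side)
      rec <- .recording_from_stream(cfg, "cal", "cal", s)
      st <- .trial_side_stats(rec, cfg$detector, cfg$aois)
      if (st["left_n"] == 0 || st["right_n"] == 0) next
      kept <- kept + 1L
      sgn <- if (side == "left") 1 else -1
      d_time[kept] <- sgn * (st["left_t"] - st["right_t"])
      d_count[kept] <- sgn * (st["left_n"] - st["right_n"])
    }
    if (kept < 20L)
      stop("calibration: fewer than 20 of ", n_rep, " pre-run trials ",
           "survive curation; targets are too extreme for the trial ",
           "duration")
    d_time <- d_time[seq_len(kept)]; d_count <- d_count[seq_len(kept)]
    c(mean_t = mean(d_time), sd_t = sd(d_time), mean_c = mean(d_count),
      sd_c = sd(d_count))
  }

  combos$mult <- as.numeric(cfg$nat_resid_mult[combos$nationality])
  ckey <- paste(combos$tau, combos$cnt, combos$mult)
  ukey <- unique(ckey)
  res_u <- .with_seed(seed, {
    lapply(ukey, function(key) {
      i <- match(key, ckey)
      tau <- combos$tau[i]; cnt <- combos$cnt[i]
      target_tot <- cfg$resid_sd_ms * combos$mult[i]
      # pass 1: intrinsic noise and first-order bias
      p1 <- measure(tau, cnt, 0, n_prerun)
      sigma0 <- p1["sd_t"]
      tau1 <- tau + (tau - p1["mean_t"])
      cnt1 <- cnt + (cnt - p1["mean_c"])
      sigma_add <- sqrt(max(0, target_tot^2 - sigma0^2))
      short <- target_tot < sigma0
      # pass 2: fixed-point iteration updating the mean corrections and
      # (when extra noise is present) the added-noise SD jointly -- the
      # realized post-curation difference responds with slope below 1 and
      # saturates for extreme per-trial targets
      for (k in seq_len(5L)) {
        pk <- measure(tau1, cnt1, sigma_add, 3L * n_prerun)
        mean_ok <- abs(pk["mean_t"] - tau) < 0.05 * max(target_tot, 400)
        sd_ok <- sigma_add == 0 ||
          abs(pk["sd_t"] - target_tot) / target_tot < 0.03
        if (mean_ok && sd_ok && k > 1L) break
        tau1 <- tau1 + (tau - pk["mean_t"])
        cnt1 <- cnt1 + (cnt - pk["mean_c"])
        if (sigma_add > 0 && !sd_ok) {
          excess <- max(pk["sd_t"]^2 - sigma0^2, (0.2 * sigma_add)^2)
          step <- sqrt((target_tot^2 - sigma0^2) / excess)
          sigma_add <- sigma_add * min(max(step, 0.7), 1.5)
        }
      }
      # pass 3: final mean correction at the converged noise level
      p3 <- measure(tau1, cnt1, sigma_add, 10L * n_prerun)
      c(tau_adj = unname(tau1 + (tau - p3["mean_t"])),
        cnt_adj = unname(cnt1 + (cnt - p3["mean_c"])),
        sigma0 = unname(sigma0), sigma_add = unname(sigma_add),
        target_total_sd = max(target_tot, sigma0),
        sigma0_count = unname(p1["sd_c"]), short = unname(short))
    })
  })
  stats_df <- do.call(rbind, res_u)[match(ckey, ukey), , drop = FALSE]
  if (any(stats_df[, "short"] > 0))
    warning(sum(stats_df[, "short"]), " cell(s) have target residual SD ",
            "below the intrinsic fixation-process SD; extra noise set to ",
            "0 there", call. = FALSE)
  for (col in c("tau_adj", "cnt_adj", "sigma0", "sigma_add",
                "target_total_sd", "sigma0_count"))
    combos[[col]] <- stats_df[, col]
  cfg$calibration <- list(cal = cal, cells = combos,
                          n_prerun = as.integer(n_prerun), seed = seed)
  cfg
}

#' Simulate one trial
#'
#' Generates the gaze recording of one participant viewing one slide, with
#' the attentional bias of the participant's design cell. Randomness is
#' taken from the current RNG stream.
#'
#' @param cfg a calibrated [generator_config()] (calibration is computed on
#'   the fly if absent).
#' @param participant a list or one-row data frame with `participant_id`,
#'   `nationality`, `gender` and optionally `b_i` (participant-level shift
#'   of the time difference, default 0).
#' @param slide one row of a schedule slide table (needs `pair_id`,
#'   `pair_type`, `left_category`).
#' @param inject `"none"`, `"a"` or `"b"`: optionally plant a
#'   curation-violating trial.
#' @return A list with the `recording` (a `trial_recording`) and `latent`
#'   (the planted fixation plan: target, first sample index, length).
#' @export
simulate_trial <- function(cfg, participant, slide, inject = "none") {
  if (is.null(cfg$calibration)) cfg <- calibrate_generator(cfg)
  cells <- cfg$calibration$cells
  i <- which(cells$pair_type == as.character(slide$pair_type) &
               cells$nationality == participant$nationality &
               cells$gender == participant$gender)
  if (length(i) != 1L)
    stop("no calibrated cell for ", slide$pair_type, " / ",
         participant$nationality, " / ", participant$gender)
  b_i <- if (!is.null(participant$b_i)) participant$b_i else 0
  tau <- cells$tau_adj[i] + b_i + rnorm(1, 0, cells$sigma_add[i])
  pr <- .trial_params(tau, cells$cnt_adj[i], cfg, cfg$calibration$cal)
  focal <- .pair_first[as.character(slide$pair_type)]
  threat_side <- if (slide$left_category == focal) "left" else "right"
  s <- .sim_trial_core(cfg, cfg$calibration$cal, pr$p, pr$m, threat_side,
                       inject = inject)
  rec <- .recording_from_stream(cfg, participant$participant_id,
                                slide$pair_id, s)
  list(recording = rec, latent = s$latent, threat_side = threat_side)
}

#' Simulate a full cohort
#'
#' Generates a complete synthetic dataset ready for the analysis pipeline:
#' a roster, a seeded presentation schedule (with its reversed version
#' assigned to every other participant in each design cell), one recording
#' per participant x slide, and the exported ground truth (per-cell true
#' differences, participant effects, per-nationality total residual SDs,
#' planted invalid trials and, optionally, every trial's latent fixation
#' plan). Byte-identical output for identical seed and configuration.
#'
#' @param cfg a [generator_config()]; calibrated on the fly if needed
#'   (calibrate once and reuse when simulating many cohorts).
#' @param seed integer seed; all randomness derives from it.
#' @param keep_latent store per-trial latent fixation plans in the ground
#'   truth.
#' @return An object of class `gaze_cohort`: list with `recordings`,
#'   `roster`, `schedule`, `schedule_reversed`, `truth`, `config`, `seed`.
#' @export
simulate_cohort <- function(cfg = generator_config(), seed = 1L,
                            keep_latent = TRUE) {
  if (is.null(cfg$calibration)) cfg <- calibrate_generator(cfg)
  .with_seed(seed, {
    images <- stimulus_images()
    slides <- mirror_pairs(build_pairs(images))
    sched <- make_schedule(slides, seed = sample.int(2^30, 1L),
                           slide_ms = cfg$slide_ms)
    sched_rev <- reverse_schedule(sched)

    pc <- cfg$participant_counts
    roster <- do.call(rbind, lapply(seq_len(nrow(pc)), function(i)
      if (pc$n[i] > 0)
        data.frame(nationality = pc$nationality[i], gender = pc$gender[i],
                   idx = seq_len(pc$n[i]), stringsAsFactors = FALSE)))
    roster$participant_id <- sprintf("p%03d", seq_len(nrow(roster)))
    age_mu <- ifelse(roster$nationality == "Somali", 22.2, 24.3)
    age_lo <- ifelse(roster$nationality == "Somali", 19, 18)
    age_hi <- ifelse(roster$nationality == "Somali", 39, 44)
    roster$age <- pmin(pmax(round(rnorm(nrow(roster), age_mu, 3.5)),
                            age_lo), age_hi)
    roster$schedule_version <- ifelse(roster$idx %% 2L == 1L, "original",
                                      "reversed")
    roster$b_i <- rnorm(nrow(roster), 0, cfg$participant_sd_ms)
    roster$idx <- NULL
    roster <- roster[, c("participant_id", "nationality", "gender", "age",
                         "schedule_version", "b_i")]

    cells <- cfg$calibration$cells
    ra <- cfg$inject_a_rate; rb <- cfg$inject_b_rate
    recordings <- vector("list", nrow(roster) * nrow(sched$slides))
    latent <- if (keep_latent) vector("list", length(recordings))
    inj_pid <- character(0); inj_slide <- character(0); inj_type <-
      character(0)
    k <- 0L
    for (pi in seq_len(nrow(roster))) {
      p <- roster[pi, ]
      sl <- if (p$schedule_version == "original") sched$slides
            else sched_rev$slides
      for (si in seq_len(nrow(sl))) {
        slide <- sl[si, ]
        u <- runif(1)
        inject <- if (u < ra) "a" else if (u < ra + rb) "b" else "none"
        if (inject != "none") {
          inj_pid <- c(inj_pid, p$participant_id)
          inj_slide <- c(inj_slide, slide$pair_id)
          inj_type <- c(inj_type, inject)
        }
        tr <- simulate_trial(cfg, p, slide, inject = inject)
        k <- k + 1L
        recordings[[k]] <- tr$recording
        if (keep_latent) latent[[k]] <- tr$latent
      }
    }
    if (keep_latent)
      names(latent) <- vapply(recordings, function(r)
        paste(r$participant_id, r$slide_id, sep = "\r"), "")
    truth <- list(
      bias_time_ms = cfg$bias_time_ms, bias_count = cfg$bias_count,
      participant_effects = roster[, c("participant_id", "b_i")],
      resid_sd = unique(cells[, c("nationality", "target_total_sd")]),
      cells = cells,
      injected = data.frame(participant_id = inj_pid,
                            slide_id = inj_slide, type = inj_type,
                            stringsAsFactors = FALSE),
      latent = if (keep_latent) latent)
    structure(list(recordings = recordings,
                   roster = roster[, setdiff(names(roster), "b_i")],
                   schedule = sched, schedule_reversed = sched_rev,
                   truth = truth, config = cfg, seed = seed),
              class = "gaze_cohort")
  })
}

#' @export
print.gaze_cohort <- function(x, ...) {
  cat(sprintf(
    "<gaze_cohort> %d participants x %d slides = %d recordings (seed %s)\n",
    nrow(x$roster), nrow(x$schedule$slides), length(x$recordings),
    x$seed))
  cat(sprintf("  planted invalid trials: a=%d, b=%d\n",
              sum(x$truth$injected$type == "a"),
              sum(x$truth$injected$type == "b")))
  invisible(x)
}

#' Score parameter recovery against ground truth
#'
#' Compares estimates (optionally from many replicate analyses) with the
#' generator's true values: per-parameter bias, root-mean-square error and,
#' when interval bounds are supplied, empirical CI coverage.
#'
#' @param truth named numeric vector of true values.
#' @param reports a data frame with columns `name, estimate` (optionally
#'   `lower, upper`), or a list of such data frames (one per replicate).
#' @return Data frame with one row per parameter: `name, truth, mean_est,
#'   bias, rmse, coverage, n_reports`.
#' @export
score_recovery <- function(truth, reports) {
  stopifnot(is.numeric(truth), !is.null(names(truth)))
  if (is.data.frame(reports)) reports <- list(reports)
  for (r in reports) {
    if (!all(c("name", "estimate") %in% names(r)))
      stop("each report needs 'name' and 'estimate' columns")
    if (!setequal(r$name, names(truth)))
      stop("mismatched truth/report keys: truth has {",
           paste(names(truth), collapse = ", "), "}, report has {",
           paste(r$name, collapse = ", "), "}")
  }
  out <- lapply(names(truth), function(nm) {
    est <- vapply(reports, function(r) r$estimate[r$name == nm][1], 0)
    cover <- if (all(c("lower", "upper") %in% names(reports[[1]]))) {
      mean(vapply(reports, function(r) {
        i <- which(r$name == nm)[1]
        r$lower[i] <= truth[[nm]] && truth[[nm]] <= r$upper[i]
      }, TRUE))
    } else NA_real_
    data.frame(name = nm, truth = truth[[nm]], mean_est = mean(est),
               bias = mean(est) - truth[[nm]],
               rmse = sqrt(mean((est - truth[[nm]])^2)),
               coverage = cover, n_reports = length(reports),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# light-weight data.frame constructor (no checks, no string conversion)
.fast_df <- function(cols) {
  n <- length(cols[[1]])
  structure(cols, class = "data.frame", row.names = c(NA_integer_, -n))
}
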