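# construct curated-style per-animal observations directly (bypassing the
# gaze layer) so model behaviour can be tested fast against known truth
mk_curated <- function(n_per_cell = 6, seed = 1, b_sd = 100, e_sd = 200,
                       animal_means = c(spider = 2000, scorpion = 2300,
                                        grasshopper = 1700)) {
  set.seed(seed)
  cells <- expand.grid(nationality = c("Somali", "Czech"),
                       gender = c("woman", "man"),
                       stringsAsFactors = FALSE)
  rows <- list()
  pid <- 0
  for (ci in seq_len(nrow(cells))) for (r in seq_len(n_per_cell)) {
    pid <- pid + 1
    b <- rnorm(1, 0, b_sd)
    for (bp in sprintf("bp%02d", 1:6)) for (an in names(animal_means)) {
      pt <- if (an == "grasshopper") "scorpion-grasshopper"
            else "scorpion-spider"
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = sprintf("p%03d", pid), base_pair_id = bp,
        pair_type = pt, animal = an,
        n_fixations = rpois(1, 8), fixation_time_ms =
          animal_means[[an]] + b + rnorm(1, 0, e_sd),
        n_fix_sum = rpois(1, 16), n_slides = 2L, weight = 1,
        w_inv = 1, role = "first",
        nationality = cells$nationality[ci], gender = cells$gender[ci],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$animal <- factor(out$animal, c("spider", "scorpion", "grasshopper"))
  out$nationality <- factor(out$nationality, c("Somali", "Czech"))
  out$gender <- factor(out$gender, c("woman", "man"))
  out
}

mk_diffs <- function(n_per_cell = 10, seed = 1, b_sd = 100,
                     e_sd = c(Somali = 300, Czech = 300),
                     cell_means = NULL, half_frac = 0) {
  set.seed(seed)
  pts <- c("spider-grasshopper", "scorpion-grasshopper", "scorpion-spider")
  cells <- expand.grid(nationality = c("Somali", "Czech"),
                       gender = c("woman", "man"),
                       stringsAsFactors = FALSE)
  if (is.null(cell_means)) {
    cell_means <- expand.grid(pair_type = pts,
                              nationality = c("Somali", "Czech"),
                              gender = c("woman", "man"),
                              stringsAsFactors = FALSE)
    cell_means$value <- 0
  }
  rows <- list(); pid <- 0
  for (ci in seq_len(nrow(cells))) for (r in seq_len(n_per_cell)) {
    pid <- pid + 1
    b <- rnorm(1, 0, b_sd)
    for (bp in 1:18) {
      pt <- pts[(bp - 1) %% 3 + 1]
      mu <- cell_means$value[cell_means$pair_type == pt &
        cell_means$nationality == cells$nationality[ci] &
        cell_means$gender == cells$gender[ci]]
      w <- if (runif(1) < half_frac) 0.5 else 1
      sd_i <- e_sd[[cells$nationality[ci]]] / sqrt(w)
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = sprintf("p%03d", pid),
        base_pair_id = sprintf("bp%02d", bp), pair_type = pt,
        d_fix_count = rnorm(1, 0, 2),
        d_fix_time_ms = mu + b + rnorm(1, 0, sd_i),
        weight = w, w_inv = 1 / w,
        nationality = cells$nationality[ci], gender = cells$gender[ci],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$pair_type <- factor(out$pair_type, pts)
  out$nationality <- factor(out$nationality, c("Somali", "Czech"))
  out$gender <- factor(out$gender, c("woman", "man"))
  out
}

test_that("difference records follow the first-minus-second sign
          convention", {
  cu <- mk_curated(n_per_cell = 1, seed = 2)
  # build a minimal curated pair by hand
  cu2 <- cu[cu$participant_id == "p001" & cu$base_pair_id == "bp01", ]
  cu2 <- cu2[cu2$animal %in% c("scorpion", "spider"), ]
  cu2$pair_type <- "scorpion-spider"
  cu2$role <- ifelse(cu2$animal == "scorpion", "first", "second")
  cu2$fixation_time_ms <- c(2400, 2000)[match(cu2$animal,
                                              c("scorpion", "spider"))]
  cu2$n_fixations <- c(9, 9)[match(cu2$animal, c("scorpion", "spider"))]
  d <- compute_differences(cu2)
  expect_equal(d$d_fix_time_ms, 400)
  expect_equal(d$d_fix_count, 0)  # equal attention -> zero difference
  # swapping the roles negates every difference
  cu3 <- cu2
  cu3$role <- ifelse(cu2$role == "first", "second", "first")
  expect_equal(compute_differences(cu3)$d_fix_time_ms,
               -d$d_fix_time_ms)
  # a missing second-animal metric is an error
  expect_error(compute_differences(cu2[cu2$role == "first", ]),
               "missing metric")
})

test_that("with unit weights and one nationality the weighted model
          collapses to an ordinary random-intercept fit", {
  d <- mk_diffs(n_per_cell = 8, seed = 3)
  d <- d[d$nationality == "Somali", ]
  expect_warning(
    fit <- fit_gaze_model(d, "d_fix_time_ms", c("pair_type", "gender"),
                          var_nationality = TRUE, var_weight = TRUE),
    "variance multiplier dropped")
  plain <- nlme::lme(d_fix_time_ms ~ pair_type * gender,
                     random = ~ 1 | participant_id, data = d,
                     method = "REML")
  expect_equal(coef(fit), nlme::fixef(plain), tolerance = 1e-6)
  expect_equal(as.numeric(logLik(fit)), as.numeric(logLik(plain)),
               tolerance = 1e-6)
})

test_that("the per-nationality variance multiplier recovers a planted 2x
          residual SD ratio and inverse-weight scaling is honoured", {
  d <- mk_diffs(n_per_cell = 25, seed = 4,
                e_sd = c(Somali = 300, Czech = 600), half_frac = 0.2)
  fit <- fit_difference_model(d, "d_fix_time_ms")
  r <- nat_sd_ratio(fit)
  expect_equal(unname(r["Somali"]), 1)
  expect_gt(unname(r["Czech"]), 1.8)
  expect_lt(unname(r["Czech"]), 2.25)
  # the fitted residual SD refers to weight-1 observations
  expect_equal(fit$model$sigma, 300, tolerance = 0.08 * 300)
})

test_that("cell means are equivariant under shifting every difference by a
          constant", {
  d <- mk_diffs(n_per_cell = 5, seed = 5)
  f1 <- fit_difference_model(d, "d_fix_time_ms")
  d2 <- d
  d2$d_fix_time_ms <- d2$d_fix_time_ms + 500
  f2 <- fit_difference_model(d2, "d_fix_time_ms")
  z1 <- test_differences_against_zero(f1)
  z2 <- test_differences_against_zero(f2)
  expect_equal(z2$estimate, z1$estimate + 500, tolerance = 1e-6)
})

test_that("direct cell predictions agree with emmeans to numerical
          precision", {
  d <- mk_diffs(n_per_cell = 5, seed = 6, half_frac = 0.15)
  fit <- fit_difference_model(d, "d_fix_time_ms")
  z <- test_differences_against_zero(fit)
  emm <- as.data.frame(summary(emmeans::emmeans(
    fit$model, c("pair_type", "nationality", "gender"), data = fit$data),
    infer = c(TRUE, TRUE)))
  key_z <- paste(z$pair_type, z$nationality, z$gender)
  key_e <- paste(emm$pair_type, emm$nationality, emm$gender)
  m <- match(key_e, key_z)
  expect_equal(z$estimate[m], emm$emmean, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(z$SE[m], emm$SE, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("Tukey post hoc contrasts equal differences of estimated
          marginal means, three per stratum", {
  cu <- mk_curated(n_per_cell = 4, seed = 7)
  fit <- fit_total_metric_model(cu)
  ph <- posthoc_contrasts(fit, "animal", by = "nationality")
  expect_equal(nrow(ph$contrasts), 6L)  # 3 contrasts x 2 strata
  for (i in seq_len(nrow(ph$contrasts))) {
    cc <- ph$contrasts[i, ]
    lv <- strsplit(as.character(cc$contrast), " - ")[[1]]
    means <- ph$means[ph$means$nationality == cc$nationality, ]
    expect_equal(cc$estimate,
                 means$emmean[means$animal == lv[1]] -
                   means$emmean[means$animal == lv[2]],
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_error(posthoc_contrasts(fit, "age"), "not in the fitted model")
})

test_that("backward reduction drops an absent interaction, keeps a strong
          one, respects marginality and returns minimal models
          unchanged", {
  # strong animal x nationality pattern, no gender involvement
  set.seed(8)
  keep_int <- 0; drop3 <- 0; marg_ok <- TRUE
  reps <- 15
  for (r in seq_len(reps)) {
    cu <- mk_curated(n_per_cell = 5, seed = 100 + r, e_sd = 150)
    boost <- cu$nationality == "Somali" & cu$animal == "scorpion"
    cu$fixation_time_ms <- cu$fixation_time_ms + ifelse(boost, 400, 0)
    fit <- reduce_model(fit_total_metric_model(cu))
    terms_final <- attr(terms(as.formula(paste("~", fit$rhs))),
                        "term.labels")
    if ("animal:nationality" %in% terms_final) keep_int <- keep_int + 1
    if (!"animal:nationality:gender" %in% terms_final) drop3 <- drop3 + 1
    if ("animal:nationality" %in% terms_final &&
        !all(c("animal", "nationality") %in% terms_final))
      marg_ok <- FALSE
  }
  expect_gte(keep_int, 13)
  # the drop gate is p > alpha AND no AIC worsening; for the df-2 three-way
  # term the AIC side binds, so a null interaction is retained with
  # probability about P(chisq2 > 4) ~ 0.14
  expect_gte(drop3, 10)
  expect_true(marg_ok)
  # a minimal model whose only term is clearly needed is returned unchanged
  cm <- expand.grid(pair_type = c("spider-grasshopper",
                                  "scorpion-grasshopper",
                                  "scorpion-spider"),
                    nationality = c("Somali", "Czech"),
                    gender = c("woman", "man"), stringsAsFactors = FALSE)
  cm$value <- c("spider-grasshopper" = 0, "scorpion-grasshopper" = 800,
                "scorpion-spider" = 400)[cm$pair_type]
  d <- mk_diffs(n_per_cell = 6, seed = 9, cell_means = cm)
  f <- fit_gaze_model(d, "d_fix_time_ms", "pair_type",
                      var_nationality = FALSE, var_weight = FALSE)
  f2 <- reduce_model(f)
  expect_equal(f2$rhs, "pair_type")
  expect_s3_class(f2$reduction$full_vs_final, "data.frame")
})

test_that("the Poisson count model validates its response, needs a
          two-level design and recovers a planted rate ratio", {
  cu <- mk_curated(n_per_cell = 6, seed = 10)
  bad <- cu
  bad$n_fix_sum <- bad$n_fix_sum + 0.5
  expect_error(fit_count_model(bad), "non-negative integers")
  one_level <- cu[cu$animal == "spider", ]
  one_level$animal <- droplevels(one_level$animal)
  expect_error(fit_gaze_model(one_level, "n_fix_sum", "animal",
                              family = "poisson"), "degenerate design")
  # planted scorpion:grasshopper rate ratio 1.3
  set.seed(11)
  lam <- c(spider = 16, scorpion = 16 * 1.3, grasshopper = 16)
  cu$n_fix_sum <- rpois(nrow(cu), lam[as.character(cu$animal)])
  fit <- fit_count_model(cu)
  cf <- coef(fit)
  est_rr <- exp(cf[["animalgrasshopper"]] - cf[["animalscorpion"]])
  expect_equal(1 / est_rr, 1.3, tolerance = 0.12)
  expect_equal(fit$family, "poisson")
  # half-weight observations are excluded from the analysed subset
  cu$weight[1:30] <- 0.5
  fit2 <- fit_count_model(cu)
  expect_equal(nrow(fit2$data), nrow(cu) - 30)
})

test_that("null effects stay non-significant at roughly the nominal rate
          in reduction and Tukey contrasts", {
  set.seed(12)
  n_reject <- 0; fwer_hits <- 0; reps <- 20
  for (r in 1:reps) {
    cu <- mk_curated(n_per_cell = 4, seed = 200 + r,
                     animal_means = c(spider = 2000, scorpion = 2000,
                                      grasshopper = 2000))
    fit <- fit_gaze_model(cu, "fixation_time_ms", "animal",
                          var_nationality = FALSE, var_weight = FALSE)
    an <- anova(fit$model, type = "marginal")
    if (an["animal", "p-value"] < 0.05) n_reject <- n_reject + 1
    ph <- posthoc_contrasts(fit, "animal")
    if (any(ph$contrasts$p.value < 0.05)) fwer_hits <- fwer_hits + 1
  }
  expect_lte(n_reject / reps, 0.2)
  expect_lte(fwer_hits / reps, 0.2)
})

test_that("model reports serialize to JSON", {
  d <- mk_diffs(n_per_cell = 3, seed = 13)
  fit <- reduce_model(fit_difference_model(d, "d_fix_time_ms"))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_report(fit, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$response, "d_fix_time_ms")
  expect_true(!is.null(rep$coefficients))
  expect_true(!is.null(rep$reduction$full_vs_final))
})
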