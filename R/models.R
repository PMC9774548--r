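#' Per-pair difference responses
#'
#' Converts curated per-animal observations into one difference record per
#' participant x base pair: the first-named animal's metric minus the
#' second-named one's, for both fixation counts and fixation time. The sign
#' convention is spider-grasshopper, scorpion-grasshopper, scorpion-spider:
#' positive values mean more attention on the (putatively more threatening)
#' first-named animal.
#'
#' @param curated data frame from [average_mirror_pairs()].
#' @return Data frame with columns `participant_id, base_pair_id,
#'   pair_type, d_fix_count, d_fix_time_ms, weight, w_inv` plus any
#'   participant covariates present in the input.
#' @export
compute_differences <- function(curated) {
  f <- curated[curated$role == "first", , drop = FALSE]
  s <- curated[curated$role == "second", , drop = FALSE]
  key_f <- paste(f$participant_id, f$base_pair_id, sep = "\r")
  key_s <- paste(s$participant_id, s$base_pair_id, sep = "\r")
  m <- match(key_f, key_s)
  if (anyNA(m))
    stop("missing metric for the second-named animal of base pair(s): ",
         paste(unique(f$base_pair_id[is.na(m)]), collapse = ", "))
  out <- data.frame(participant_id = f$participant_id,
                    base_pair_id = f$base_pair_id,
                    pair_type = f$pair_type,
                    d_fix_count = f$n_fixations - s$n_fixations[m],
                    d_fix_time_ms = f$fixation_time_ms -
                      s$fixation_time_ms[m],
                    weight = f$weight, w_inv = f$w_inv,
                    stringsAsFactors = FALSE)
  for (col in intersect(c("nationality", "gender", "age"), names(curated)))
    out[[col]] <- f[[col]]
  rownames(out) <- NULL
  out
}

#' Fit a weighted mixed-effects attention model
#'
#' The central fitting routine behind [fit_total_metric_model()],
#' [fit_count_model()] and [fit_difference_model()]. Gaussian responses are
#' fitted with `nlme::lme` with a participant random intercept and, when
#' requested, the residual variance model
#' \deqn{Var(\epsilon_{ij}) = \sigma^2 \, \delta^2_{nat(i)} / w_{ij},}
#' i.e. a per-nationality variance multiplier (`nlme::varIdent`, reference
#' level fixed at 1) combined with inverse observation-weight scaling
#' (`nlme::varFixed` on `w_inv = 1/weight`). Poisson responses are fitted
#' with `lme4::glmer` (log link, Laplace approximation); no weight-based
#' variance structure exists for that family, so callers restrict the data
#' to full-weight observations instead.
#'
#' @param data model frame; must contain `participant_id`, the response and
#'   all fixed-effect variables (and `nationality`, `w_inv` as applicable).
#' @param response response column name.
#' @param fixed character vector of fixed-effect variables, crossed with all
#'   interactions when `interactions = TRUE`; alternatively a full RHS
#'   string such as `"animal * nationality + gender"`.
#' @param family `"gaussian"` or `"poisson"`.
#' @param var_nationality use the per-nationality variance multiplier
#'   (gaussian only; dropped with a warning when fewer than two nationality
#'   levels are present).
#' @param var_weight use inverse-weight residual variance scaling (gaussian
#'   only).
#' @param interactions cross the `fixed` variables (`*`) or add them (`+`).
#' @param method `"REML"` (reported estimates) or `"ML"` (model comparison).
#' @return An object of class `gazefit`; see [print.gazefit()].
#' @export
fit_gaze_model <- function(data, response, fixed,
                           family = c("gaussian", "poisson"),
                           var_nationality = TRUE, var_weight = TRUE,
                           interactions = TRUE,
                           method = c("REML", "ML")) {
  family <- match.arg(family)
  method <- match.arg(method)
  stopifnot(is.data.frame(data), response %in% names(data),
            "participant_id" %in% names(data))
  rhs <- if (length(fixed) > 1L)
    paste(fixed, collapse = if (interactions) " * " else " + ")
  else fixed
  fvars <- all.vars(as.formula(paste("~", rhs)))
  missing_vars <- setdiff(fvars, names(data))
  if (length(missing_vars))
    stop("fixed-effect variable(s) absent from data: ",
         paste(missing_vars, collapse = ", "))
  for (v in fvars)
    if (is.factor(data[[v]]) && nlevels(droplevels(data[[v]])) < 2L)
      stop("degenerate design: factor '", v,
           "' has fewer than 2 observed levels")
  if (family == "poisson") {
    y <- data[[response]]
    if (any(is.na(y)) || any(y < 0) || any(y != round(y)))
      stop("Poisson response '", response,
           "' must be non-negative integers")
    fit <- .glmer_fit(response, rhs, data)
    var_desc <- "none (Poisson family)"
  } else {
    if (var_nationality &&
        (!"nationality" %in% names(data) ||
         nlevels(droplevels(factor(data$nationality))) < 2L)) {
      warning("fewer than 2 nationality levels; ",
              "per-nationality variance multiplier dropped", call. = FALSE)
      var_nationality <- FALSE
    }
    if (var_weight && !"w_inv" %in% names(data)) {
      if ("weight" %in% names(data)) data$w_inv <- 1 / data$weight
      else var_weight <- FALSE
    }
    fit <- .lme_fit(response, rhs, data, var_nationality, var_weight,
                    method)
    var_desc <- paste(c(
      if (var_nationality) "per-nationality multiplier (varIdent)",
      if (var_weight) "inverse observation weight (varFixed)",
      if (!var_nationality && !var_weight) "constant"), collapse = " x ")
  }
  structure(list(model = fit,
                 engine = if (family == "poisson") "glmer" else "lme",
                 family = family, response = response, rhs = rhs,
                 data = data, var_nationality = var_nationality,
                 var_weight = var_weight, var_desc = var_desc,
                 method = if (family == "poisson") "ML" else method,
                 reduction = NULL),
            class = "gazefit")
}

.lme_fit <- function(response, rhs, data, var_nationality, var_weight,
                     method) {
  fixed <- as.formula(paste(response, "~", rhs))
  environment(fixed) <- environment()
  parts <- list()
  if (var_nationality)
    parts <- c(parts, list(nlme::varIdent(form = ~ 1 | nationality)))
  if (var_weight)
    parts <- c(parts, list(nlme::varFixed(~ w_inv)))
  w <- if (length(parts) == 2L) do.call(nlme::varComb, parts)
       else if (length(parts) == 1L) parts[[1L]]
       else NULL
  ctrl <- nlme::lmeControl(maxIter = 100, msMaxIter = 100, niterEM = 50,
                           returnObject = FALSE)
  tryCatch(
    nlme::lme(fixed, random = ~ 1 | participant_id, data = data,
              weights = w, method = method, control = ctrl,
              na.action = stats::na.fail),
    error = function(e) stop("mixed-model fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
}

.glmer_fit <- function(response, rhs, data) {
  f <- as.formula(paste(response, "~", rhs, "+ (1 | participant_id)"))
  environment(f) <- environment()
  fit <- lme4::glmer(f, data = data, family = stats::poisson(link = "log"),
                     nAGQ = 1L,
                     control = lme4::glmerControl(
                       check.conv.singular = "ignore"))
  fit
}

#' Fit the total fixation metric model
#'
#' Mixed model for a per-animal total metric on curated observations:
#' fixed effects `animal * nationality * gender`, participant random
#' intercept, and the heteroscedastic residual structure of
#' [fit_gaze_model()] (per-nationality multiplier over inverse observation
#' weight). `fixation_time_ms` is fitted as gaussian by REML.
#'
#' @param curated data frame from [average_mirror_pairs()] with roster
#'   covariates joined.
#' @param response metric column (default total fixation time).
#' @param ... passed on to [fit_gaze_model()].
#' @return A `gazefit`.
#' @export
fit_total_metric_model <- function(curated, response = "fixation_time_ms",
                                   ...) {
  fit_gaze_model(curated, response,
                 fixed = c("animal", "nationality", "gender"),
                 family = "gaussian", ...)
}

#' Fit the Poisson fixation-count model
#'
#' Generalized linear mixed model (Poisson, log link, participant random
#' intercept) for the total number of fixations. Because no weight-based
#' variance structure exists for this family, only full mirror pairs are
#' analysed: the response is the integer sum of fixation counts over the two
#' side-swapped slides, and half-weight observations are excluded.
#'
#' @param curated data frame from [average_mirror_pairs()] with roster
#'   covariates.
#' @param ... passed on to [fit_gaze_model()].
#' @return A `gazefit` (the data slot holds the analysed full-pair subset).
#' @export
fit_count_model <- function(curated, ...) {
  full <- curated[curated$weight == 1, , drop = FALSE]
  if (!nrow(full)) stop("no full-weight observations to analyse")
  fit_gaze_model(full, "n_fix_sum",
                 fixed = c("animal", "nationality", "gender"),
                 family = "poisson", ...)
}

#' Fit a difference-response model
#'
#' Mixed model for the per-pair attentional-bias differences from
#' [compute_differences()]: fixed effects
#' `pair_type * nationality * gender`, participant random intercept, and the
#' same heteroscedastic variance structure as the total-metric model.
#'
#' @param differences data frame from [compute_differences()].
#' @param response `"d_fix_time_ms"` or `"d_fix_count"`.
#' @param ... passed on to [fit_gaze_model()].
#' @return A `gazefit`.
#' @export
fit_difference_model <- function(differences,
                                 response = c("d_fix_time_ms",
                                              "d_fix_count"), ...) {
  response <- match.arg(response)
  fit_gaze_model(differences, response,
                 fixed = c("pair_type", "nationality", "gender"),
                 family = "gaussian", ...)
}

#' Backward model reduction by LRT and AIC
#'
#' Simplifies the fixed-effects structure of a `gazefit` by backward
#' elimination starting from the highest-order interactions. At each step
#' every droppable term (marginality respected: a main effect is never
#' removed while part of a retained interaction) is tested by a
#' likelihood-ratio test between maximum-likelihood fits; a term is removed
#' only if it is non-significant at `alpha` *and* removal does not worsen
#' the AIC. Among removable terms the least significant is dropped first.
#' Gaussian models are refitted by REML at the end; the full-versus-final
#' likelihood ratio is recorded.
#'
#' @param object a `gazefit`.
#' @param alpha significance gate for the LRT (default 0.05).
#' @return The reduced `gazefit`, with a `reduction` element: `history`
#'   (one row per tested term) and `full_vs_final` (LRT of the final
#'   against the initial model).
#' @export
reduce_model <- function(object, alpha = 0.05) {
  stopifnot(inherits(object, "gazefit"))
  refit_ml <- function(rhs) .refit(object, rhs, method = "ML")
  cur_rhs <- object$rhs
  cur_ml <- refit_ml(cur_rhs)
  full_ml <- cur_ml
  history <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    scope <- drop.scope(as.formula(paste("~", cur_rhs)))
    if (!length(scope)) break
    cand <- lapply(scope, function(term) {
      red_rhs <- .drop_term(cur_rhs, term)
      red_ml <- refit_ml(red_rhs)
      lr <- as.numeric(2 * (logLik(cur_ml) - logLik(red_ml)))
      df <- attr(logLik(cur_ml), "df") - attr(logLik(red_ml), "df")
      list(term = term, rhs = red_rhs, fit = red_ml, lrt = lr, df = df,
           p = stats::pchisq(lr, df, lower.tail = FALSE),
           aic_full = AIC(cur_ml), aic_red = AIC(red_ml))
    })
    removable <- vapply(cand, function(c0)
      c0$p > alpha && c0$aic_red <= c0$aic_full, TRUE)
    pick <- if (any(removable))
      which.max(vapply(cand, function(c0)
        if (c0$p > alpha && c0$aic_red <= c0$aic_full) c0$p else -Inf,
        0)) else 0L
    history[[step]] <- data.frame(
      step = step,
      term = vapply(cand, `[[`, "", "term"),
      lrt = vapply(cand, `[[`, 0, "lrt"),
      df = vapply(cand, `[[`, 0, "df"),
      p = vapply(cand, `[[`, 0, "p"),
      aic_current = vapply(cand, `[[`, 0, "aic_full"),
      aic_reduced = vapply(cand, `[[`, 0, "aic_red"),
      dropped = seq_along(cand) == pick)
    if (pick == 0L) break
    cur_rhs <- cand[[pick]]$rhs
    cur_ml <- cand[[pick]]$fit
  }
  lr_ff <- as.numeric(2 * (logLik(full_ml) - logLik(cur_ml)))
  df_ff <- attr(logLik(full_ml), "df") - attr(logLik(cur_ml), "df")
  final <- if (object$family == "gaussian") .refit(object, cur_rhs, "REML")
           else .refit(object, cur_rhs, "ML")
  final$reduction <- list(
    history = if (length(history)) do.call(rbind, history) else NULL,
    full_vs_final = data.frame(
      lrt = lr_ff, df = df_ff,
      p = if (df_ff > 0) stats::pchisq(lr_ff, df_ff, lower.tail = FALSE)
          else NA_real_),
    full_rhs = object$rhs)
  final
}

.refit <- function(object, rhs, method) {
  fit_gaze_model(object$data, object$response, fixed = rhs,
                 family = object$family,
                 var_nationality = object$var_nationality,
                 var_weight = object$var_weight, method = method)
}

.drop_term <- function(rhs, term) {
  f <- update.formula(as.formula(paste("~", rhs)),
                      as.formula(paste("~ . -", term)))
  paste(deparse(f[[2]]), collapse = " ")
}

#' Tukey post hoc contrasts
#'
#' Pairwise comparisons of one fixed factor's levels, optionally within the
#' levels of grouping factors, on the final model: estimated marginal means
#' and Tukey-adjusted contrasts with 95% confidence intervals (via
#' \pkg{emmeans}).
#'
#' @param object a `gazefit`.
#' @param factor name of the factor to compare (e.g. `"animal"`).
#' @param by optional name(s) of stratifying factor(s) (e.g.
#'   `"nationality"`).
#' @param adjust p adjustment for the contrasts (default `"tukey"`).
#' @return A list of class `gaze_posthoc` with data frames `means` and
#'   `contrasts`.
#' @export
posthoc_contrasts <- function(object, factor, by = NULL,
                              adjust = "tukey") {
  stopifnot(inherits(object, "gazefit"))
  present <- all.vars(as.formula(paste("~", object$rhs)))
  if (!factor %in% present)
    stop("factor '", factor, "' is not in the fitted model")
  emm <- emmeans::emmeans(object$model, specs = reformulate(factor),
                          by = by, data = object$data)
  means <- as.data.frame(summary(emm, infer = c(TRUE, FALSE)))
  ctr <- emmeans::contrast(emm, method = "pairwise", adjust = adjust)
  contrasts <- as.data.frame(summary(ctr, infer = c(TRUE, TRUE)))
  structure(list(means = means, contrasts = contrasts, factor = factor,
                 by = by, adjust = adjust), class = "gaze_posthoc")
}

#' @export
print.gaze_posthoc <- function(x, ...) {
  cat(sprintf("Estimated marginal means for %s%s\n", x$factor,
              if (!is.null(x$by)) paste0(" by ",
                                         paste(x$by, collapse = ", "))
              else ""))
  print(x$means, row.names = FALSE)
  cat(sprintf("\nPairwise contrasts (%s-adjusted)\n", x$adjust))
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Test predicted cell means against zero
#'
#' For difference-response models: the model-predicted mean of every
#' stimuli-pair x nationality x gender cell (restricted to the factors
#' retained in the model), with a t test against zero and 95% confidence
#' interval. Positive estimates mean more attention on the first-named
#' animal of the pair.
#'
#' @param object a `gazefit` on a difference response.
#' @return A data frame of class `gaze_zero_tests`: one row per cell with
#'   `estimate, SE, df, lower.CL, upper.CL, t.ratio, p.value`.
#' @export
test_differences_against_zero <- function(object) {
  stopifnot(inherits(object, "gazefit"), object$engine == "lme")
  present <- intersect(c("pair_type", "nationality", "gender"),
                       all.vars(as.formula(paste("~", object$rhs))))
  if (!length(present)) stop("no design factors retained in the model")
  dat <- object$data
  grid <- expand.grid(lapply(setNames(nm = present), function(v)
    levels(droplevels(factor(dat[[v]])))), stringsAsFactors = TRUE)
  for (v in present)
    grid[[v]] <- factor(grid[[v]], levels(droplevels(factor(dat[[v]]))))
  tt <- stats::delete.response(terms(as.formula(paste(
    object$response, "~", object$rhs))))
  X <- stats::model.matrix(tt, grid, contrasts.arg = object$model$contrasts)
  beta <- nlme::fixef(object$model)
  X <- X[, names(beta), drop = FALSE]
  V <- object$model$varFix
  est <- drop(X %*% beta)
  se <- sqrt(rowSums((X %*% V) * X))
  # containment-style df: smallest denominator df among the coefficients
  # involved in each cell prediction
  fdf <- object$model$fixDF$X[names(beta)]
  df <- apply(X, 1, function(r) min(fdf[abs(r) > 1e-12]))
  tval <- est / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  ci <- stats::qt(0.975, df) * se
  out <- cbind(grid,
               data.frame(estimate = est, SE = se, df = df,
                          lower.CL = est - ci, upper.CL = est + ci,
                          t.ratio = tval, p.value = p))
  rownames(out) <- NULL
  class(out) <- c("gaze_zero_tests", "data.frame")
  out
}

#' Per-nationality residual standard-deviation multipliers
#'
#' Extracts the estimated `varIdent` multipliers (reference level fixed at
#' 1) from a gaussian `gazefit` with the per-nationality variance structure.
#'
#' @param object a `gazefit`.
#' @return Named numeric vector of SD multipliers, one per nationality
#'   level.
#' @export
nat_sd_ratio <- function(object) {
  stopifnot(inherits(object, "gazefit"), object$engine == "lme")
  if (!object$var_nationality)
    stop("model was fitted without the per-nationality variance structure")
  vs <- object$model$modelStruct$varStruct
  cf <- coef(vs, unconstrained = FALSE, allCoef = TRUE)
  # keep the varIdent coefficients (named by nationality level)
  lv <- levels(droplevels(factor(object$data$nationality)))
  keep <- names(cf) %in% c(lv, paste0("A.", lv))
  out <- cf[keep]
  names(out) <- sub("^A\\.", "", names(out))
  out
}

#' Export a machine-readable model report
#'
#' Writes the fitted fixed effects (with confidence intervals), marginal
#' tests, AIC/log-likelihood and, when present, the reduction history to a
#' JSON file.
#'
#' @param object a `gazefit`.
#' @param path output path.
#' @export
write_model_report <- function(object, path) {
  s <- summary(object)
  report <- list(
    response = object$response, family = object$family,
    fixed = paste("~", object$rhs), variance_structure = object$var_desc,
    method = object$method,
    logLik = as.numeric(logLik(object$model)),
    AIC = AIC(object$model),
    coefficients = cbind(term = rownames(s$coefficients),
                         as.data.frame(s$coefficients)),
    tests = if (!is.null(s$tests))
      cbind(term = rownames(s$tests), as.data.frame(s$tests)),
    reduction = if (!is.null(object$reduction))
      list(history = object$reduction$history,
           full_vs_final = object$reduction$full_vs_final))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
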