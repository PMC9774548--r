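#' Methods for fitted attention models
#'
#' A `gazefit` wraps the underlying engine fit (`nlme::lme` or
#' `lme4::glmer`) together with the model frame and the variance-structure
#' description. Standard extractors delegate to the engine.
#'
#' @param x,object a `gazefit`.
#' @param ... passed to the underlying method.
#' @name gazefit-methods
NULL

#' @rdname gazefit-methods
#' @export
print.gazefit <- function(x, ...) {
  cat(sprintf("<gazefit> %s model: %s ~ %s\n", x$family, x$response, x$rhs))
  cat(sprintf("  engine: %s (%s), random intercept per participant\n",
              x$engine, x$method))
  cat(sprintf("  residual variance: %s\n", x$var_desc))
  cat(sprintf("  n obs: %d, logLik: %.2f, AIC: %.2f\n",
              nrow(x$data), as.numeric(logLik(x$model)), AIC(x$model)))
  if (!is.null(x$reduction)) {
    ff <- x$reduction$full_vs_final
    cat(sprintf("  reduced from ~ %s (full vs final LRT %.3f, df %d, p = %.3g)\n",
                x$reduction$full_rhs, ff$lrt, ff$df, ff$p))
  }
  invisible(x)
}

#' @rdname gazefit-methods
#' @export
summary.gazefit <- function(object, ...) {
  if (object$engine == "lme") {
    sm <- summary(object$model)
    tt <- sm$tTable
    ci <- stats::qt(0.975, tt[, "DF"]) * tt[, "Std.Error"]
    coefs <- cbind(Estimate = tt[, "Value"], `Std.Error` = tt[, "Std.Error"],
                   lower = tt[, "Value"] - ci, upper = tt[, "Value"] + ci,
                   df = tt[, "DF"], statistic = tt[, "t-value"],
                   p.value = tt[, "p-value"])
    rownames(coefs) <- rownames(tt)
    tests <- as.data.frame(anova(object$model, type = "marginal"))
  } else {
    sm <- summary(object$model)
    cc <- sm$coefficients
    coefs <- cbind(Estimate = cc[, "Estimate"],
                   `Std.Error` = cc[, "Std. Error"],
                   lower = cc[, "Estimate"] - 1.96 * cc[, "Std. Error"],
                   upper = cc[, "Estimate"] + 1.96 * cc[, "Std. Error"],
                   df = NA, statistic = cc[, "z value"],
                   p.value = cc[, "Pr(>|z|)"])
    rownames(coefs) <- rownames(cc)
    tests <- NULL
  }
  out <- list(fit = object, coefficients = coefs, tests = tests,
              var_multipliers = if (isTRUE(object$var_nationality))
                tryCatch(nat_sd_ratio(object), error = function(e) NULL))
  class(out) <- "summary.gazefit"
  out
}

#' @export
print.summary.gazefit <- function(x, ...) {
  print(x$fit)
  cat("\nFixed effects:\n")
  print(round(x$coefficients, 4))
  if (!is.null(x$tests)) {
    cat("\nMarginal (type III style) tests:\n")
    print(x$tests)
  }
  if (!is.null(x$var_multipliers)) {
    cat("\nPer-nationality residual SD multipliers:\n")
    print(round(x$var_multipliers, 4))
  }
  invisible(x)
}

#' @rdname gazefit-methods
#' @export
coef.gazefit <- function(object, ...) {
  if (object$engine == "lme") nlme::fixef(object$model)
  else lme4::fixef(object$model)
}

#' @rdname gazefit-methods
#' @export
residuals.gazefit <- function(object, ...) residuals(object$model, ...)

#' @rdname gazefit-methods
#' @export
fitted.gazefit <- function(object, ...) fitted(object$model, ...)

#' @rdname gazefit-methods
#' @param newdata optional data frame for predictions; defaults to the
#'   model frame.
#' @param level grouping level passed to the engine (0 = population).
#' @export
predict.gazefit <- function(object, newdata = NULL, level = 0, ...) {
  if (is.null(newdata)) newdata <- object$data
  if (object$engine == "lme")
    predict(object$model, newdata = newdata, level = level, ...)
  else
    predict(object$model, newdata = newdata,
            re.form = if (level == 0) NA else NULL, ...)
}

#' @rdname gazefit-methods
#' @export
logLik.gazefit <- function(object, ...) logLik(object$model, ...)

#' @export
print.gaze_zero_tests <- function(x, ...) {
  cat("Predicted cell means tested against zero\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
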