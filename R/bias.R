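#' Egger-type funnel-asymmetry test on the multilevel model
#'
#' Refits the full random-effects structure with the precision of each
#' effect size, \eqn{1/\sqrt{v_i}}, added as a moderator, and tests the
#' intercept against zero. A non-zero intercept indicates that effect size
#' and precision are systematically related (funnel asymmetry), the usual
#' signature of publication bias; the dataset is flagged as biased when the
#' intercept differs from zero at \code{alpha} (default 0.1). The slope on
#' precision is reported for completeness. A variant with the standard
#' error as moderator (slope tested) is available for sensitivity analysis
#' via \code{moderator = "sei"}.
#'
#' @param effects data.frame with \code{yi}, \code{vi}, \code{study_id} and
#'   optionally \code{species}.
#' @param phylo optional species correlation matrix.
#' @param alpha significance level of the bias verdict (default 0.1).
#' @param moderator \code{"precision"} (test the intercept, default) or
#'   \code{"sei"} (test the slope on the standard error).
#' @param ... passed to \code{\link{meta_ml}}.
#' @return An object of class \code{"bias_test"}: list with the tested
#'   \code{coefficient}, \code{estimate}, \code{se}, \code{zval}, \code{pval},
#'   \code{alpha}, logical \code{biased} verdict, the companion coefficient
#'   (\code{other}) and the underlying \code{fit}.
#' @export
eggers_test <- function(effects, phylo = NULL, alpha = 0.1,
                        moderator = c("precision", "sei"), ...) {
  moderator <- match.arg(moderator)
  stopifnot(all(c("yi", "vi") %in% names(effects)))
  if (nrow(effects) < 3)
    stop("Egger's test needs at least 3 effect sizes", call. = FALSE)
  if (stats::var(effects$vi) < .Machine$double.eps)
    stop("all sampling variances are equal: the precision moderator is ",
         "collinear with the intercept", call. = FALSE)
  mod <- switch(moderator,
                precision = cbind(precision = 1 / sqrt(effects$vi)),
                sei = cbind(sei = sqrt(effects$vi)))
  fit <- .fit_effects_mods(effects, phylo, mod, ...)
  tested <- if (moderator == "precision") 1L else 2L
  .bias_result(fit, tested, alpha)
}

#' Time-lag bias test
#'
#' Regresses the magnitude (absolute value) of the effect sizes on
#' mean-centered publication year within the multilevel model and tests the
#' slope against zero at \code{alpha} (default 0.05). A negative slope is
#' the classical time-lag signature: early studies report inflated effects
#' that later studies fail to match.
#'
#' @param effects data.frame with \code{yi}, \code{vi}, \code{study_id},
#'   \code{year} and optionally \code{species}.
#' @param phylo optional species correlation matrix.
#' @param alpha significance level of the verdict (default 0.05).
#' @param ... passed to \code{\link{meta_ml}}.
#' @return A \code{"bias_test"} object (slope tested).
#' @export
time_lag_test <- function(effects, phylo = NULL, alpha = 0.05, ...) {
  stopifnot(all(c("yi", "vi", "year") %in% names(effects)))
  if (length(unique(effects$year)) < 2)
    stop("time-lag test needs at least 2 distinct publication years",
         call. = FALSE)
  effects <- abs_effects(effects)
  mod <- cbind(year_c = effects$year - mean(effects$year))
  fit <- .fit_effects_mods(effects, phylo, mod, ...)
  .bias_result(fit, 2L, alpha)
}

.fit_effects_mods <- function(effects, phylo, mod, ...) {
  if (!is.null(phylo)) {
    meta_ml(effects$yi, effects$vi, study = effects$study_id,
            species = effects$species, phylo = phylo, mods = mod, ...)
  } else if ("study_id" %in% names(effects)) {
    meta_ml(effects$yi, effects$vi, study = effects$study_id,
            mods = mod, ...)
  } else {
    meta_ml(effects$yi, effects$vi, mods = mod, ...)
  }
}

.bias_result <- function(fit, tested, alpha) {
  other <- if (tested == 1L) 2L else 1L
  structure(list(
    coefficient = names(fit$b)[tested],
    estimate = unname(fit$b[tested]),
    se = unname(fit$se[tested]),
    zval = unname(fit$zval[tested]),
    pval = unname(fit$pval[tested]),
    alpha = alpha,
    biased = unname(fit$pval[tested] < alpha),
    other = list(coefficient = names(fit$b)[other],
                 estimate = unname(fit$b[other]),
                 se = unname(fit$se[other]),
                 pval = unname(fit$pval[other])),
    fit = fit), class = "bias_test")
}

#' @export
print.bias_test <- function(x, digits = 4, ...) {
  cat(sprintf("Bias test on '%s': estimate = %.*f, se = %.*f, z = %.*f, p = %.4g\n",
              x$coefficient, digits, x$estimate, digits, x$se,
              digits, x$zval, x$pval))
  cat(sprintf("verdict at alpha = %.2g: %s\n", x$alpha,
              if (x$biased) "biased" else "no evidence of bias"))
  invisible(x)
}

#' Funnel-plot coordinates
#'
#' Per-effect coordinates for a funnel plot of a fitted multilevel model:
#' the residual effect size \eqn{y_i - x_i'\hat\beta} against the precision
#' \eqn{1/\sqrt{v_i}}.
#'
#' @param fit a \code{"meta_ml"} fit.
#' @return data.frame with columns \code{residual} and \code{precision},
#'   one row per effect size.
#' @export
funnel_data <- function(fit) {
  stopifnot(inherits(fit, "meta_ml"))
  data.frame(residual = residuals(fit), precision = 1 / sqrt(fit$vi))
}
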