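#' @export
print.meta_ml <- function(x, digits = 4, ...) {
  cat("Multilevel random-effects meta-analysis (REML)\n")
  cat(sprintf("k = %d effect sizes; strata: %s%s\n", x$k,
              paste(names(x$sigma2), collapse = ", "),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("\nVariance components:\n")
  print(round(x$sigma2, digits))
  for (n in x$notes) cat("note: ", n, "\n", sep = "")
  cat(sprintf("\nResidual heterogeneity: Q = %.*f, df = %d, p = %.4g\n",
              min(digits, 2), x$QE, x$QE.df, x$QE.p))
  cat("\nModel results:\n")
  tab <- data.frame(estimate = x$b, se = x$se, zval = x$zval, pval = x$pval,
                    ci.lb = x$ci.lb, ci.ub = x$ci.ub)
  print(round(tab, digits))
  if (!is.null(x$folded))
    cat(sprintf("\nFolded-normal magnitude: %.4f [%.4f, %.4f]\n",
                x$folded$estimate, x$folded$ci.lb, x$folded$ci.ub))
  invisible(x)
}

#' Summarize a multilevel meta-analytic fit
#'
#' @param object a \code{"meta_ml"} fit.
#' @param ... unused.
#' @return The fit augmented with its heterogeneity partition (class
#'   \code{"summary.meta_ml"}).
#' @export
summary.meta_ml <- function(object, ...) {
  object$heterogeneity <- heterogeneity(object)
  class(object) <- c("summary.meta_ml", "meta_ml")
  object
}

#' @export
print.summary.meta_ml <- function(x, digits = 4, ...) {
  NextMethod()
  cat("\n")
  print(x$heterogeneity, digits = digits)
  cat(sprintf("\nRestricted log-likelihood: %.4f\n", x$reml))
  invisible(x)
}

#' @export
coef.meta_ml <- function(object, ...) object$b

#' @export
vcov.meta_ml <- function(object, ...) object$vb

#' @export
confint.meta_ml <- function(object, parm, level, ...) {
  ci <- cbind(ci.lb = object$ci.lb, ci.ub = object$ci.ub)
  rownames(ci) <- names(object$b)
  ci
}

#' @export
logLik.meta_ml <- function(object, ...) {
  structure(object$reml, df = object$p + length(object$sigma2),
            class = "logLik")
}

#' @export
fitted.meta_ml <- function(object, ...) drop(object$X %*% object$b)

#' Marginal residuals of a multilevel meta-analytic fit
#'
#' @param object a \code{"meta_ml"} fit.
#' @param ... unused.
#' @return \code{yi - X beta-hat}.
#' @export
residuals.meta_ml <- function(object, ...) object$yi - fitted(object)

#' Pooled prediction from a multilevel meta-analytic fit
#'
#' Returns the pooled estimate with its confidence interval; with
#' \code{transform = "folded"} the estimate and bounds are passed through
#' \code{\link{folded_normal_mean}} with the estimate's SE, giving the
#' expected magnitude of response.
#'
#' @param object a \code{"meta_ml"} fit (intercept only for a pooled value).
#' @param transform \code{"none"} or \code{"folded"}.
#' @param ... unused.
#' @return data.frame with \code{pred}, \code{se}, \code{ci.lb}, \code{ci.ub}.
#' @export
predict.meta_ml <- function(object, transform = c("none", "folded"), ...) {
  transform <- match.arg(transform)
  out <- data.frame(pred = unname(object$b[1]), se = unname(object$se[1]),
                    ci.lb = unname(object$ci.lb[1]),
                    ci.ub = unname(object$ci.ub[1]))
  if (transform == "folded") {
    out$pred <- folded_normal_mean(out$pred, out$se)
    out$ci.lb <- folded_normal_mean(out$ci.lb, out$se)
    out$ci.ub <- folded_normal_mean(out$ci.ub, out$se)
  }
  out
}

#' Simulate effect sizes from a fitted multilevel model
#'
#' Draws new effect-size vectors from the fitted marginal distribution
#' \eqn{N(X\hat\beta, \hat V)}, i.e. parametric-bootstrap replicates.
#'
#' @param object a \code{"meta_ml"} fit.
#' @param nsim number of replicate vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return A k x nsim data.frame of simulated \code{yi}.
#' @export
simulate.meta_ml <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  L <- t(chol(object$V))
  mu <- fitted(object)
  out <- replicate(nsim, mu + drop(L %*% stats::rnorm(object$k)))
  as.data.frame(out)
}

#' Funnel plot of a multilevel meta-analytic fit
#'
#' Plots precision (\eqn{1/\sqrt{v_i}}) against the residual effect sizes
#' (see \code{\link{funnel_data}}); asymmetry around zero suggests
#' small-study effects.
#'
#' @param x a \code{"meta_ml"} fit.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.meta_ml <- function(x, ...) {
  fd <- funnel_data(x)
  graphics::plot(fd$residual, fd$precision,
                 xlab = "residual effect size", ylab = "precision (1/SE)",
                 pch = 19, ...)
  graphics::abline(v = 0, lty = 2)
  invisible(fd)
}
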