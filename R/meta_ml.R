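#' Fit a multilevel phylogenetic random-effects meta-analysis by REML
#'
#' Fits the model \eqn{y \sim N(X\beta, V)} with
#' \deqn{V = \sigma^2_{phylo} Z_p A Z_p' + \sigma^2_{study} Z_s Z_s' +
#'       \sigma^2_{es} I + diag(v_i),}
#' where \eqn{A} is a phylogenetic correlation matrix over species,
#' \eqn{Z_s} indicates studies, the effect-size stratum is the residual
#' (identity) level, and the per-effect sampling variances \eqn{v_i} are
#' treated as known. Variance components are estimated by restricted maximum
#' likelihood over log-variances with several deterministic starting points
#' and a bounded quasi-Newton optimizer; components whose optimum falls on
#' the lower boundary are reported as exact zeros. Fixed effects are
#' estimated by generalized least squares at the optimum, with standard
#' normal (z) inference.
#'
#' @param yi numeric vector of effect sizes (or column name in \code{data}).
#' @param vi positive sampling variances of \code{yi}.
#' @param study optional study labels; adds an exchangeable study stratum.
#' @param species optional species labels; together with \code{phylo} adds
#'   the phylogenetic stratum.
#' @param phylo optional species correlation matrix (see
#'   \code{\link{phylo_cor}}); required for the phylogenetic stratum.
#' @param mods optional numeric vector or matrix of moderators; the fixed
#'   part is intercept + moderators.
#' @param data optional data.frame in which \code{yi}, \code{vi},
#'   \code{study}, \code{species} and \code{mods} are looked up.
#' @param level confidence level for Wald intervals (default 0.95).
#' @return An object of class \code{"meta_ml"}: a list with coefficient
#'   estimates (\code{b}, \code{se}, \code{zval}, \code{pval}, \code{ci.lb},
#'   \code{ci.ub}), variance components \code{sigma2} (named by stratum),
#'   the restricted log-likelihood \code{reml}, Cochran's \code{QE} test for
#'   residual heterogeneity, convergence information, and the model frame.
#' @seealso \code{\link{heterogeneity}}, \code{\link{magnitude_fit}},
#'   \code{\link{direction_fit}}, \code{\link{eggers_test}}
#' @examples
#' es <- data.frame(yi = c(0.2, 0.5, 0.4, 0.9), vi = c(0.05, 0.1, 0.06, 0.2),
#'                  study = c("s1", "s1", "s2", "s3"))
#' meta_ml(yi, vi, study = study, data = es)
#' @export
meta_ml <- function(yi, vi, study = NULL, species = NULL, phylo = NULL,
                    mods = NULL, data = NULL, level = 0.95) {
  cl <- match.call()
  pf <- parent.frame()
  grab <- function(e) eval(e, data, pf)
  yi <- as.numeric(grab(substitute(yi)))
  vi <- as.numeric(grab(substitute(vi)))
  study <- grab(substitute(study))
  species <- grab(substitute(species))
  mods <- grab(substitute(mods))

  k <- length(yi)
  if (length(vi) != k) stop("yi and vi lengths differ", call. = FALSE)
  if (anyNA(yi) || anyNA(vi)) stop("yi/vi contain NA", call. = FALSE)
  if (any(vi <= 0)) stop("all vi must be > 0", call. = FALSE)

  X <- cbind(intrcpt = rep(1, k))
  if (!is.null(mods)) {
    mods <- as.matrix(mods)
    if (nrow(mods) != k) stop("mods length mismatch", call. = FALSE)
    if (is.null(colnames(mods)))
      colnames(mods) <- paste0("mod", seq_len(ncol(mods)))
    X <- cbind(X, mods)
  }
  p <- ncol(X)
  if (qr(X)$rank < p)
    stop("singular design: moderators are collinear with the intercept",
         call. = FALSE)
  if (k < p + 1)
    stop("need at least ", p + 1, " effect sizes", call. = FALSE)

  # random-effect covariance blocks (each scaled by its sigma^2); a
  # stratum with a single cluster level is confounded with the intercept
  # under REML, so its variance is fixed at the boundary and noted
  notes <- character(0)
  fixed0 <- character(0)
  blocks <- list(es = diag(k))
  if (!is.null(study)) {
    study <- as.character(study)
    if (length(study) != k) stop("study length mismatch", call. = FALSE)
    if (length(unique(study)) < 2) {
      fixed0 <- c(fixed0, "study")
      notes <- c(notes,
                 "single study: sigma2[study] unidentifiable, fixed at 0")
    } else {
      blocks$study <- outer(study, study, "==") * 1
    }
  }
  if (!is.null(species)) {
    species <- as.character(species)
    if (length(species) != k) stop("species length mismatch", call. = FALSE)
    if (is.null(phylo))
      stop("species given without a phylogenetic correlation matrix",
           call. = FALSE)
    if (length(unique(species)) < 2) {
      fixed0 <- c(fixed0, "phylo")
      notes <- c(notes,
                 "single species: sigma2[phylo] unidentifiable, fixed at 0")
    } else {
      al <- align_phylo(phylo, species)
      blocks$phylo <- al$A[al$index, al$index, drop = FALSE]
      dimnames(blocks$phylo) <- NULL
    }
  }
  m <- length(blocks)

  nll <- function(logs2) {
    val <- .reml_loglik(exp(logs2), yi, X, vi, blocks)
    if (!is.finite(val)) 1e10 else -val
  }

  # deterministic starts: total excess variance from DerSimonian-Laird,
  # split equally / concentrated on each stratum / near-zero
  w <- 1 / vi
  muFE <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - muFE)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau0 <- max((Q - (k - 1)) / C, 0.05)
  starts <- list(rep(tau0 / m, m))
  for (j in seq_len(m)) {
    s <- rep(0.05 * tau0 / m, m); s[j] <- 0.9 * tau0
    starts[[length(starts) + 1L]] <- s
  }
  starts[[length(starts) + 1L]] <- rep(1e-3, m)

  lower <- rep(-30, m)
  upper <- rep(log(max(100 * tau0, 100)), m)
  fits <- lapply(starts, function(s) {
    stats::optim(pmin(pmax(log(s), lower), upper), nll, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = 500, factr = 10, pgtol = 1e-12,
                                ndeps = rep(1e-6, m)))
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  converged <- best$convergence == 0
  # derivative-free polish from the best point (the quasi-Newton line
  # search can stall on boundary ridges)
  if (m == 1) {
    op <- stats::optimize(function(l) nll(l), c(lower, upper), tol = 1e-10)
    if (op$objective <= best$value + 1e-10) {
      best$par <- op$minimum; best$value <- op$objective
      converged <- TRUE
    }
  } else {
    nm <- stats::optim(best$par, nll, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-14))
    if (nm$value <= best$value + 1e-10) {
      if (nm$convergence == 0) converged <- TRUE
      if (nm$value < best$value) best <- nm
    }
  }
  sigma2 <- exp(pmin(pmax(best$par, lower), upper))
  sigma2[best$par < log(1e-8)] <- 0          # boundary projection
  names(sigma2) <- names(blocks)
  if (!converged)
    warning("REML optimizer did not report convergence; result is flagged",
            call. = FALSE)
  if (length(fixed0)) {
    sigma2[fixed0] <- 0
    sigma2 <- sigma2[intersect(c("es", "study", "phylo"), names(sigma2))]
  }

  # GLS fixed effects at the optimum
  V <- diag(vi, k)
  for (nm2 in names(blocks)) V <- V + sigma2[nm2] * blocks[[nm2]]
  ch <- chol(V)
  Vinv <- chol2inv(ch)
  XtVinv <- crossprod(X, Vinv)
  vb <- solve(XtVinv %*% X)
  b <- drop(vb %*% XtVinv %*% yi)
  names(b) <- colnames(X)
  se <- sqrt(diag(vb))
  zval <- b / se
  pval <- 2 * stats::pnorm(-abs(zval))
  zc <- stats::qnorm(1 - (1 - level) / 2)

  # residual heterogeneity: WLS (weights 1/vi) residual Q with df = k - p;
  # reduces to the classical Cochran's Q for an intercept-only fixed part
  W <- diag(w, k)
  bFE <- drop(solve(crossprod(X, W %*% X), crossprod(X, W %*% yi)))
  rFE <- yi - drop(X %*% bFE)
  QE <- sum(w * rFE^2)

  structure(list(
    b = b, se = se, zval = zval, pval = pval,
    ci.lb = b - zc * se, ci.ub = b + zc * se,
    sigma2 = sigma2,
    reml = .reml_loglik(sigma2[names(blocks)], yi, X, vi, blocks),
    converged = converged, notes = notes,
    restart_criteria = -vals,
    QE = unname(QE), QE.df = k - p,
    QE.p = stats::pchisq(QE, df = k - p, lower.tail = FALSE),
    k = k, p = p, level = level,
    yi = yi, vi = vi, X = X, V = V, vb = vb,
    study = study, species = species, blocks = blocks,
    call = cl), class = "meta_ml")
}

# restricted log-likelihood of y ~ N(X beta, V(s2)); the constant includes
# the +log|X'X|/2 term so values are comparable with the usual REML
# likelihood convention
.reml_loglik <- function(s2, y, X, vi, blocks) {
  k <- length(y); p <- ncol(X)
  V <- diag(vi, k)
  for (j in seq_along(blocks)) V <- V + s2[j] * blocks[[j]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  Vinv <- chol2inv(ch)
  XtVX <- crossprod(X, Vinv %*% X)
  chx <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chx)) return(NA_real_)
  beta <- drop(chol2inv(chx) %*% crossprod(X, Vinv %*% y))
  r <- y - drop(X %*% beta)
  quad <- drop(crossprod(r, Vinv %*% r))
  as.numeric(
    -0.5 * ((k - p) * log(2 * pi) + 2 * sum(log(diag(ch))) +
              2 * sum(log(diag(chx))) + quad) +
      0.5 * determinant(crossprod(X), logarithm = TRUE)$modulus)
}

#' Cochran's Q test of homogeneity
#'
#' Weighted sum of squared deviations of the effect sizes from their
#' fixed-effect mean, with weights \eqn{1/v_i}; under homogeneity it follows
#' a chi-square distribution with \eqn{k - 1} degrees of freedom. The
#' statistic depends only on \code{yi} and \code{vi} — not on the random
#' structure or the tree.
#'
#' @param yi effect sizes, or a data.frame with columns \code{yi}, \code{vi}.
#' @param vi sampling variances (ignored when \code{yi} is a data.frame).
#' @return An object of class \code{"cochran_q"}: list with \code{Q},
#'   \code{df} and upper-tail \code{p}.
#' @examples
#' cochran_q(c(0, 2), c(1, 1))
#' @export
cochran_q <- function(yi, vi = NULL) {
  if (is.data.frame(yi)) { vi <- yi$vi; yi <- yi$yi }
  k <- length(yi)
  if (k < 2) stop("Cochran's Q needs at least 2 effect sizes", call. = FALSE)
  if (any(vi <= 0)) stop("all vi must be > 0", call. = FALSE)
  w <- 1 / vi
  muFE <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - muFE)^2)
  structure(list(Q = Q, df = k - 1,
                 p = stats::pchisq(Q, df = k - 1, lower.tail = FALSE)),
            class = "cochran_q")
}

#' @export
print.cochran_q <- function(x, digits = 4, ...) {
  cat(sprintf("Cochran's Q = %.*f, df = %d, p = %.4g\n",
              digits, x$Q, x$df, x$p))
  invisible(x)
}

#' Mean of the folded normal distribution
#'
#' Expectation of \eqn{|X|} for \eqn{X \sim N(\mu, \sigma^2)}:
#' \deqn{E|X| = \sigma \sqrt{2/\pi}\, e^{-\mu^2/(2\sigma^2)} +
#'       \mu (1 - 2\Phi(-\mu/\sigma)).}
#' Converts a signed pooled estimate (and its uncertainty) into an unbiased
#' summary of the magnitude of response, which a standardized mean
#' difference averaged over opposite-signed responses underestimates.
#'
#' @param mu mean of the underlying normal (a pooled SMD estimate).
#' @param sigma standard deviation (> 0), typically the estimate's SE.
#' @return \eqn{E|X|}, always \eqn{\ge |\mu|}.
#' @examples
#' folded_normal_mean(0, 1)   # sqrt(2/pi)
#' @export
folded_normal_mean <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  sigma * sqrt(2 / pi) * exp(-mu^2 / (2 * sigma^2)) +
    mu * (1 - 2 * stats::pnorm(-mu / sigma))
}

#' Magnitude analysis of signal adjustment
#'
#' Fits the multilevel phylogenetic model to the magnitude of response. The
#' default mode \code{"abs"} fits \code{\link{meta_ml}} to absolute effect
#' sizes and reports the Wald summary as-is. Mode \code{"abs+fold"}
#' additionally reports the folded-normal transform of the estimate and CI
#' bounds (using the estimate's SE) as a secondary magnitude summary; mode
#' \code{"fold-only"} fits the signed effects and folds the result, for
#' sensitivity analysis.
#'
#' @param effects data.frame with columns \code{yi}, \code{vi},
#'   \code{study_id}, \code{species} (from \code{\link{compute_effects}}).
#' @param phylo optional species correlation matrix; omitted, the model has
#'   study and effect-size strata only.
#' @param mode one of \code{"abs"}, \code{"abs+fold"}, \code{"fold-only"}.
#' @param ... passed to \code{\link{meta_ml}}.
#' @return A \code{"meta_ml"} fit; modes with folding attach a \code{folded}
#'   list (estimate, ci.lb, ci.ub).
#' @export
magnitude_fit <- function(effects, phylo = NULL,
                          mode = c("abs", "abs+fold", "fold-only"), ...) {
  mode <- match.arg(mode)
  dat <- if (mode == "fold-only") effects else abs_effects(effects)
  fit <- .fit_effects(dat, phylo, ...)
  fit$mode <- mode
  if (mode != "abs") {
    se1 <- unname(fit$se[1])
    fit$folded <- list(
      estimate = folded_normal_mean(unname(fit$b[1]), se1),
      ci.lb = folded_normal_mean(unname(fit$ci.lb[1]), se1),
      ci.ub = folded_normal_mean(unname(fit$ci.ub[1]), se1))
  }
  fit
}

#' Direction analysis of signal adjustment
#'
#' Fits the multilevel phylogenetic model to the signed (raw) effect sizes,
#' quantifying which way a signal component shifts under noise.
#'
#' @inheritParams magnitude_fit
#' @return A \code{"meta_ml"} fit.
#' @export
direction_fit <- function(effects, phylo = NULL, ...) {
  .fit_effects(effects, phylo, ...)
}

.fit_effects <- function(effects, phylo, ...) {
  stopifnot(all(c("yi", "vi", "study_id") %in% names(effects)))
  if (!is.null(phylo)) {
    if (!"species" %in% names(effects))
      stop("effects need a species column for a phylogenetic fit",
           call. = FALSE)
    meta_ml(effects$yi, effects$vi, study = effects$study_id,
            species = effects$species, phylo = phylo, ...)
  } else {
    meta_ml(effects$yi, effects$vi, study = effects$study_id, ...)
  }
}
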