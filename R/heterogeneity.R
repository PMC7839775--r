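#' Typical sampling variance of a set of effect sizes
#'
#' The "typical" within-effect sampling variance used by the multilevel
#' I-squared: with weights \eqn{w_i = 1/v_i},
#' \deqn{\bar{s}^2 = \frac{(k-1)\sum w_i}{(\sum w_i)^2 - \sum w_i^2}.}
#' When all \eqn{v_i} are equal it reduces to their common value, and it
#' always lies between \code{min(v)} and \code{max(v)}.
#'
#' @param vi positive sampling variances (length >= 2).
#' @return The typical sampling variance (same units as \code{vi}).
#' @export
typical_sampling_variance <- function(vi) {
  k <- length(vi)
  if (k < 2) stop("need at least 2 sampling variances", call. = FALSE)
  if (any(vi <= 0)) stop("all vi must be > 0", call. = FALSE)
  w <- 1 / vi
  (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))
}

#' Multilevel I-squared heterogeneity partition
#'
#' Partitions the proportion of variance not attributable to sampling error
#' into the contributions of the random strata: for stratum \eqn{l},
#' \deqn{I^2_l = 100\, \sigma^2_l / (\sigma^2_{phylo} + \sigma^2_{study} +
#'       \sigma^2_{es} + \bar{s}^2),}
#' and the total is their sum. \code{I2_es} reflects inconsistencies within
#' studies, \code{I2_study} among studies, and \code{I2_phylo}
#' inconsistencies due to phylogenetic relatedness among species.
#'
#' @param sigma2 named vector of variance components (names among
#'   \code{"es"}, \code{"study"}, \code{"phylo"}; absent strata count as 0),
#'   or a \code{"meta_ml"} fit.
#' @param sbar2 typical sampling variance (see
#'   \code{\link{typical_sampling_variance}}); ignored when \code{sigma2} is
#'   a fit.
#' @return An object of class \code{"i2_partition"}: list with \code{sbar2},
#'   \code{i2_es}, \code{i2_study}, \code{i2_phylo} and \code{i2_total}
#'   (percentages in [0, 100]).
#' @export
i2_partition <- function(sigma2, sbar2) {
  if (inherits(sigma2, "meta_ml")) {
    sbar2 <- typical_sampling_variance(sigma2$vi)
    sigma2 <- sigma2$sigma2
  }
  if (any(sigma2 < 0) || sbar2 <= 0)
    stop("variance components must be >= 0 and sbar2 > 0", call. = FALSE)
  get0 <- function(nm) if (nm %in% names(sigma2)) unname(sigma2[nm]) else 0
  s2 <- c(es = get0("es"), study = get0("study"), phylo = get0("phylo"))
  denom <- sum(s2) + sbar2
  i2 <- 100 * s2 / denom
  structure(list(sbar2 = sbar2,
                 i2_es = unname(i2["es"]),
                 i2_study = unname(i2["study"]),
                 i2_phylo = unname(i2["phylo"]),
                 i2_total = sum(i2)),
            class = "i2_partition")
}

#' Heterogeneity partition of a fitted multilevel model
#'
#' Convenience wrapper computing \code{\link{i2_partition}} from a
#' \code{"meta_ml"} fit's variance components and sampling variances.
#'
#' @param fit a \code{"meta_ml"} fit.
#' @return An \code{"i2_partition"} object.
#' @export
heterogeneity <- function(fit) {
  stopifnot(inherits(fit, "meta_ml"))
  i2_partition(fit)
}

#' @export
print.i2_partition <- function(x, digits = 2, ...) {
  cat("Heterogeneity (multilevel I-squared, %):\n")
  print(round(c(ES = x$i2_es, Study = x$i2_study, Phylogeny = x$i2_phylo,
                Total = x$i2_total), digits))
  cat(sprintf("typical sampling variance: %.4g\n", x$sbar2))
  invisible(x)
}
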