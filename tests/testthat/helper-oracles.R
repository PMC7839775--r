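# Independent oracles used by the tests. These deliberately avoid the code
# paths of the package: plain solve()/determinant() linear algebra, grid
# search instead of quasi-Newton, quadrature instead of closed forms.

# restricted log-likelihood of y ~ N(X beta, V), V = sum s2_j B_j + diag(vi)
oracle_remlik <- function(s2, y, X, vi, blocks) {
  V <- diag(vi, length(y))
  for (j in seq_along(blocks)) V <- V + s2[j] * blocks[[j]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  as.numeric(
    -0.5 * ((length(y) - ncol(X)) * log(2 * pi) +
              determinant(V)$modulus +
              determinant(XtViX)$modulus +
              t(r) %*% Vi %*% r) +
      0.5 * determinant(t(X) %*% X)$modulus)
}

# brute-force REML optimum: log-spaced lattice with local refinement
oracle_grid_reml <- function(y, X, vi, blocks, lo = -12, hi = 2,
                             n = 7, rounds = 20) {
  m <- length(blocks)
  centers <- rep((lo + hi) / 2, m)
  width <- (hi - lo) / 2
  best <- -Inf
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(m), function(j)
      seq(centers[j] - width, centers[j] + width, length.out = n))
    pts <- as.matrix(expand.grid(grids))
    vals <- apply(pts, 1, function(ls)
      oracle_remlik(exp(ls), y, X, vi, blocks))
    i <- which.max(vals)
    centers <- pts[i, ]
    best <- vals[i]
    width <- width * 0.6
  }
  s2 <- exp(centers)
  s2[centers <= lo + 1e-6] <- 0
  list(sigma2 = unname(s2), value = best)
}

# quadrature oracle for E|X|, X ~ N(mu, sigma^2)
oracle_folded_mean <- function(mu, sigma) {
  stats::integrate(function(x) abs(x) * stats::dnorm(x, mu, sigma),
                   mu - 12 * sigma, mu + 12 * sigma,
                   rel.tol = 1e-10)$value
}

# a small multilevel dataset with known structure for oracle comparisons
tiny_dataset <- function(seed, k = 5) {
  set.seed(seed)
  tree <- sim_tree(3)
  A <- phylo_cor(tree)
  species <- sample(rownames(A), k, replace = TRUE)
  study <- sample(paste0("s", 1:3), k, replace = TRUE)
  vi <- runif(k, 0.02, 0.3)
  yi <- rnorm(k, 0.5, 0.5)
  list(yi = yi, vi = vi, study = study, species = species, A = A)
}

# covariance blocks in the package's stratum order (es, study, phylo)
tiny_blocks <- function(d) {
  k <- length(d$yi)
  Aexp <- d$A[d$species, d$species, drop = FALSE]
  dimnames(Aexp) <- NULL
  list(es = diag(k), study = outer(d$study, d$study, "==") * 1, phylo = Aexp)
}
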