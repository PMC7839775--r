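test_that("constant effect sizes give the constant and zero variance components", {
  k <- 8
  A <- phylo_cor(sim_tree(k, seed = 41))  # any tree; strata must vanish
  fit <- meta_ml(rep(0.7, k), rep(0.1, k),
                 study = paste0("s", 1:k),
                 species = rownames(A), phylo = A)
  expect_equal(unname(fit$b[1]), 0.7, tolerance = 1e-6)
  expect_equal(unname(fit$sigma2), rep(0, 3))
  expect_equal(fit$QE, 0, tolerance = 1e-10)
})

test_that("REML optimum matches a brute-force grid search on small datasets", {
  for (seed in c(101, 102, 103)) {
    d <- tiny_dataset(seed, k = 5)
    blocks <- tiny_blocks(d)
    X <- matrix(1, 5, 1)
    oracle <- oracle_grid_reml(d$yi, X, d$vi, blocks)
    fit <- meta_ml(d$yi, d$vi, study = d$study, species = d$species,
                   phylo = d$A)
    expect_equal(fit$reml, oracle$value, tolerance = 1e-4)
    expect_equal(unname(fit$sigma2), oracle$sigma2, tolerance = 1e-4)
  }
})

test_that("the reported optimum is the best across restarts", {
  d <- tiny_dataset(104, k = 5)
  fit <- meta_ml(d$yi, d$vi, study = d$study, species = d$species,
                 phylo = d$A)
  expect_gte(fit$reml + 1e-8, max(fit$restart_criteria))
})

test_that("with no phylogeny and one effect per study the fit is the classic two-level REML", {
  set.seed(42)
  for (r in 1:20) {
    k <- sample(6:15, 1)
    vi <- runif(k, 0.02, 0.4)
    yi <- rnorm(k, 0.4, sqrt(0.15 + vi))
    fit <- meta_ml(yi, vi)
    ref <- metafor::rma(yi, vi, method = "REML",
                        control = list(threshold = 1e-12))
    expect_equal(unname(fit$sigma2["es"]), unname(ref$tau2), tolerance = 1e-6)
    expect_equal(unname(fit$b[1]), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$se[1]), unname(ref$se), tolerance = 1e-6)
  }
})

test_that("the full three-stratum fit agrees with an independent multilevel REML implementation", {
  set.seed(43)
  sim <- sim_dataset(sim_params(n_species = 12), seed = 44)
  eff <- compute_effects(sim$records)
  A <- phylo_cor(sim$tree)
  fit <- meta_ml(eff$yi, eff$vi, study = eff$study_id,
                 species = eff$species, phylo = A)
  dat <- eff
  dat$es_id <- seq_len(nrow(dat))
  Asub <- align_phylo(A, dat$species)$A
  ref <- metafor::rma.mv(yi, vi,
                         random = list(~1 | es_id, ~1 | study_id, ~1 | species),
                         R = list(species = Asub), data = dat,
                         method = "REML")
  expect_equal(unname(fit$sigma2), unname(ref$sigma2), tolerance = 1e-4)
  expect_equal(unname(fit$b[1]), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(unname(fit$se[1]), unname(ref$se), tolerance = 1e-5)
  expect_equal(fit$reml, as.numeric(logLik(ref)), tolerance = 1e-5)
})

test_that("the marginal covariance stays positive definite wherever it is evaluated", {
  d <- tiny_dataset(105, k = 5)
  fit <- meta_ml(d$yi, d$vi, study = d$study, species = d$species,
                 phylo = d$A)
  expect_gt(min(eigen(fit$V, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("degenerate designs are handled loudly", {
  expect_error(meta_ml(c(1, 2, 3), c(0.1, 0.1, 0.1),
                       mods = cbind(x = c(2, 2, 2))), "singular")
  expect_error(meta_ml(c(1, 2), c(0.1, -0.1)), "vi")
  # a single study still fits; the study variance hits the boundary
  fit <- meta_ml(c(0.2, 0.4, 0.3, 0.25), rep(0.05, 4),
                 study = rep("only", 4))
  expect_equal(unname(fit$sigma2["study"]), 0)
})

test_that("cochran_q reproduces hand arithmetic and its invariances", {
  q <- cochran_q(c(0, 2), c(1, 1))
  expect_equal(q$Q, 2)
  expect_equal(q$df, 1)
  expect_equal(q$p, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(q$p, 0.157, tolerance = 1e-2)

  expect_equal(cochran_q(rep(1.3, 5), runif(5, 0.1, 1))$Q, 0)

  set.seed(45)
  yi <- rnorm(12); vi <- runif(12, 0.05, 0.5)
  perm <- sample(12)
  expect_equal(cochran_q(yi, vi)$Q, cochran_q(yi[perm], vi[perm])$Q)
  expect_error(cochran_q(1, 0.1), "at least 2")
})

test_that("folded_normal_mean matches the closed form, quadrature and its bounds", {
  expect_equal(folded_normal_mean(0, 1), sqrt(2 / pi), tolerance = 1e-12)
  expect_equal(folded_normal_mean(-2, 1e-8), 2, tolerance = 1e-6)
  expect_equal(folded_normal_mean(1.42, 0.72), 1.433, tolerance = 1e-3)

  for (mu in c(-2, -0.3, 0, 0.7, 1.42, 5)) {
    for (sig in c(0.2, 0.72, 1, 2)) {
      expect_equal(folded_normal_mean(mu, sig), oracle_folded_mean(mu, sig),
                   tolerance = 1e-6)
      expect_gte(folded_normal_mean(mu, sig), abs(mu))
    }
  }
  expect_error(folded_normal_mean(1, 0), "sigma")
})

test_that("magnitude and direction fits behave under sign symmetry and folding", {
  set.seed(46)
  k <- 12
  eff <- data.frame(yi = rnorm(k, 0, 0.8), vi = runif(k, 0.05, 0.2),
                    study_id = paste0("s", rep(1:6, each = 2)),
                    species = paste0("Sp", rep(1:6, each = 2)))
  # star tree: independent species
  A <- diag(6); dimnames(A) <- list(unique(eff$species), unique(eff$species))

  up <- direction_fit(eff, phylo = A)
  flip <- eff; flip$yi <- -flip$yi
  down <- direction_fit(flip, phylo = A)
  expect_equal(unname(up$b[1]), -unname(down$b[1]), tolerance = 1e-6)
  expect_equal(unname(up$se[1]), unname(down$se[1]), tolerance = 1e-6)
  expect_equal(unname(up$sigma2), unname(down$sigma2), tolerance = 1e-6)

  # all |yi| = c -> magnitude estimate c
  eq <- data.frame(yi = c(0.6, -0.6, 0.6, -0.6), vi = rep(0.1, 4),
                   study_id = paste0("s", 1:4))
  expect_equal(unname(magnitude_fit(eq)$b[1]), 0.6, tolerance = 1e-6)

  # folded correction vanishes for large mu/se
  strong <- data.frame(yi = rnorm(20, 5, 0.1), vi = rep(0.01, 20),
                       study_id = paste0("s", 1:20))
  m1 <- magnitude_fit(strong, mode = "abs")
  m2 <- magnitude_fit(strong, mode = "abs+fold")
  expect_gt(unname(m1$b[1]) / m1$se[1], 6)
  expect_equal(m2$folded$estimate, unname(m1$b[1]), tolerance = 1e-3)
  expect_equal(m2$folded$ci.lb, unname(m1$ci.lb[1]), tolerance = 1e-3)
})

test_that("meta_ml methods are coherent with the stored fit", {
  d <- tiny_dataset(106, k = 8)
  fit <- meta_ml(d$yi, d$vi, study = d$study, species = d$species,
                 phylo = d$A)
  expect_equal(unname(coef(fit)[1]), unname(fit$b[1]))
  expect_equal(residuals(fit), d$yi - fitted(fit))
  expect_equal(unname(sqrt(diag(vcov(fit)))), unname(fit$se))
  expect_equal(unname(confint(fit)[1, ]), c(fit$ci.lb[1], fit$ci.ub[1]),
               ignore_attr = TRUE)
  pr <- predict(fit)
  expect_equal(pr$pred, unname(fit$b[1]))
  prf <- predict(fit, transform = "folded")
  expect_gte(prf$pred, abs(pr$pred))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$k, 3))
  expect_output(print(summary(fit)), "Heterogeneity")
})
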