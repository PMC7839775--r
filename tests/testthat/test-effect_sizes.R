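test_that("smdh reproduces hand-computed values and the trivial cases", {
  # equal means -> zero effect
  expect_equal(smdh(5, 1, 10, 5, 2, 10)$yi, 0)

  # hand evaluation: sp = sqrt(10), d = 2/sqrt(10) = 0.6325,
  # J(18) = gamma(9)/(3 gamma(8.5)) = 0.9578 (approx 1 - 3/71), yi = 0.6058
  es <- smdh(10, 2, 10, 12, 4, 10)
  expect_equal(es$yi, exp(lgamma(9) - lgamma(8.5)) / 3 * 2 / sqrt(10),
               tolerance = 1e-12)
  expect_equal(es$yi, 0.6057, tolerance = 2.5e-4)
  expect_equal(es$yi, (1 - 3 / 71) * 2 / sqrt(10), tolerance = 2e-4)

  # sign convention: positive = larger under noise
  expect_gt(smdh(0, 1, 10, 1, 1, 10)$yi, 0)
})

test_that("smdh rejects invalid group summaries", {
  expect_error(smdh(5, 1, 1, 5, 1, 10), "n >= 2")
  expect_error(smdh(5, 0, 10, 5, 1, 10), "> 0")
  expect_error(smdh(5, 1, 10, NA, 1, 10), "missing")
})

test_that("smdh is antisymmetric and consistent in the large-sample limit", {
  a <- smdh(10, 2, 12, 13, 3, 17)
  b <- smdh(13, 3, 17, 10, 2, 12)
  expect_equal(a$yi, -b$yi)
  expect_equal(a$vi, b$vi)

  # n -> infinity with fixed moments: yi -> dmean/sp, vi -> 0
  big <- smdh(10, 2, 1e7, 12, 4, 1e7)
  expect_equal(big$yi, 2 / sqrt(10), tolerance = 1e-5)
  expect_lt(big$vi, 1e-5)
})

test_that("smdh matches the reference implementation on random inputs", {
  set.seed(11)
  n1 <- sample(5:40, 20, replace = TRUE)
  n2 <- sample(5:40, 20, replace = TRUE)
  m1 <- rnorm(20, 5); m2 <- rnorm(20, 6)
  s1 <- runif(20, 0.5, 3); s2 <- runif(20, 0.5, 3)
  ours <- smdh(m1, s1, n1, m2, s2, n2)
  ref <- metafor::escalc(measure = "SMDH", m1i = m2, sd1i = s2, n1i = n2,
                         m2i = m1, sd2i = s1, n2i = n1)
  expect_equal(ours$yi, as.numeric(ref$yi), tolerance = 1e-10)
  expect_equal(ours$vi, as.numeric(ref$vi), tolerance = 1e-10)
})

test_that("smdh sampling variance is calibrated against Monte-Carlo", {
  # empirical variance of simulated SMDH within 10% of the formula value
  set.seed(21)
  cases <- list(c(m1 = 10, s1 = 2, n1 = 10, m2 = 12, s2 = 4, n2 = 10),
                c(m1 = 0, s1 = 1, n1 = 15, m2 = 1, s2 = 1.5, n2 = 12),
                c(m1 = 5, s1 = 3, n1 = 30, m2 = 4, s2 = 1, n2 = 20))
  for (cs in cases) {
    nrep <- 1e5
    x <- matrix(rnorm(nrep * cs["n1"], cs["m1"], cs["s1"]), nrow = nrep)
    y <- matrix(rnorm(nrep * cs["n2"], cs["m2"], cs["s2"]), nrow = nrep)
    sim <- smdh(rowMeans(x), apply(x, 1, sd), cs["n1"],
                rowMeans(y), apply(y, 1, sd), cs["n2"])
    vi <- smdh(cs["m1"], cs["s1"], cs["n1"],
               cs["m2"], cs["s2"], cs["n2"])$vi
    expect_equal(var(sim$yi), vi, tolerance = 0.1)
  }
})

test_that("abs_effects folds signs and preserves everything else", {
  es <- data.frame(yi = c(-0.5, 0, 1.2), vi = c(0.1, 0.2, 0.3),
                   study_id = c("a", "b", "c"))
  out <- abs_effects(es)
  expect_equal(out$yi, c(0.5, 0, 1.2))
  expect_equal(out$vi, es$vi)
  expect_equal(out$study_id, es$study_id)
})

make_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  f
}

base_rows <- function(n = 3) {
  data.frame(study_id = paste0("s", seq_len(n)), species = paste0("sp", seq_len(n)),
             component = "rate", year = 2010,
             mean_control = 5, sd_control = 1, n_control = 10,
             mean_noise = 6, sd_noise = 1.2, n_noise = 10)
}

test_that("read_records parses valid rows and reports invalid ones", {
  f <- make_csv(base_rows(3))
  rec <- read_records(f, quiet = TRUE)
  expect_equal(nrow(rec), 3)
  expect_equal(unname(attr(rec, "census")["effect_sizes"]), 3)

  bad <- base_rows(3)
  bad$n_control[2] <- 1
  rec <- read_records(make_csv(bad), quiet = TRUE)
  expect_equal(nrow(rec), 2)
  rej <- attr(rec, "rejections")
  expect_equal(rej$row, 2)
  expect_match(rej$reason, "n < 2")
})

test_that("read_records enforces the schema and collects row errors", {
  bad <- base_rows(3)
  bad$sd_noise <- NULL
  expect_error(read_records(make_csv(bad), quiet = TRUE), "sd_noise")

  bad <- base_rows(3)
  bad$mean_noise <- as.character(bad$mean_noise)
  bad$mean_noise[1] <- "oops"
  rec <- read_records(make_csv(bad), quiet = TRUE)
  expect_equal(nrow(rec), 2)
  expect_match(attr(rec, "rejections")$reason, "unparseable|missing")
})

test_that("read_records applies the SE-to-SD and yi/vi fallbacks with flags", {
  rows <- base_rows(2)
  rows$sd_control[1] <- NA
  rows$se_control <- c(0.5, NA)
  rec <- read_records(make_csv(rows), quiet = TRUE)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$sd_control[1], 0.5 * sqrt(10))
  expect_match(attr(rec, "flags"), "converted from SE", all = FALSE)

  rows <- base_rows(2)
  rows$mean_control[1] <- NA
  rows$yi <- c(0.4, NA)
  rows$vi <- c(0.05, NA)
  rec <- read_records(make_csv(rows), quiet = TRUE)
  expect_equal(nrow(rec), 2)
  eff <- compute_effects(rec)
  expect_equal(eff$yi[1], 0.4)
  expect_equal(eff$vi[1], 0.05)
})

test_that("peak frequency is pooled into the dominant-frequency level", {
  rows <- base_rows(2)
  rows$component <- c("peak_frequency", "Dominant frequency")
  rec <- read_records(make_csv(rows), quiet = TRUE)
  expect_equal(unique(rec$component), "dominant_frequency")
})

test_that("compute_effects agrees with smdh row-wise", {
  rec <- base_rows(3)
  rec$mean_noise <- c(6, 4, 5.5)
  eff <- compute_effects(rec)
  manual <- smdh(rec$mean_control, rec$sd_control, rec$n_control,
                 rec$mean_noise, rec$sd_noise, rec$n_noise)
  expect_equal(eff$yi, manual$yi)
  expect_equal(eff$vi, manual$vi)
  expect_equal(eff$component, rec$component)
})
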