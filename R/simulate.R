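#' Parameters of the synthetic noise-exposure dataset generator
#'
#' Bundles the generative settings mirroring the structure the analysis
#' assumes: species effects correlated by the tree, study effects nested in
#' species, effect-size-level effects, and two-group sampling error. The
#' defaults describe a typical noise-exposure meta-analytic scenario: 30
#' species, 2 studies per species, 2 effect sizes per study, 20 subjects per
#' group, a pooled effect of 0.5 SMD, and variance components
#' (phylo 0.2, study 0.1, effect size 0.05) in SMD-squared units.
#' \code{baseline_mean}/\code{baseline_sd} parameterize the control-group
#' trait distribution in arbitrary signal units (e.g. kHz); both groups
#' share the population SD, so the population SMDH of an effect equals its
#' true deviation \eqn{\delta_i}.
#'
#' @param n_species number of species (tips of the simulated tree).
#' @param studies_per_species,effects_per_study,n_per_group integer ranges
#'   (length-2 \code{c(min, max)}) sampled uniformly per species / study /
#'   effect.
#' @param mu true pooled effect (SMD units).
#' @param sigma2_phylo,sigma2_study,sigma2_es true variance components.
#' @param baseline_mean,baseline_sd control-group trait mean and SD.
#' @param years publication-year range.
#' @return A validated list of class \code{"sim_params"}.
#' @export
sim_params <- function(n_species = 30,
                       studies_per_species = c(2, 2),
                       effects_per_study = c(2, 2),
                       n_per_group = c(20, 20),
                       mu = 0.5,
                       sigma2_phylo = 0.2, sigma2_study = 0.1,
                       sigma2_es = 0.05,
                       baseline_mean = 4, baseline_sd = 1,
                       years = c(1998, 2018)) {
  p <- list(n_species = n_species,
            studies_per_species = studies_per_species,
            effects_per_study = effects_per_study,
            n_per_group = n_per_group, mu = mu,
            sigma2_phylo = sigma2_phylo, sigma2_study = sigma2_study,
            sigma2_es = sigma2_es,
            baseline_mean = baseline_mean, baseline_sd = baseline_sd,
            years = years)
  stopifnot(n_species >= 2, baseline_sd > 0,
            sigma2_phylo >= 0, sigma2_study >= 0, sigma2_es >= 0,
            length(studies_per_species) == 2,
            studies_per_species[1] >= 1,
            studies_per_species[1] <= studies_per_species[2],
            length(effects_per_study) == 2,
            effects_per_study[1] >= 1,
            effects_per_study[1] <= effects_per_study[2],
            length(n_per_group) == 2, n_per_group[1] >= 2,
            n_per_group[1] <= n_per_group[2],
            length(years) == 2, years[1] <= years[2])
  structure(p, class = "sim_params")
}

#' Simulate a random species tree
#'
#' Builds a rooted binary topology by sequential random joins of clades and
#' assigns Grafen branch lengths, so the result is ultrametric with
#' root-to-tip depth 1. A fixed seed fixes the topology.
#'
#' @param n_species number of tips (>= 2); labels are
#'   \code{Species_01, Species_02, ...}.
#' @param seed optional RNG seed; \code{NULL} uses the current stream.
#' @return An ultrametric \code{phylo} object.
#' @export
sim_tree <- function(n_species, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_species >= 2)
  clades <- sprintf("Species_%02d", seq_len(n_species))
  while (length(clades) > 1) {
    i <- sample.int(length(clades), 2)
    clades <- c(clades[-i], paste0("(", clades[i[1]], ",", clades[i[2]], ")"))
  }
  grafen_tree(ape::read.tree(text = paste0(clades, ";")))
}

#' Simulate true per-effect standardized mean differences
#'
#' Draws the latent structure of the multilevel model read generatively:
#' \eqn{\delta_i = \mu + a_{species(i)} + b_{study(i)} + e_i} with
#' \eqn{a \sim MVN(0, \sigma^2_{phylo} A)}, \eqn{b \sim N(0,
#' \sigma^2_{study})}, \eqn{e \sim N(0, \sigma^2_{es})}. Studies are nested
#' in species. Draw order within the single RNG stream: (1) the species
#' vector, (2) per species, its number of studies; per study, the study
#' effect and number of effects; per effect, its component, year, and
#' effect-level deviation — so extending the design never perturbs earlier
#' draws.
#'
#' @param tree ultrametric \code{phylo} over the species.
#' @param params a \code{\link{sim_params}} object.
#' @param components character vector of component labels cycled over the
#'   effects (any subset of the six signal components).
#' @return data.frame with \code{study_id}, \code{species},
#'   \code{component}, \code{year} and the true effect \code{delta}.
#' @export
sim_true_effects <- function(tree, params,
                             components = c("amplitude", "complexity",
                                            "dominant_frequency", "duration",
                                            "minimum_frequency", "rate")) {
  stopifnot(inherits(params, "sim_params"), inherits(tree, "phylo"))
  A <- phylo_cor(tree)
  sp <- rownames(A)
  a <- if (params$sigma2_phylo > 0)
    drop(t(chol(params$sigma2_phylo * A)) %*% stats::rnorm(length(sp)))
  else rep(0, length(sp))
  names(a) <- sp

  rows <- vector("list", length(sp))
  runif_int <- function(rg) if (rg[1] == rg[2]) rg[1] else
    sample(seq(rg[1], rg[2]), 1)
  for (s in seq_along(sp)) {
    ns <- runif_int(params$studies_per_species)
    srows <- vector("list", ns)
    for (st in seq_len(ns)) {
      b <- stats::rnorm(1, 0, sqrt(params$sigma2_study))
      ne <- runif_int(params$effects_per_study)
      comp <- sample(components, ne, replace = TRUE)
      yr <- sample(seq(params$years[1], params$years[2]), 1)
      e <- stats::rnorm(ne, 0, sqrt(params$sigma2_es))
      srows[[st]] <- data.frame(
        study_id = sprintf("Study_%s_%d", sp[s], st),
        species = sp[s], component = comp, year = yr,
        delta = params$mu + a[sp[s]] + b + e,
        stringsAsFactors = FALSE)
    }
    rows[[s]] <- do.call(rbind, srows)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate two-group study records from true effects
#'
#' For each true effect \eqn{\delta_i}, draws a control sample of n subjects
#' from \eqn{N(baseline\_mean, baseline\_sd^2)} and a noise-exposed sample
#' from \eqn{N(baseline\_mean + \delta_i \cdot baseline\_sd,
#' baseline\_sd^2)}, then summarizes each to (mean, sd, n). Both groups
#' share the population SD, so the population SMDH equals \eqn{\delta_i}
#' and \code{\link{smdh}} is exercised end to end.
#'
#' @param truth output of \code{\link{sim_true_effects}}.
#' @param params a \code{\link{sim_params}} object.
#' @return data.frame in the input-CSV schema of \code{\link{read_records}}.
#' @export
sim_records <- function(truth, params) {
  stopifnot(inherits(params, "sim_params"))
  k <- nrow(truth)
  runif_int <- function(rg, n) if (rg[1] == rg[2]) rep(rg[1], n) else
    sample(seq(rg[1], rg[2]), n, replace = TRUE)
  n_c <- runif_int(params$n_per_group, k)
  n_n <- runif_int(params$n_per_group, k)
  mc <- sc <- mn <- sn <- numeric(k)
  for (i in seq_len(k)) {
    x <- stats::rnorm(n_c[i], params$baseline_mean, params$baseline_sd)
    y <- stats::rnorm(n_n[i],
                      params$baseline_mean + truth$delta[i] * params$baseline_sd,
                      params$baseline_sd)
    mc[i] <- mean(x); sc[i] <- stats::sd(x)
    mn[i] <- mean(y); sn[i] <- stats::sd(y)
  }
  data.frame(study_id = truth$study_id, species = truth$species,
             component = truth$component, year = truth$year,
             mean_control = mc, sd_control = sc, n_control = n_c,
             mean_noise = mn, sd_noise = sn, n_noise = n_n,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic dataset
#'
#' Runs \code{\link{sim_tree}}, \code{\link{sim_true_effects}} and
#' \code{\link{sim_records}} under one seeded RNG stream. With
#' \code{fast = TRUE} the two-group sampling stage is skipped and
#' \eqn{(y_i, v_i)} are emitted directly, with \eqn{v_i} set to the
#' theoretical SMDH variance at the population values
#' (\eqn{v_i = 2/(n-1) + \delta_i^2/(4(n-1))}, equal group sizes and SDs).
#'
#' @param params a \code{\link{sim_params}} object.
#' @param seed RNG seed fixing the entire stream.
#' @param fast emit \code{(yi, vi)} directly instead of group summaries.
#' @param components passed to \code{\link{sim_true_effects}}.
#' @return A list of class \code{"sim_dataset"}: \code{records} (or
#'   \code{effects} when \code{fast}), \code{tree}, \code{truth} (the true
#'   per-effect deltas) and \code{params}.
#' @export
sim_dataset <- function(params = sim_params(), seed = NULL, fast = FALSE,
                        components = c("amplitude", "complexity",
                                       "dominant_frequency", "duration",
                                       "minimum_frequency", "rate")) {
  if (!is.null(seed)) set.seed(seed)
  tree <- sim_tree(params$n_species)
  truth <- sim_true_effects(tree, params, components = components)
  out <- list(tree = tree, truth = truth, params = params)
  if (fast) {
    n <- if (params$n_per_group[1] == params$n_per_group[2])
      rep(params$n_per_group[1], nrow(truth)) else
      sample(seq(params$n_per_group[1], params$n_per_group[2]),
             nrow(truth), replace = TRUE)
    vi <- 2 / (n - 1) + truth$delta^2 / (4 * (n - 1))
    out$effects <- data.frame(
      yi = stats::rnorm(nrow(truth), truth$delta, sqrt(vi)), vi = vi,
      study_id = truth$study_id, species = truth$species,
      component = truth$component, year = truth$year,
      stringsAsFactors = FALSE)
  } else {
    out$records <- sim_records(truth, params)
  }
  structure(out, class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  tab <- if (is.null(x$records)) x$effects else x$records
  cat(sprintf(
    "Synthetic noise-exposure dataset: %d effect sizes, %d studies, %d species%s\n",
    nrow(tab), length(unique(tab$study_id)), length(unique(tab$species)),
    if (is.null(x$records)) " (fast mode: yi/vi only)" else ""))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the records CSV (same schema as \code{\link{read_records}}), the
#' tree as newick, and a JSON sidecar with the true parameters and
#' per-effect deltas.
#'
#' @param sim a \code{"sim_dataset"} object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- if (is.null(sim$records)) sim$effects else sim$records
  paths <- c(csv = file.path(dir, "dataset.csv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(tab, paths["csv"], row.names = FALSE)
  ape::write.tree(sim$tree, paths["tree"])
  writeLines(jsonlite::toJSON(list(params = unclass(sim$params),
                                   delta = sim$truth$delta),
                              auto_unbox = TRUE, digits = NA),
             paths["truth"])
  invisible(paths)
}

#' Parameter-recovery suite for the full pipeline
#'
#' Simulates replicate datasets at the given parameters, runs the whole
#' pipeline (group summaries -> SMDH -> phylogenetic multilevel REML fit)
#' on each, and reports bias and CI coverage for the pooled effect and the
#' variance components.
#'
#' @param params a \code{\link{sim_params}} object (the true values).
#' @param n_replicates number of replicate datasets.
#' @param seed RNG seed fixing the whole suite.
#' @param fast use the summary-free fast mode of \code{\link{sim_dataset}}.
#' @return An object of class \code{"recovery_suite"}: per-replicate
#'   estimates (\code{draws}) plus summary \code{bias}, \code{coverage}
#'   (of the 95\% CI for mu) and mean variance-component estimates.
#' @export
recovery_suite <- function(params = sim_params(), n_replicates = 50,
                           seed = 1, fast = FALSE) {
  set.seed(seed)
  draws <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sim <- sim_dataset(params, seed = NULL, fast = fast)
    effects <- if (fast) sim$effects else compute_effects(sim$records)
    A <- phylo_cor(sim$tree)
    fit <- meta_ml(effects$yi, effects$vi, study = effects$study_id,
                   species = effects$species, phylo = A)
    draws[[r]] <- data.frame(
      mu_hat = unname(fit$b[1]), se = unname(fit$se[1]),
      covered = fit$ci.lb[1] <= params$mu & params$mu <= fit$ci.ub[1],
      s2_es = fit$sigma2["es"], s2_study = fit$sigma2["study"],
      s2_phylo = fit$sigma2["phylo"], converged = fit$converged)
  }
  draws <- do.call(rbind, draws)
  rownames(draws) <- NULL
  structure(list(
    draws = draws,
    bias = mean(draws$mu_hat) - params$mu,
    coverage = mean(draws$covered),
    sigma2_mean = c(es = mean(draws$s2_es), study = mean(draws$s2_study),
                    phylo = mean(draws$s2_phylo)),
    sigma2_true = c(es = params$sigma2_es, study = params$sigma2_study,
                    phylo = params$sigma2_phylo),
    mu_true = params$mu, n_replicates = n_replicates, seed = seed),
    class = "recovery_suite")
}

#' @export
print.recovery_suite <- function(x, digits = 4, ...) {
  cat(sprintf("Parameter recovery over %d replicates:\n", x$n_replicates))
  cat(sprintf("  pooled effect: true %.3f, mean bias %+.*f, 95%% CI coverage %.3f\n",
              x$mu_true, digits, x$bias, x$coverage))
  cat("  variance components (mean estimate / true):\n")
  for (nm in names(x$sigma2_mean))
    cat(sprintf("    %-6s %.*f / %.*f\n", nm, digits, x$sigma2_mean[nm],
                digits, x$sigma2_true[nm]))
  invisible(x)
}
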