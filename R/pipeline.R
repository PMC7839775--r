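#' Analyse one signal component
#'
#' Subsets the effect sizes to one signal component, fits the
#' phylogenetically controlled multilevel model for either the magnitude
#' (absolute effect sizes) or the direction (signed), and assembles one
#' fully populated summary row: pooled estimate with z-inference, the
#' multilevel I-squared partition, and Cochran's Q.
#'
#' @param effects data.frame from \code{\link{compute_effects}} (columns
#'   \code{yi}, \code{vi}, \code{study_id}, \code{species},
#'   \code{component}, \code{year}).
#' @param phylo species correlation matrix covering the dataset species
#'   (\code{NULL} drops the phylogenetic stratum).
#' @param component one of the six signal components.
#' @param kind \code{"magnitude"} or \code{"direction"}.
#' @param mode magnitude mode, see \code{\link{magnitude_fit}}.
#' @param ... passed to the fitting function.
#' @return A one-row data.frame: component, kind, k, studies, species,
#'   estimate, se, zval, ci.lb, ci.ub, pval, i2_es, i2_study, i2_phylo,
#'   i2_total, Q, Q_df, Q_p; the underlying fit is in attribute
#'   \code{"fit"}.
#' @export
run_component <- function(effects, phylo = NULL, component, kind,
                          mode = "abs", ...) {
  kind <- match.arg(kind, c("magnitude", "direction"))
  sub <- effects[effects$component == component, , drop = FALSE]
  if (nrow(sub) < 2)
    stop("component '", component, "' has fewer than 2 effect sizes",
         call. = FALSE)
  sub_phylo <- if (!is.null(phylo)) align_phylo(phylo, sub$species)$A
  fit <- if (kind == "magnitude")
    magnitude_fit(sub, phylo = sub_phylo, mode = mode, ...)
  else direction_fit(sub, phylo = sub_phylo, ...)
  q <- if (kind == "magnitude") cochran_q(abs(sub$yi), sub$vi)
  else cochran_q(sub$yi, sub$vi)
  i2 <- heterogeneity(fit)
  row <- data.frame(
    component = component, kind = kind,
    k = nrow(sub), studies = length(unique(sub$study_id)),
    species = length(unique(sub$species)),
    estimate = unname(fit$b[1]), se = unname(fit$se[1]),
    zval = unname(fit$zval[1]),
    ci.lb = unname(fit$ci.lb[1]), ci.ub = unname(fit$ci.ub[1]),
    pval = unname(fit$pval[1]),
    i2_es = i2$i2_es, i2_study = i2$i2_study, i2_phylo = i2$i2_phylo,
    i2_total = i2$i2_total,
    Q = q$Q, Q_df = q$df, Q_p = q$p,
    stringsAsFactors = FALSE)
  attr(row, "fit") <- fit
  row
}

#' Per-species forest data for one component
#'
#' For each species within a component, pools its effect sizes with
#' fixed-effect (inverse-variance) weights and attaches a 95\% Wald CI; a
#' species with a single effect size gets the effect itself. This is a
#' display convention for species-level forest plots, not an inferential
#' model.
#'
#' @param effects effect-size data.frame (see \code{\link{run_component}}).
#' @param component signal component to display.
#' @param kind \code{"magnitude"} (absolute values) or \code{"direction"}.
#' @param level confidence level.
#' @return data.frame: species, k, estimate, se, ci.lb, ci.ub, ordered by
#'   species label.
#' @export
forest_data <- function(effects, component, kind = "direction",
                        level = 0.95) {
  kind <- match.arg(kind, c("magnitude", "direction"))
  sub <- effects[effects$component == component, , drop = FALSE]
  if (!nrow(sub)) stop("no effect sizes for component '", component, "'",
                       call. = FALSE)
  if (kind == "magnitude") sub <- abs_effects(sub)
  zc <- stats::qnorm(1 - (1 - level) / 2)
  out <- lapply(split(sub, sub$species), function(d) {
    w <- 1 / d$vi
    est <- sum(w * d$yi) / sum(w)
    se <- sqrt(1 / sum(w))
    data.frame(species = d$species[1], k = nrow(d), estimate = est, se = se,
               ci.lb = est - zc * se, ci.ub = est + zc * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[sort(names(out))])
  rownames(out) <- NULL
  out
}

#' Run the full per-component analysis
#'
#' Orchestrates the complete analysis: for every signal component present,
#' fits both the magnitude and the direction model, partitions
#' heterogeneity, computes Cochran's Q, per-species forest data, funnel
#' coordinates, and Egger-type and time-lag bias tests. Outputs are
#' deterministic functions of the inputs. Components with fewer than 2
#' effect sizes are skipped with a log entry, and every boundary-zero
#' variance component is logged.
#'
#' @param records parsed study records (see \code{\link{read_records}}) or
#'   an effects data.frame already carrying \code{yi}/\code{vi}.
#' @param tree species tree (\code{phylo}); branch lengths are replaced by
#'   Grafen lengths when absent. \code{NULL} drops the phylogenetic stratum.
#' @param components components to analyse (default: all present).
#' @param mode magnitude mode (see \code{\link{magnitude_fit}}).
#' @param egger_alpha significance level of the Egger verdict.
#' @param level confidence level of all intervals.
#' @param outdir optional directory; when given, writes \code{results.csv},
#'   \code{results.json}, \code{forest_<component>_<kind>.csv},
#'   \code{funnel_<component>.csv}, \code{bias_tests.csv} and
#'   \code{run.log}.
#' @return A list of class \code{"noise_analysis"}: \code{table} (one row
#'   per component x kind), \code{forest} (named list of data.frames),
#'   \code{funnel} (named list), \code{bias} (data.frame of per-component
#'   Egger and time-lag tests, magnitude and direction both computed and
#'   labelled), and \code{log} (character).
#' @export
run_all <- function(records, tree = NULL, components = NULL, mode = "abs",
                    egger_alpha = 0.1, level = 0.95, outdir = NULL) {
  effects <- if (all(c("yi", "vi") %in% names(records))) records
  else compute_effects(records)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  A <- NULL
  if (!is.null(tree)) {
    if (is.null(tree$edge.length)) {
      tree <- grafen_tree(tree)
      note("tree had no branch lengths; Grafen lengths applied")
    }
    A <- phylo_cor(tree)
  }
  if (is.null(components)) components <- sort(unique(effects$component))

  rows <- list(); forest <- list(); funnel <- list(); bias <- list()
  for (comp in components) {
    sub <- effects[effects$component == comp, , drop = FALSE]
    if (nrow(sub) < 2) {
      note("component '%s' skipped: %d effect size(s)", comp, nrow(sub))
      next
    }
    for (kind in c("magnitude", "direction")) {
      row <- run_component(effects, phylo = A, component = comp,
                           kind = kind, mode = mode, level = level)
      fit <- attr(row, "fit")
      zero <- names(fit$sigma2)[fit$sigma2 == 0]
      if (length(zero))
        note("component '%s' (%s): variance component(s) at boundary zero: %s",
             comp, kind, paste(zero, collapse = ", "))
      rows[[paste(comp, kind)]] <- row
      forest[[paste0(comp, "_", kind)]] <- forest_data(effects, comp, kind,
                                                       level = level)
      if (kind == "magnitude")
        funnel[[comp]] <- funnel_data(fit)
      # bias diagnostics per component, both scales computed and labelled
      dat <- if (kind == "magnitude") abs_effects(sub) else sub
      sub_A <- if (!is.null(A)) align_phylo(A, sub$species)$A
      eg <- tryCatch(eggers_test(dat, phylo = sub_A, alpha = egger_alpha,
                                 level = level),
                     error = function(e) e)
      tl <- tryCatch(time_lag_test(sub, phylo = sub_A, level = level),
                     error = function(e) e)
      for (nm in c("egger", "time_lag")) {
        bt <- if (nm == "egger") eg else tl
        if (inherits(bt, "error")) {
          note("component '%s' (%s): %s test unavailable: %s", comp, kind,
               nm, conditionMessage(bt))
        } else {
          bias[[paste(comp, kind, nm)]] <- data.frame(
            component = comp, kind = kind, test = nm,
            coefficient = bt$coefficient, estimate = bt$estimate,
            se = bt$se, zval = bt$zval, pval = bt$pval,
            alpha = bt$alpha, biased = bt$biased,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  bias <- if (length(bias)) do.call(rbind, bias) else NULL
  if (!is.null(bias)) rownames(bias) <- NULL

  res <- structure(list(table = tab, forest = forest, funnel = funnel,
                        bias = bias, log = log), class = "noise_analysis")
  if (!is.null(outdir)) .write_analysis(res, outdir)
  res
}

.write_analysis <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$table, file.path(outdir, "results.csv"),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(res$table, dataframe = "rows", digits = NA),
             file.path(outdir, "results.json"))
  for (nm in names(res$forest))
    utils::write.csv(res$forest[[nm]],
                     file.path(outdir, paste0("forest_", nm, ".csv")),
                     row.names = FALSE)
  for (nm in names(res$funnel))
    utils::write.csv(res$funnel[[nm]],
                     file.path(outdir, paste0("funnel_", nm, ".csv")),
                     row.names = FALSE)
  if (!is.null(res$bias))
    utils::write.csv(res$bias, file.path(outdir, "bias_tests.csv"),
                     row.names = FALSE)
  writeLines(res$log, file.path(outdir, "run.log"))
  invisible(outdir)
}

#' @export
print.noise_analysis <- function(x, digits = 2, ...) {
  cat("Per-component noise-adjustment analysis\n\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  if (length(x$log)) {
    cat("\nLog:\n")
    cat(paste0("  ", x$log, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Path to a packaged example file
#'
#' The package ships two small plain-text fixtures: a synthetic
#' noise-exposure dataset (\code{"dataset"}) whose study structure — 121
#' effect sizes from 23 studies on 31 species, with per-component counts
#' matching a published noise meta-analysis — is realistic but whose
#' numbers are simulated, and a matching synthetic species tree
#' (\code{"tree"}).
#'
#' @param which \code{"dataset"} or \code{"tree"}.
#' @return Path to the file.
#' @export
noisemeta_example <- function(which = c("dataset", "tree")) {
  which <- match.arg(which)
  fn <- switch(which, dataset = "noise_dataset_synthetic.csv",
               tree = "species_tree_synthetic.nwk")
  system.file("extdata", fn, package = "noisemeta", mustWork = TRUE)
}
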