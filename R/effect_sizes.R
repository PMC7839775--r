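#' Standardized mean difference with heteroscedastic group variances (SMDH)
#'
#' Computes the standardized mean difference between a noise-exposure group
#' and a control group without assuming equal population variances, together
#' with its large-sample sampling variance (Bonett 2008, 2009). The
#' standardizer is the square root of the average of the two group variances,
#' and the estimate carries the exact small-sample bias correction
#' \eqn{J(m) = \Gamma(m/2)/(\sqrt{m/2}\,\Gamma((m-1)/2))} with
#' \eqn{m = n_c + n_n - 2} (approximately \eqn{1 - 3/(4m - 1)}).
#'
#' The sign convention is noise minus control: positive \code{yi} means the
#' signal component is larger under noise exposure.
#'
#' @param mean_control,sd_control,n_control summary statistics of the control
#'   group: mean, standard deviation (> 0) and sample size (>= 2).
#' @param mean_noise,sd_noise,n_noise the same for the noise-exposed group.
#' @return A data.frame with columns \code{yi} (SMDH estimate, unitless) and
#'   \code{vi} (its sampling variance), one row per input element.
#' @examples
#' smdh(10, 2, 10, 12, 4, 10)
#' @export
smdh <- function(mean_control, sd_control, n_control,
                 mean_noise, sd_noise, n_noise) {
  args <- cbind(mean_control, sd_control, n_control,
                mean_noise, sd_noise, n_noise)
  if (anyNA(args))
    stop("group summaries contain missing values", call. = FALSE)
  if (any(n_control < 2) || any(n_noise < 2))
    stop("each group needs n >= 2", call. = FALSE)
  if (any(sd_control <= 0) || any(sd_noise <= 0))
    stop("group standard deviations must be > 0", call. = FALSE)

  sp2 <- (sd_control^2 + sd_noise^2) / 2
  # exact small-sample correction J(m) = Gamma(m/2)/(sqrt(m/2) Gamma((m-1)/2))
  # with m = n_c + n_n - 2; approximately 1 - 3/(4m - 1)
  m <- n_control + n_noise - 2
  j <- exp(lgamma(m / 2) - lgamma((m - 1) / 2)) / sqrt(m / 2)
  yi <- j * (mean_noise - mean_control) / sqrt(sp2)
  # Bonett's large-sample variance for the heteroscedastic standardizer
  vi <- yi^2 * (sd_control^4 / (n_control - 1) + sd_noise^4 / (n_noise - 1)) /
          (8 * sp2^2) +
        (sd_control^2 / (n_control - 1) + sd_noise^2 / (n_noise - 1)) / sp2
  data.frame(yi = as.numeric(yi), vi = as.numeric(vi))
}

#' Fold effect sizes to absolute values
#'
#' Replaces each effect size by its absolute value, leaving sampling
#' variances and labels untouched. Used for magnitude analyses, where the
#' question is how much a signal component changes rather than which way.
#'
#' @param effects a data.frame with at least columns \code{yi} and \code{vi}.
#' @return The same data.frame with \code{yi} replaced by \code{abs(yi)}.
#' @export
abs_effects <- function(effects) {
  stopifnot(is.data.frame(effects), all(c("yi", "vi") %in% names(effects)))
  effects$yi <- abs(effects$yi)
  effects
}

# the six recognized signal components; dominant and peak frequency are
# biologically comparable (both locate the frequency with most energy) and
# are pooled into one level
.components <- c("amplitude", "complexity", "dominant_frequency",
                 "duration", "minimum_frequency", "rate")

.normalize_component <- function(x) {
  x <- gsub("[ -]+", "_", tolower(trimws(x)))
  x[x == "peak_frequency"] <- "dominant_frequency"
  x
}

#' Read a noise-exposure effect-size dataset
#'
#' Parses a CSV of two-group experimental contrasts, one row per effect size.
#' Required columns: \code{study_id}, \code{species}, \code{component},
#' \code{year}, \code{mean_control}, \code{sd_control}, \code{n_control},
#' \code{mean_noise}, \code{sd_noise}, \code{n_noise}. \code{component} must
#' be one of amplitude, complexity, dominant_frequency (peak_frequency is
#' mapped to it), duration, minimum_frequency, rate.
#'
#' Rows violating the invariants (n < 2, sd <= 0, unparseable numerics) are
#' collected with their row numbers in the \code{"rejections"} attribute and
#' reported, never silently dropped. Two fallbacks are applied and flagged:
#' rows with a missing SD but a reported SE column (\code{se_control} /
#' \code{se_noise}) use \code{sd = se * sqrt(n)}; rows carrying precomputed
#' \code{yi}, \code{vi} columns are passed through verbatim by
#' \code{\link{compute_effects}}.
#'
#' @param path path to the CSV file (UTF-8, header row required).
#' @param quiet suppress the census message.
#' @return A data.frame of validated study records with attributes
#'   \code{"rejections"} (data.frame of row, reason), \code{"flags"}
#'   (character notes on conversions) and \code{"census"} (effect sizes,
#'   studies, species counts).
#' @export
read_records <- function(path, quiet = FALSE) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  required <- c("study_id", "species", "component", "year",
                "mean_control", "sd_control", "n_control",
                "mean_noise", "sd_noise", "n_noise")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  num_cols <- c("year", "mean_control", "sd_control", "n_control",
                "mean_noise", "sd_noise", "n_noise")
  flags <- character(0)
  rej <- list()
  reject <- function(row, reason) rej[[length(rej) + 1L]] <<-
    data.frame(row = row, reason = reason)

  for (cl in num_cols) {
    if (!is.numeric(raw[[cl]])) {
      coerced <- suppressWarnings(as.numeric(raw[[cl]]))
      bad <- which(is.na(coerced) & !is.na(raw[[cl]]) &
                     !(cl %in% c("sd_control", "sd_noise")))
      for (b in bad) reject(b, paste0("unparseable numeric in ", cl))
      raw[[cl]] <- coerced
    }
  }

  # SE -> SD fallback
  for (side in c("control", "noise")) {
    sdc <- paste0("sd_", side); sec <- paste0("se_", side)
    nc <- paste0("n_", side)
    if (sec %in% names(raw)) {
      sev <- suppressWarnings(as.numeric(raw[[sec]]))
      fix <- which(is.na(raw[[sdc]]) & !is.na(sev))
      if (length(fix)) {
        raw[[sdc]][fix] <- sev[fix] * sqrt(raw[[nc]][fix])
        flags <- c(flags, sprintf(
          "row %d: %s converted from SE (sd = se*sqrt(n))", fix, side))
      }
    }
  }

  has_yivi <- all(c("yi", "vi") %in% names(raw))
  raw$component <- .normalize_component(raw$component)

  ok <- rep(TRUE, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    r <- raw[i, ]
    pre <- has_yivi && is.finite(suppressWarnings(as.numeric(r$yi))) &&
      is.finite(suppressWarnings(as.numeric(r$vi)))
    if (!(r$component %in% .components)) {
      reject(i, paste0("unknown component '", r$component, "'")); ok[i] <- FALSE
    } else if (!pre) {
      if (anyNA(r[num_cols])) {
        reject(i, "missing group summary"); ok[i] <- FALSE
      } else if (r$n_control < 2 || r$n_noise < 2) {
        reject(i, "group sample size n < 2"); ok[i] <- FALSE
      } else if (r$sd_control <= 0 || r$sd_noise <= 0) {
        reject(i, "group sd <= 0"); ok[i] <- FALSE
      }
    } else {
      flags <- c(flags, sprintf("row %d: precomputed yi/vi passed through", i))
    }
  }

  records <- raw[ok, , drop = FALSE]
  rownames(records) <- NULL
  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(row = integer(0), reason = character(0))
  census <- c(effect_sizes = nrow(records),
              studies = length(unique(records$study_id)),
              species = length(unique(records$species)))
  attr(records, "rejections") <- rejections
  attr(records, "flags") <- flags
  attr(records, "census") <- census
  if (!quiet) {
    message(sprintf("parsed %d effect sizes from %d studies on %d species",
                    census[1], census[2], census[3]))
    if (nrow(rejections))
      message(sprintf("rejected %d row(s): %s", nrow(rejections),
                      paste(sprintf("#%d (%s)", rejections$row,
                                    rejections$reason), collapse = "; ")))
    for (f in flags) message(f)
  }
  records
}

#' Compute effect sizes from study records
#'
#' Applies \code{\link{smdh}} row-wise to a parsed record table. Rows that
#' carry precomputed \code{yi}/\code{vi} columns (e.g. from sources reporting
#' the effect size directly) are passed through verbatim.
#'
#' @param records a data.frame as returned by \code{\link{read_records}}.
#' @return A data.frame with columns \code{yi}, \code{vi}, \code{study_id},
#'   \code{species}, \code{component}, \code{year}.
#' @export
compute_effects <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  has_yivi <- all(c("yi", "vi") %in% names(records))
  pre <- if (has_yivi)
    is.finite(suppressWarnings(as.numeric(records$yi))) &
    is.finite(suppressWarnings(as.numeric(records$vi)))
  else rep(FALSE, nrow(records))

  yi <- vi <- numeric(nrow(records))
  if (any(!pre)) {
    es <- smdh(records$mean_control[!pre], records$sd_control[!pre],
               records$n_control[!pre],
               records$mean_noise[!pre], records$sd_noise[!pre],
               records$n_noise[!pre])
    yi[!pre] <- es$yi; vi[!pre] <- es$vi
  }
  if (any(pre)) {
    yi[pre] <- as.numeric(records$yi[pre])
    vi[pre] <- as.numeric(records$vi[pre])
  }
  data.frame(yi = yi, vi = vi,
             study_id = as.character(records$study_id),
             species = as.character(records$species),
             component = as.character(records$component),
             year = records$year,
             stringsAsFactors = FALSE)
}
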