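#' Read a species tree from a newick file or string
#'
#' Thin wrapper around \code{\link[ape]{read.tree}} that validates tip labels
#' and records whether branch lengths were supplied. Trees without branch
#' lengths can be given Grafen lengths with \code{\link{grafen_tree}}.
#'
#' @param path path to a newick file, or a literal newick string ending in
#'   \code{";"}.
#' @return An \code{ape} \code{phylo} object.
#' @export
read_tree <- function(path) {
  tree <- if (grepl(";", path, fixed = TRUE))
    ape::read.tree(text = path)
  else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    ape::read.tree(path)
  }
  if (is.null(tree)) stop("could not parse newick input", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  tree
}

#' Assign Grafen branch lengths
#'
#' Gives every internal node a height proportional to (number of descendant
#' tips - 1) raised to the power \code{rho}, rescaled so the root has height 1
#' and tips height 0; each edge length is the height difference between its
#' endpoints. The result is an ultrametric tree with root-to-tip depth 1,
#' suitable for building a Brownian-motion correlation matrix from a
#' topology without divergence-time estimates.
#'
#' @param tree a rooted \code{phylo} object (branch lengths, if any, are
#'   discarded).
#' @param rho positive exponent applied to the relative node heights;
#'   \code{rho = 1} is the conventional default.
#' @return The tree with Grafen branch lengths.
#' @export
grafen_tree <- function(tree, rho = 1) {
  stopifnot(inherits(tree, "phylo"), rho > 0)
  if (!ape::is.rooted(tree) && tree$Nnode > 1)
    stop("tree must be rooted", call. = FALSE)
  ape::compute.brlen(tree, method = "Grafen", power = rho)
}

#' Phylogenetic correlation matrix
#'
#' Builds the species-by-species correlation matrix implied by a
#' Brownian-motion model on an ultrametric tree: entry (i, j) is the depth of
#' the most recent common ancestor of i and j divided by the total
#' root-to-tip depth. The diagonal is exactly 1. This matrix is the
#' covariance structure of the phylogenetic random effect in
#' \code{\link{meta_ml}}.
#'
#' @param tree an ultrametric \code{phylo} object with branch lengths (see
#'   \code{\link{grafen_tree}}).
#' @param tol relative tolerance for the ultrametricity check.
#' @return A symmetric positive semi-definite matrix with unit diagonal,
#'   dimnames set to the tip labels.
#' @export
phylo_cor <- function(tree, tol = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; apply grafen_tree() first",
         call. = FALSE)
  if (!ape::is.ultrametric(tree, tol = tol, option = 2))
    stop("tree is not ultrametric; apply grafen_tree() or supply an ",
         "ultrametric tree", call. = FALSE)
  A <- ape::vcv(tree, corr = TRUE)
  # guard against round-off on the diagonal
  diag(A) <- 1
  (A + t(A)) / 2
}

.normalize_label <- function(x) tolower(gsub("[ ]+", "_", trimws(x)))

#' Align a phylogenetic correlation matrix to a dataset
#'
#' Restricts and reorders a correlation matrix to the species present in an
#' effect-size dataset. Species names are matched after normalization
#' (spaces to underscores, case-insensitive); an ambiguous or missing match
#' is an error, never a guess.
#'
#' @param A correlation matrix with species dimnames (see
#'   \code{\link{phylo_cor}}).
#' @param species character vector of dataset species labels (one per
#'   effect size, duplicates fine).
#' @return A list with \code{A} (matrix over the unique dataset species, in
#'   first-appearance order) and \code{index} (integer vector mapping each
#'   element of \code{species} to a row of \code{A}).
#' @export
align_phylo <- function(A, species) {
  stopifnot(is.matrix(A), !is.null(rownames(A)))
  tips_norm <- .normalize_label(rownames(A))
  if (anyDuplicated(tips_norm))
    stop("tree tip labels are ambiguous after normalization: ",
         paste(rownames(A)[duplicated(tips_norm) |
                             duplicated(tips_norm, fromLast = TRUE)],
               collapse = ", "), call. = FALSE)
  sp_norm <- .normalize_label(species)
  u_norm <- unique(sp_norm)
  sp_unique <- species[match(u_norm, sp_norm)]  # first raw spelling
  hit <- match(u_norm, tips_norm)
  if (anyNA(hit))
    stop("species missing from tree: ",
         paste(sp_unique[is.na(hit)], collapse = ", "), call. = FALSE)
  Asub <- A[hit, hit, drop = FALSE]
  dimnames(Asub) <- list(sp_unique, sp_unique)
  list(A = Asub, index = match(sp_norm, u_norm))
}

#' Export a correlation matrix as CSV
#'
#' @param A matrix with species dimnames.
#' @param path output file.
#' @export
write_phylo_cor <- function(A, path) {
  utils::write.csv(as.data.frame(A), path, row.names = TRUE)
  invisible(path)
}
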