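#' Read and validate a time-calibrated phylogeny
#'
#' Parses Newick (via ape) and checks the properties the regression engine
#' relies on: unique tip labels, branch lengths present and non-negative,
#' and approximate ultrametricity (root-to-tip depths within 1% of each
#' other; a warning, not an error, since summary trees can carry small
#' rounding noise).
#'
#' @param x Path to a Newick file, or a Newick string, or an `ape::phylo`
#'   object.
#' @return An `ape::phylo` object with normalized tip labels
#'   (see [normalize_taxon_names()]).
#' @export
read_phylogeny <- function(x) {
  tree <- if (inherits(x, "phylo")) {
    x
  } else if (is.character(x) && length(x) == 1 && grepl("\\(", x)) {
    ape::read.tree(text = x)
  } else {
    ape::read.tree(x)
  }
  if (is.null(tree)) stop("malformed Newick input", call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("phylogeny has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("phylogeny has negative branch lengths", call. = FALSE)
  }
  tree$tip.label <- normalize_taxon_names(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  if (diff(range(depths)) > 0.01 * max(depths)) {
    warning("tree is not ultrametric: root-to-tip depths vary by more than 1%",
            call. = FALSE)
  }
  tree
}

#' Normalize taxon names for tree/table matching
#'
#' Unifies whitespace and underscores (case-sensitive otherwise) so tip
#' labels and trait-table keys compare reliably.
#'
#' @param x Character vector of taxon names.
#' @return Normalized names with internal spaces replaced by underscores.
#' @export
normalize_taxon_names <- function(x) {
  gsub("\\s+", "_", trimws(x))
}

#' Phylogenetic covariance matrix
#'
#' `C[i, j]` is the summed branch length from the root to the most recent
#' common ancestor of tips i and j — the shared phylogenetic history in
#' time units — and `C[i, i]` is the root-to-tip depth. This is the
#' Brownian-motion expectation of trait covariance among tips.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param order Optional character vector of tip labels giving the
#'   row/column order (must be a subset of the tree's tips; the tree is
#'   pruned to it).
#' @return A symmetric positive semi-definite matrix with dimnames.
#' @export
phylo_covariance <- function(tree, order = NULL) {
  tree <- read_phylogeny(tree)
  if (!is.null(order)) {
    order <- normalize_taxon_names(order)
    missing <- setdiff(order, tree$tip.label)
    if (length(missing)) {
      stop("taxa absent from tree: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    drop <- setdiff(tree$tip.label, order)
    if (length(drop)) tree <- ape::drop.tip(tree, drop)
  }
  C <- ape::vcv.phylo(tree)
  if (!is.null(order)) C <- C[order, order, drop = FALSE]
  C
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries (shared history) by `lambda`,
#' leaving tip variances unchanged. `lambda = 1` is strict Brownian
#' motion; `lambda = 0` removes all phylogenetic covariance (independent
#' tips).
#'
#' @param C Phylogenetic covariance matrix.
#' @param lambda Scalar in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  }
  V <- C * lambda
  diag(V) <- diag(C)
  V
}
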