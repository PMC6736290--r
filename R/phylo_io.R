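#' Read and validate a rooted, time-calibrated phylogeny
#'
#' Parses a Newick string or file into an [ape::phylo] object and enforces the
#' contract the downstream comparative analyses rely on: a single root, unique
#' tip labels, and a non-negative branch length on every edge. Polytomies are
#' accepted and never resolved.
#'
#' @param x a Newick string (must contain `"("`) or a path to a Newick file.
#' @return an object of class `phylo`.
#' @export
read_phylogeny <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  tree <- if (grepl("(", x, fixed = TRUE)) {
    tryCatch(ape::read.tree(text = x),
             error = function(e) stop("malformed Newick string: ",
                                      conditionMessage(e), call. = FALSE))
  } else {
    if (!file.exists(x)) stop("no such file: ", x, call. = FALSE)
    ape::read.tree(x)
  }
  if (is.null(tree)) stop("malformed Newick: could not parse input", call. = FALSE)
  validate_phylogeny(tree)
  tree
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))
    stop("missing branch length on edge(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(tree$edge.length < 0))
    stop("negative branch length on edge(s) ",
         paste(which(tree$edge.length < 0), collapse = ", "), call. = FALSE)
  invisible(tree)
}

#' Write a phylogeny as Newick
#'
#' Serialises with enough digits that `read_phylogeny(write_phylogeny(t))`
#' reproduces branch lengths to better than 1e-12.
#'
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_phylogeny <- function(tree, file = NULL) {
  validate_phylogeny(tree)
  txt <- ape::write.tree(tree, digits = 15)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Prune a phylogeny to a set of taxa
#'
#' Keeps the requested tips, suppressing the degree-2 internal nodes this
#' creates (their branch lengths are summed), so all pairwise patristic
#' distances among retained tips are unchanged.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  validate_phylogeny(tree)
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(keep) < 2L) stop("need at least 2 taxa to keep", call. = FALSE)
  ape::keep.tip(tree, keep)
}

#' Height of a tree (maximum root-to-tip path length)
#' @param tree a `phylo` object.
#' @return numeric scalar, in the branch-length units (My here).
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}

#' Is the tree ultrametric (to a relative tolerance)?
#'
#' @param tree a `phylo` object.
#' @param tol relative tolerance on root-to-tip depth spread, as a fraction
#'   of tree height; default `1e-6`.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  h <- max(depths)
  (h - min(depths)) <= tol * h
}

#' Phylogenetic variance-covariance (relatedness) matrix
#'
#' The `A` matrix of the animal model with the phylogeny standing in for a
#' pedigree: entry (i,j) is the shared root-to-MRCA path length of tips i and
#' j, and the diagonal holds root-to-tip path lengths. With
#' `scale_height = TRUE` (the default) the matrix is divided by tree height,
#' so an ultrametric tree gives unit diagonal; this makes the phylogenetic and
#' residual covariances of the mixed model directly comparable and puts the
#' per-component signal `lambda` on \[0, 1\].
#'
#' @param tree a `phylo` object with at least 2 tips.
#' @param scale_height divide by tree height? Default `TRUE`.
#' @return symmetric positive-semidefinite matrix with tip-label dimnames.
#' @export
phylo_vcv <- function(tree, scale_height = TRUE) {
  validate_phylogeny(tree)
  if (ape::Ntip(tree) < 2L) stop("need at least 2 tips", call. = FALSE)
  v <- ape::vcv.phylo(tree)
  if (scale_height) v <- v / tree_height(tree)
  v
}

#' Write a labelled square matrix (VCV or patristic distances) as TSV
#'
#' @param m square matrix with dimnames.
#' @param file output path.
#' @export
write_matrix_tsv <- function(m, file) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
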