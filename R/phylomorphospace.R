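#' Principal component analysis of the phylogenetic covariance matrix
#'
#' Eigen-decomposes the posterior-mean PCOV so its leading axes define the
#' venom phylomorphospace: the directions of greatest phylogenetically
#' heritable variation among components. Variance fractions are eigenvalues
#' over the trace. Axis signs follow a deterministic convention — the
#' largest-magnitude loading on each axis is made positive — so results are
#' reproducible across platforms.
#'
#' @param G symmetric (to 1e-8) PCOV matrix, m >= 2, ideally with component
#'   dimnames.
#' @return a `pcov_pca` list: `eigenvalues` (descending), `loadings`
#'   (component x axis, orthonormal), `variance_fractions`, `scores = NULL`
#'   until [species_scores()] fills them.
#' @export
pcov_pca <- function(G) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G), nrow(G) >= 2)
  asym <- max(abs(G - t(G)))
  if (asym > 1e-8)
    stop("G is not symmetric (max asymmetry ", format(asym), ")")
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  load <- e$vectors
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- rownames(G)
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  structure(list(eigenvalues = e$values, loadings = load,
                 variance_fractions = e$values / sum(e$values),
                 scores = NULL),
            class = "pcov_pca")
}

#' @export
print.pcov_pca <- function(x, ...) {
  vf <- round(100 * x$variance_fractions, 1)
  cat("pcov_pca:", length(x$eigenvalues), "axes; variance % =",
      paste(vf, collapse = ", "), "\n")
  invisible(x)
}

#' Project species into the phylomorphospace
#'
#' Scores are projections of the (column-centred) species x component data
#' onto the PCOV eigenvectors. Centring uses the arithmetic cross-species
#' mean by default; pass phylogenetic weights (e.g. rows of
#' `solve(phylo_vcv(tree))` summed and normalised) to centre on the
#' phylogenetically weighted mean instead.
#'
#' @param table species x component numeric matrix (or [toxin_table()]) on
#'   the same scale as the data the PCOV was estimated from; columns must
#'   match the loading rows.
#' @param result a `pcov_pca` object.
#' @param weights optional non-negative species weights for the centring
#'   mean; default equal weights.
#' @return `result` with `scores` (species x axis) filled in.
#' @export
species_scores <- function(table, result, weights = NULL) {
  stopifnot(inherits(result, "pcov_pca"))
  v <- as_values(table)
  if (!is.null(rownames(result$loadings))) {
    if (!identical(colnames(v), rownames(result$loadings))) {
      if (!setequal(colnames(v), rownames(result$loadings)))
        stop("table columns do not match PCA components")
      v <- v[, rownames(result$loadings), drop = FALSE]
    }
  } else if (ncol(v) != nrow(result$loadings)) {
    stop("table has ", ncol(v), " columns but loadings have ",
         nrow(result$loadings), " rows")
  }
  if (is.null(weights)) weights <- rep(1, nrow(v))
  stopifnot(length(weights) == nrow(v), all(weights >= 0), sum(weights) > 0)
  ctr <- colSums(v * (weights / sum(weights)))
  centered <- sweep(v, 2, ctr)
  result$scores <- centered %*% result$loadings
  result
}

#' Write a PCA result (loadings + scores) as TSV files
#'
#' @param result a `pcov_pca`.
#' @param prefix path prefix; writes `<prefix>_loadings.tsv` and, when
#'   scores are present, `<prefix>_scores.tsv`.
#' @export
write_pca_tsv <- function(result, prefix) {
  stopifnot(inherits(result, "pcov_pca"))
  ld <- data.frame(component = rownames(result$loadings), result$loadings,
                   check.names = FALSE)
  write.table(ld, paste0(prefix, "_loadings.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(result$scores)) {
    sc <- data.frame(species = rownames(result$scores), result$scores,
                     check.names = FALSE)
    write.table(sc, paste0(prefix, "_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}
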