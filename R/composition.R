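#' Species-by-component toxin abundance table
#'
#' A light container for compositional venom-expression data: a numeric
#' matrix of abundances (rows = species, columns = toxin families) plus an
#' optional per-species batch label (e.g. sequencing technology). Values are
#' percent of the toxin transcriptome once [percent_normalize()] has run.
#'
#' @param values numeric matrix with species rownames and component colnames;
#'   all entries must be non-negative and finite.
#' @param batch optional character/factor vector of per-species labels, either
#'   named by species or in row order.
#' @return an object of class `toxin_table`.
#' @export
toxin_table <- function(values, batch = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("values needs species rownames")
  if (is.null(colnames(values))) stop("values needs component colnames")
  if (anyNA(values) || any(!is.finite(values))) stop("non-finite abundance values")
  if (any(values < 0)) stop("negative abundance values")
  if (!is.null(batch)) {
    if (!is.null(names(batch))) {
      miss <- setdiff(rownames(values), names(batch))
      if (length(miss)) stop("batch labels missing for: ", paste(miss, collapse = ", "))
      batch <- batch[rownames(values)]
    } else if (length(batch) != nrow(values)) {
      stop("batch must have one label per species")
    }
    batch <- setNames(as.character(batch), rownames(values))
  }
  structure(list(values = values, batch = batch), class = "toxin_table")
}

#' @export
print.toxin_table <- function(x, ...) {
  cat("toxin_table:", nrow(x$values), "species x", ncol(x$values), "components\n")
  cat("components:", paste(colnames(x$values), collapse = ", "), "\n")
  if (!is.null(x$batch))
    cat("batches:", paste(names(table(x$batch)), table(x$batch),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.toxin_table <- function(x) dim(x$values)

as_values <- function(table) {
  if (inherits(table, "toxin_table")) table$values else as.matrix(table)
}

rebuild_table <- function(table, values) {
  if (inherits(table, "toxin_table")) toxin_table(values, table$batch)
  else toxin_table(values)
}

#' Read a toxin abundance table from TSV/CSV
#'
#' First column: species label; optional column named `batch`; remaining
#' columns: component abundances.
#'
#' @param file path; tab- or comma-separated, inferred from the extension.
#' @return a [toxin_table()].
#' @export
read_toxin_table <- function(file) {
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  df <- read.table(file, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  species <- as.character(df[[1L]])
  df <- df[-1L]
  batch <- NULL
  if ("batch" %in% names(df)) {
    batch <- setNames(as.character(df[["batch"]]), species)
    df <- df[setdiff(names(df), "batch")]
  }
  values <- as.matrix(df)
  rownames(values) <- species
  toxin_table(values, batch)
}

#' Write a toxin abundance table as TSV
#' @param table a [toxin_table()].
#' @param file output path.
#' @export
write_toxin_table <- function(table, file) {
  v <- as_values(table)
  df <- data.frame(species = rownames(v), check.names = FALSE)
  if (inherits(table, "toxin_table") && !is.null(table$batch))
    df$batch <- table$batch[rownames(v)]
  df <- cbind(df, as.data.frame(v, check.names = FALSE))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Convert raw abundances to percent of the toxin transcriptome
#'
#' Each species row is rescaled to sum to 100, the scale on which the curated
#' dataset is analysed; zeros stay zeros.
#'
#' @param raw non-negative species x component matrix or [toxin_table()].
#' @return a [toxin_table()] with rows summing to 100.
#' @export
percent_normalize <- function(raw) {
  v <- as_values(raw)
  rs <- rowSums(v)
  if (any(rs <= 0))
    stop("all-zero abundance row(s): ",
         paste(rownames(v)[rs <= 0], collapse = ", "), call. = FALSE)
  rebuild_table(raw, 100 * v / rs)
}

#' Drop components observed in too few species
#'
#' A component is retained iff it is present (abundance above `presence_tol`)
#' in at least `threshold` of the species; the boundary is inclusive.
#' Retained rows are re-normalised to sum to 100 so
#' downstream stages operate on a closed composition of the retained
#' components.
#'
#' @param table a [toxin_table()] with percent rows.
#' @param threshold prevalence fraction in (0, 1]; default 0.5.
#' @param presence_tol abundances at or below this (in percent) count as
#'   absent; default 1e-6.
#' @return the filtered, re-normalised [toxin_table()], with the retained
#'   component names in attribute `"retained"`.
#' @export
prevalence_filter <- function(table, threshold = 0.5, presence_tol = 1e-6) {
  stopifnot(threshold > 0, threshold <= 1)
  v <- as_values(table)
  prev <- colMeans(v > presence_tol)
  keep <- prev >= threshold
  if (!any(keep)) stop("prevalence filter removed every component", call. = FALSE)
  out <- percent_normalize(rebuild_table(table, v[, keep, drop = FALSE]))
  attr(out, "prevalence") <- prev
  attr(out, "retained") <- colnames(v)[keep]
  out
}

#' Impute structural zeros by multiplicative replacement
#'
#' Replaces every zero with `delta = 0.65 *` (smallest nonzero value in the
#' table) and shrinks the nonzero entries of each row by `1 - k * delta / 100`
#' (k = zeros in that row) so the row still sums to 100. Deterministic, and a
#' prerequisite for [clr_transform()].
#'
#' @param table a [toxin_table()] with percent rows.
#' @param delta_frac fraction of the smallest nonzero value used as the
#'   imputed value; default 0.65.
#' @return a strictly positive [toxin_table()] with rows summing to 100.
#' @export
impute_zeros <- function(table, delta_frac = 0.65) {
  v <- as_values(table)
  if (!any(v == 0)) return(rebuild_table(table, v))
  delta <- delta_frac * min(v[v > 0])
  nz <- rowSums(v == 0)
  if (any(nz * delta >= 100))
    stop("imputed mass exceeds the row total; delta too large", call. = FALSE)
  out <- v * (1 - nz * delta / 100)
  out[v == 0] <- delta
  rebuild_table(table, out)
}

#' Centred log-ratio transform
#'
#' `clr(x) = log(x) - mean(log(x))` per species row; maps a closed
#' composition to unconstrained real space where ordinary covariance analysis
#' is free of the sum constraint. Rows of the output sum to zero.
#'
#' @param table a strictly positive [toxin_table()] (run [impute_zeros()]
#'   first if the data contain structural zeros).
#' @return species x component numeric matrix.
#' @export
clr_transform <- function(table) {
  v <- as_values(table)
  if (any(v <= 0))
    stop("clr needs strictly positive values; run impute_zeros() first",
         call. = FALSE)
  lg <- log(v)
  lg - rowMeans(lg)
}
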