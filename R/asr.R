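#' Maximum-likelihood ancestral states for one component
#'
#' Brownian-motion reconstruction by the contrasts (re-rooting) algorithm of
#' phytools' `fastAnc`, equivalent to the joint GLS reconstruction
#' `x_anc = C_at C_tt^-1 (x - mu) + mu` with `mu` the GLS root mean. The
#' Brownian rate is the REML contrasts estimate (mean squared standardised
#' contrast) and 95% CIs are `estimate +/- 1.96 * sqrt(variance)`.
#'
#' @param tree rooted `phylo` with branch lengths, >= 2 tips (at least 3 for
#'   nonzero estimation variances).
#' @param x per-tip values, named by tip label (or in tip order).
#' @return an `ancestral_states` list: data.frame `states` (node, estimate,
#'   variance, lower, upper), `sigma2`, and `root` (the root node's row).
#' @export
ml_ancestral_states <- function(tree, x) {
  validate_phylogeny(tree)
  n <- ape::Ntip(tree)
  if (n < 2) stop("need at least 2 tips", call. = FALSE)
  if (!is.null(names(x))) {
    miss <- setdiff(tree$tip.label, names(x))
    if (length(miss))
      stop("missing tip value(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    x <- x[tree$tip.label]
  } else if (length(x) != n) {
    stop("need one value per tip", call. = FALSE)
  }
  if (anyNA(x)) stop("missing tip value(s)", call. = FALSE)
  # contrasts need a binary tree; zero-length resolution leaves the REML
  # rate estimate unchanged
  btree <- if (ape::is.binary(tree)) tree else ape::multi2di(tree)
  pics <- ape::pic(x, btree)
  sigma2 <- mean(pics^2)
  fa <- tryCatch(phytools::fastAnc(tree, x, vars = TRUE),
                 error = function(e) NULL)
  if (!is.null(fa)) {
    est <- as.numeric(fa$ace)
    vars <- as.numeric(fa$var)
    nodes <- as.integer(names(fa$ace))
  } else {
    # re-rooting fails on some topologies (e.g. star trees); the dense GLS
    # reconstruction with kriging variances is numerically identical
    g <- gls_asr(tree, x, sigma2)
    est <- g$estimate
    vars <- g$variance
    nodes <- g$node
  }
  states <- data.frame(node = nodes, estimate = est, variance = vars,
                       lower = est - 1.96 * sqrt(vars),
                       upper = est + 1.96 * sqrt(vars))
  structure(list(states = states, sigma2 = sigma2,
                 root = states[states$node == n + 1L, ]),
            class = "ancestral_states")
}

# joint GLS reconstruction with the GLS root mean profiled out; variances
# are kriging variances including mean-estimation uncertainty, scaled by
# the contrasts rate estimate
gls_asr <- function(tree, x, sigma2) {
  tree <- stats::reorder(tree, "cladewise")
  n <- ape::Ntip(tree)
  nn <- max(tree$edge)
  child_to_edge <- integer(nn)
  child_to_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- n + 1L
  paths <- lapply(seq_len(nn), function(nd) {
    p <- integer(0)
    while (nd != root) {
      e <- child_to_edge[nd]
      p <- c(p, e)
      nd <- tree$edge[e, 1]
    }
    p
  })
  C <- matrix(0, nn, nn)
  for (i in seq_len(nn))
    for (j in seq_len(i))
      C[i, j] <- C[j, i] <- sum(tree$edge.length[intersect(paths[[i]],
                                                           paths[[j]])])
  Ci <- solve(C[1:n, 1:n])
  xo <- x[tree$tip.label]
  mu <- sum(Ci %*% xo) / sum(Ci)
  anc <- root:nn
  est <- vars <- numeric(length(anc))
  for (k in seq_along(anc)) {
    ca <- C[anc[k], 1:n]
    est[k] <- drop(ca %*% Ci %*% (xo - mu)) + mu
    vars[k] <- sigma2 * (C[anc[k], anc[k]] - drop(ca %*% Ci %*% ca) +
                           (1 - sum(Ci %*% ca))^2 / sum(Ci))
  }
  list(node = anc, estimate = est, variance = pmax(vars, 0))
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat("ancestral_states:", nrow(x$states), "internal nodes; sigma2 =",
      signif(x$sigma2, 4), "\n")
  cat(sprintf("root: %.3f [%.3f, %.3f]\n", x$root$estimate, x$root$lower,
              x$root$upper))
  invisible(x)
}

#' Ancestral states for every component of a table
#'
#' Each component is reconstructed independently (no multivariate
#' constraint), matching how the toxin reconstructions are reported.
#'
#' @param tree rooted `phylo`.
#' @param table species x component matrix or [toxin_table()].
#' @return named list of `ancestral_states`, one per component.
#' @export
ml_ancestral_states_all <- function(tree, table) {
  v <- as_values(table)
  out <- lapply(colnames(v), function(comp)
    ml_ancestral_states(tree, setNames(v[, comp], rownames(v))))
  names(out) <- colnames(v)
  out
}

#' Root-presence call from reconstructed ancestral states
#'
#' A component is called present at the root only when the root estimate's
#' confidence interval does not overlap zero on the positive side, i.e. the
#' CI lower bound is strictly positive. The Gaussian model permits negative
#' reconstructed abundances; this rule handles their interpretation.
#'
#' @param states an `ancestral_states` object or a named list of them (as
#'   from [ml_ancestral_states_all()]).
#' @return named logical vector (one element per component).
#' @export
root_presence_call <- function(states) {
  if (inherits(states, "ancestral_states")) states <- list(states)
  vapply(states, function(s) s$root$lower > 0, logical(1))
}

#' Write per-node ancestral estimates as TSV
#'
#' @param asr named list of `ancestral_states` (per component).
#' @param file output path.
#' @export
write_asr_tsv <- function(asr, file) {
  rows <- do.call(rbind, lapply(names(asr), function(comp) {
    df <- asr[[comp]]$states
    cbind(component = comp, df, sigma2 = asr[[comp]]$sigma2)
  }))
  write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
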