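# Brute-force oracles used by the equivalence tests. These deliberately use
# naive path enumeration / dense linear algebra, independent of the package's
# own code paths.

# shared-path-length matrix over a set of nodes (default: tips) by walking
# every root-to-node path edge by edge
oracle_shared_paths <- function(tree, nodes = seq_len(ape::Ntip(tree))) {
  tree <- stats::reorder(tree, "cladewise")
  root <- ape::Ntip(tree) + 1L
  child_to_edge <- integer(max(tree$edge))
  child_to_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  path <- function(nd) {
    p <- integer(0)
    while (nd != root) {
      e <- child_to_edge[nd]
      p <- c(p, e)
      nd <- tree$edge[e, 1]
    }
    p
  }
  paths <- lapply(nodes, path)
  k <- length(nodes)
  V <- matrix(0, k, k)
  for (i in seq_len(k))
    for (j in seq_len(k))
      V[i, j] <- sum(tree$edge.length[intersect(paths[[i]], paths[[j]])])
  lab <- ifelse(nodes <= ape::Ntip(tree), tree$tip.label[nodes], nodes)
  dimnames(V) <- list(lab, lab)
  V
}

oracle_patristic <- function(tree) {
  V <- oracle_shared_paths(tree)
  outer(diag(V), diag(V), "+") - 2 * V
}

# dense-GLS ancestral reconstruction: x_anc = C_at C_tt^-1 (x - mu) + mu
oracle_gls_asr <- function(tree, x) {
  tree <- stats::reorder(tree, "cladewise")
  n <- ape::Ntip(tree)
  nn <- max(tree$edge)
  C <- oracle_shared_paths(tree, seq_len(nn))
  anc <- (n + 1L):nn
  xo <- x[tree$tip.label]
  Ci <- solve(C[1:n, 1:n])
  mu <- sum(Ci %*% xo) / sum(Ci)
  est <- drop(C[anc, 1:n] %*% Ci %*% (xo - mu) + mu)
  setNames(est, anc)
}

# independent multivariate normal log-density via dense solve()
oracle_ldmvnorm <- function(x, mean, V) {
  r <- x - mean
  -0.5 * (length(x) * log(2 * pi) + determinant(V)$modulus +
            drop(t(r) %*% solve(V) %*% r))
}

# quick standard fixtures
tree_abc <- function() read_phylogeny("((A:1,B:1):0.5,C:1.5);")

small_table <- function() {
  toxin_table(matrix(c(10, 30, 60,
                       50,  0, 50,
                       25, 25, 50), 3, 3, byrow = TRUE,
                     dimnames = list(c("A", "B", "C"), c("x", "y", "z"))))
}
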