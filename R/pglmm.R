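#' Configuration for the Bayesian phylogenetic mixed model
#'
#' @param n_iterations total MCMC iterations. Default 50,000 — a desk-scale
#'   chain; the `"paper"` preset uses the study-scale settings of 20 million
#'   iterations, 1 million burn-in and thinning 1,500.
#' @param burnin iterations discarded before storage; must be < `n_iterations`.
#' @param thin storage interval (>= 1). At least 100 draws must be stored.
#' @param prior_nu inverse-Wishart degrees of freedom for both covariance
#'   priors; `NULL` means `m + 1` (weakly informative, proper). A
#'   near-improper alternative such as `m + 0.002` can be supplied for prior
#'   sensitivity checks.
#' @param prior_scale inverse-Wishart scale matrix (scalar = multiple of the
#'   identity); default identity.
#' @param seed RNG seed; the fit is bit-reproducible given the seed.
#' @param response_scaling centre and scale each component to unit variance
#'   across species before fitting (default `TRUE`), so covariance entries
#'   and lambda are comparable across components.
#' @param scale_vcv divide the relatedness matrix by tree height (default
#'   `TRUE`); see [phylo_vcv()].
#' @param preset `"desk"` (default) or `"paper"` (20e6 / 1e6 / 1500).
#' @return a `pglmm_config` list.
#' @export
pglmm_config <- function(n_iterations = 50000, burnin = 10000, thin = 20,
                         prior_nu = NULL, prior_scale = 1, seed = 1,
                         response_scaling = TRUE, scale_vcv = TRUE,
                         preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    n_iterations <- 20e6; burnin <- 1e6; thin <- 1500
  }
  stopifnot(burnin >= 0, burnin < n_iterations, thin >= 1)
  stored <- floor((n_iterations - burnin) / thin)
  if (stored < 100)
    stop("configuration stores only ", stored, " draws; need >= 100")
  structure(list(n_iterations = n_iterations, burnin = burnin, thin = thin,
                 prior_nu = prior_nu, prior_scale = prior_scale, seed = seed,
                 response_scaling = response_scaling, scale_vcv = scale_vcv),
            class = "pglmm_config")
}

#' Fit the multivariate phylogenetic mixed model
#'
#' The animal model of quantitative genetics with the phylogeny's relatedness
#' matrix in place of a pedigree: responses are the (scaled) component
#' abundances, the phylogenetic effect has covariance `G (x) A` and the
#' residual `R (x) I`. `G` is the phylogenetic covariance matrix (PCOV)
#' between components; `R` the residual covariance. Fixed effects are a
#' per-component intercept plus, when the table carries batch labels (e.g.
#' sequencing technology), per-component batch contrasts. Sampling is by a
#' blocked Gibbs scheme with conjugate inverse-Wishart covariance updates,
#' run in compiled code.
#'
#' @param table a [toxin_table()], or a plain species x component matrix
#'   (e.g. clr-transformed values); species must all be tips of `tree` (the
#'   tree is pruned to the table's species).
#' @param tree a rooted `phylo` with branch lengths.
#' @param config a [pglmm_config()].
#' @param batch optional per-species batch labels, used when `table` is a
#'   plain matrix; a `toxin_table`'s own batch labels take precedence.
#' @return an object of class `pglmm_fit` holding posterior draws of `G`,
#'   `R` (as `m x m x draws` arrays), fixed effects, and deviance.
#' @export
fit_pglmm <- function(table, tree, config = pglmm_config(), batch = NULL) {
  stopifnot(inherits(config, "pglmm_config"))
  Y <- as_values(table)
  if (nrow(Y) < 3) stop("need at least 3 species", call. = FALSE)
  if (ncol(Y) < 2) stop("need at least 2 components", call. = FALSE)
  missing <- setdiff(rownames(Y), tree$tip.label)
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(tree$tip.label) > nrow(Y))
    tree <- prune_to_taxa(tree, rownames(Y))
  Y <- Y[tree$tip.label, , drop = FALSE]

  A <- phylo_vcv(tree, scale_height = config$scale_vcv)
  eig <- eigen(A, symmetric = TRUE)
  if (min(eig$values) <= 1e-10 * max(eig$values))
    stop("relatedness matrix is not positive definite", call. = FALSE)

  scaling <- NULL
  if (config$response_scaling) {
    Ys <- scale(Y)
    scaling <- list(center = attr(Ys, "scaled:center"),
                    scale = attr(Ys, "scaled:scale"))
    Y <- Ys[, , drop = FALSE]
  }

  if (inherits(table, "toxin_table")) batch <- table$batch
  if (!is.null(batch) && is.null(names(batch))) {
    stopifnot(length(batch) == length(tree$tip.label))
    names(batch) <- rownames(as_values(table))
  }
  if (!is.null(batch) && length(unique(batch)) > 1L) {
    X0 <- stats::model.matrix(~ factor(batch[tree$tip.label]))
  } else {
    X0 <- matrix(1, nrow(Y), 1)
  }

  m <- ncol(Y)
  nu <- config$prior_nu %||% (m + 1)
  S <- config$prior_scale
  if (length(S) == 1L) S <- diag(as.numeric(S), m)

  Ytil <- crossprod(eig$vectors, Y)
  Xtil <- crossprod(eig$vectors, X0)

  set.seed(config$seed)
  raw <- pglmm_gibbs_cpp(Ytil, Xtil, eig$values, nu, S, nu, S,
                         as.integer(config$n_iterations),
                         as.integer(config$burnin), as.integer(config$thin))

  S_n <- nrow(raw$G)
  Garr <- array(apply(raw$G, 1, unvech, m = m), dim = c(m, m, S_n))
  Rarr <- array(apply(raw$R, 1, unvech, m = m), dim = c(m, m, S_n))
  dimnames(Garr) <- dimnames(Rarr) <- list(colnames(Y), colnames(Y), NULL)

  structure(list(G = Garr, R = Rarr, beta = raw$beta,
                 deviance = as.numeric(raw$deviance),
                 components = colnames(Y), species = rownames(Y),
                 config = config, scaling = scaling,
                 rotated = list(Y = Ytil, X = Xtil, d = eig$values),
                 Y = Y, tree = tree),
            class = "pglmm_fit")
}

#' @export
print.pglmm_fit <- function(x, ...) {
  cat("pglmm_fit:", length(x$species), "species,", length(x$components),
      "components,", dim(x$G)[3], "stored draws\n")
  invisible(x)
}

#' Summarise the posterior phylogenetic covariance matrix
#'
#' Entrywise posterior means of `G` and `R`, 95% highest-posterior-density
#' intervals, and a significance mask marking off-diagonal PCOV entries whose
#' 95% HPD excludes zero; a flagged pair indicates phylogenetic constraint
#' between those components, an empty mask its absence.
#'
#' @param fit a `pglmm_fit` with at least 100 stored draws.
#' @param prob HPD coverage; default 0.95.
#' @return a `pcov_summary` list: `mean_G`, `mean_R`, `hpd_G` (m x m x 2),
#'   `hpd_R`, and logical `significant` mask (diagonal always `FALSE`).
#' @export
posterior_pcov <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "pglmm_fit"))
  S_n <- dim(fit$G)[3]
  if (S_n < 100) stop("need at least 100 stored draws, have ", S_n)
  m <- dim(fit$G)[1]
  mean_G <- apply(fit$G, c(1, 2), mean)
  mean_R <- apply(fit$R, c(1, 2), mean)
  hpd_G <- apply(fit$G, c(1, 2), hpd_interval, prob = prob)
  hpd_R <- apply(fit$R, c(1, 2), hpd_interval, prob = prob)
  sig <- hpd_G[1, , ] > 0 | hpd_G[2, , ] < 0
  diag(sig) <- FALSE
  sig <- sig | t(sig)   # numerically identical draws keep it symmetric anyway
  structure(list(mean_G = mean_G, mean_R = mean_R,
                 hpd_G = aperm(hpd_G, c(2, 3, 1)),
                 hpd_R = aperm(hpd_R, c(2, 3, 1)),
                 significant = sig, prob = prob,
                 components = fit$components),
            class = "pcov_summary")
}

#' Per-component phylogenetic signal (lambda)
#'
#' For each posterior draw, `lambda_i = G_ii / (G_ii + R_ii)` — the fraction
#' of a component's variance attributable to phylogeny, equivalent to Pagel's
#' lambda here. Summarised by the posterior mean and 95% HPD; a component is
#' flagged significant when the HPD lower bound exceeds 0.05 (lambda is
#' positive by construction, so "greater than zero" is operationalised as a
#' small positive floor).
#'
#' @param fit a `pglmm_fit`.
#' @param prob HPD coverage; default 0.95.
#' @param floor significance floor on the HPD lower bound; default 0.05.
#' @return data.frame with columns `component`, `mean`, `lower`, `upper`,
#'   `significant`; the full draw matrix is in attribute `"draws"`.
#' @export
lambda_estimates <- function(fit, prob = 0.95, floor = 0.05) {
  stopifnot(inherits(fit, "pglmm_fit"))
  m <- dim(fit$G)[1]
  gd <- t(apply(fit$G, 3, diag))
  rd <- t(apply(fit$R, 3, diag))
  if (m == 1) { gd <- t(gd); rd <- t(rd) }
  tot <- gd + rd
  if (any(tot == 0)) stop("G_ii + R_ii = 0 in a draw; lambda undefined")
  lam <- gd / tot
  hpd <- apply(lam, 2, hpd_interval, prob = prob)
  out <- data.frame(component = fit$components,
                    mean = colMeans(lam),
                    lower = hpd[1, ], upper = hpd[2, ],
                    significant = hpd[1, ] > floor,
                    row.names = NULL)
  attr(out, "draws") <- lam
  out
}

#' Effective sample size of an MCMC chain
#'
#' `ESS = n / (1 + 2 * sum(rho_k))`, with the autocorrelation sum truncated
#' by the initial-positive-sequence rule: consecutive lag pairs
#' `(rho_1 + rho_2), (rho_3 + rho_4), ...` are accumulated until the first
#' nonpositive pair. A constant chain reports 1.
#'
#' @param chain numeric vector, length >= 100.
#' @return estimated number of independent draws (capped at `n`).
#' @export
effective_sample_size <- function(chain) {
  n <- length(chain)
  stopifnot(n >= 100)
  if (sd(chain) == 0) return(1)
  lag_max <- min(n - 1, 10000L)
  rho <- as.numeric(acf(chain, lag.max = lag_max, plot = FALSE,
                        demean = TRUE)$acf)[-1]
  acsum <- 0
  j <- 1L
  while (j < length(rho)) {
    pair <- rho[j] + rho[j + 1L]
    if (pair <= 0) break
    acsum <- acsum + pair
    j <- j + 2L
  }
  min(n, n / (1 + 2 * acsum))
}

#' Sample autocorrelation of a chain at a given lag
#'
#' @param chain numeric vector.
#' @param lag lag (>= 0, < length(chain)/2).
#' @return autocorrelation in \[-1, 1\]; errors on a constant chain.
#' @export
autocorrelation <- function(chain, lag) {
  n <- length(chain)
  stopifnot(lag >= 0, lag < n / 2)
  if (sd(chain) == 0) stop("autocorrelation undefined for a constant chain")
  if (lag == 0) return(1)
  x <- chain - mean(chain)
  sum(x[1:(n - lag)] * x[(lag + 1):n]) / sum(x^2)
}

#' Deviance information criterion of a fitted model
#'
#' `DIC = 2 * mean(deviance) - deviance(posterior-mean parameters)`; lower is
#' better. Used to compare the raw-scale fit against the clr-transformed
#' validation refit.
#'
#' @param fit a `pglmm_fit` with stored deviance draws.
#' @return DIC value.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "pglmm_fit"))
  if (is.null(fit$deviance) || !length(fit$deviance))
    stop("no deviance draws stored")
  Gbar <- apply(fit$G, c(1, 2), mean)
  Rbar <- apply(fit$R, c(1, 2), mean)
  m <- ncol(Gbar)
  p <- nrow(fit$rotated$X)  # n species rows in rotated space
  Bbar <- matrix(colMeans(fit$beta), ncol = m)
  resid <- fit$rotated$Y - fit$rotated$X %*% Bbar
  dev_at_mean <- 0
  for (i in seq_len(nrow(resid))) {
    Sig <- fit$rotated$d[i] * Gbar + Rbar
    dev_at_mean <- dev_at_mean - 2 * ldmvnorm_chol(resid[i, ], chol(Sig))
  }
  2 * mean(fit$deviance) - dev_at_mean
}
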