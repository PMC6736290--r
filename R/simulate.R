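# Synthetic-data generators reproducing the statistical structure the
# analyses assume: ultrametric pure-birth trees, phylogenetically heritable
# multivariate traits, OU traits under regime paintings, and a full
# venom-like compositional dataset with structural zeros, decoy components
# and batch labels.

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Forward simulation from a crown root of two lineages: waiting times
#' between successive births are exponential with rate `k * birth_rate`
#' (`k` = current lineage count), the lineage that splits is chosen
#' uniformly, and after the n-th tip appears one further exponential waiting
#' time with rate `n * birth_rate` sets the present. By default the tree is
#' rescaled to height 60 (My), the approximate root age of the venomous-snake
#' radiation; pass `height = NULL` to keep the raw simulated height.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate (1/My), > 0.
#' @param seed RNG seed (`NULL` uses the current RNG state).
#' @param height rescale tree height to this value; `NULL` = no rescaling.
#' @return an ultrametric `phylo`; the raw inter-event waiting times are in
#'   attribute `"waiting_times"` (data.frame: k, wait).
#' @export
simulate_yule_tree <- function(n_tips, birth_rate, seed = NULL, height = 60) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_tips)
  root <- n + 1L
  parent <- c(root, root)      # active lineages: parent node and start time
  start <- c(0, 0)
  next_internal <- n + 2L
  t <- 0
  ev_k <- ev_w <- numeric(0)
  ep <- ec <- el <- numeric(0)
  while (length(parent) < n) {
    k <- length(parent)
    w <- rexp(1, k * birth_rate)
    ev_k <- c(ev_k, k); ev_w <- c(ev_w, w)
    t <- t + w
    pick <- sample.int(k, 1)
    ep <- c(ep, parent[pick]); ec <- c(ec, next_internal)
    el <- c(el, t - start[pick])
    parent <- c(parent[-pick], next_internal, next_internal)
    start <- c(start[-pick], t, t)
    next_internal <- next_internal + 1L
  }
  w <- rexp(1, n * birth_rate)
  ev_k <- c(ev_k, n); ev_w <- c(ev_w, w)
  t_end <- t + w
  ep <- c(ep, parent); ec <- c(ec, seq_len(n))
  el <- c(el, t_end - start)
  tree <- structure(list(edge = cbind(as.integer(ep), as.integer(ec)),
                         edge.length = el,
                         tip.label = sprintf("s%02d", seq_len(n)),
                         Nnode = n - 1L),
                    class = "phylo")
  tree <- stats::reorder(tree, "cladewise")
  if (!is.null(height)) tree$edge.length <- tree$edge.length * height / t_end
  attr(tree, "waiting_times") <- data.frame(k = ev_k, wait = ev_w)
  attr(tree, "raw_height") <- t_end
  tree
}

#' Simulate phylogenetically heritable multivariate traits
#'
#' Tip values are drawn from `N(mu, G (x) C + R (x) I)` with `C` the
#' height-scaled phylogenetic VCV — the generative counterpart of the mixed
#' model the pipeline fits: a Brownian between-species component with
#' covariance `G` plus independent residual noise with covariance `R`.
#'
#' @param tree `phylo`.
#' @param G,R symmetric PSD m x m matrices (phylogenetic and residual
#'   covariance). Scalars are promoted to 1 x 1.
#' @param mu trait means: scalar or length-m vector; default 0.
#' @param seed RNG seed.
#' @return species x component matrix with tip-label rownames.
#' @export
simulate_bm_traits <- function(tree, G, R, mu = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(G) == 1L) G <- matrix(G, 1, 1)
  if (length(R) == 1L) R <- matrix(R, 1, 1)
  stopifnot(nrow(G) == ncol(G), identical(dim(G), dim(R)))
  m <- nrow(G)
  C <- phylo_vcv(tree, scale_height = TRUE)
  n <- nrow(C)
  SC <- mat_sqrt(C); SG <- mat_sqrt(G); SR <- mat_sqrt(R)
  Y <- SC %*% matrix(rnorm(n * m), n, m) %*% SG +
       matrix(rnorm(n * m), n, m) %*% SR
  Y <- sweep(Y, 2, rep_len(mu, m), "+")
  rownames(Y) <- rownames(C)
  colnames(Y) <- colnames(G) %||% paste0("comp", seq_len(m))
  Y
}

#' Simulate traits under a Hansen (OU) model with painted regimes
#'
#' Per trait, tips are drawn from `N(W theta, sigma2 * V(alpha))` where `W`
#' is the regime-exposure matrix of [hansen_weights()] and `V` the OU
#' covariance of [ou_vcv()].
#'
#' @param tree ultrametric `phylo`.
#' @param painting a `regime_painting`.
#' @param alpha selection strength(s), one per trait (recycled), > 0.
#' @param sigma2 diffusion rate(s), one per trait (recycled), > 0.
#' @param theta regime x trait matrix of optima (rows ordered by sorted
#'   regime id), or a vector for a single trait.
#' @param seed RNG seed.
#' @return species x trait matrix.
#' @export
simulate_ou_traits <- function(tree, painting, alpha, sigma2, theta,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.vector(theta)) theta <- matrix(theta, ncol = 1)
  m <- ncol(theta)
  alpha <- rep_len(alpha, m)
  sigma2 <- rep_len(sigma2, m)
  stopifnot(all(alpha > 0), all(sigma2 > 0))
  ctx <- tree_context(tree)
  validate_painting(painting, ctx)
  Y <- matrix(NA_real_, ctx$n, m,
              dimnames = list(ctx$tree$tip.label,
                              colnames(theta) %||% paste0("trait", seq_len(m))))
  for (j in seq_len(m)) {
    W <- hansen_weights_ctx(ctx, painting, alpha[j])
    if (nrow(theta) != ncol(W))
      stop("theta has ", nrow(theta), " rows but painting has ", ncol(W),
           " regimes")
    V <- sigma2[j] * ou_vcv_unit(ctx, alpha[j])
    Y[, j] <- W %*% theta[, j] + mat_sqrt(V) %*% rnorm(ctx$n)
  }
  Y
}

#' Scenario for a venom-like synthetic dataset
#'
#' Defaults emulate the curated study dataset: 52 species on a 60-My crown
#' tree; 10 core toxin families whose latent (log-scale) abundances evolve
#' with phylogenetic signal lambda of 0.8 for the four strong-signal
#' families (TFTx, SVMP, CRISP, KSPI) and 0.5 for the rest; 15 low-prevalence
#' decoy components so the prevalence filter has work to do; structural
#' zeros from a detection-limit rule on the latent scale; and sequencing
#' technology batch labels assigned independently of phylogeny.
#'
#' @param n_tips tip count; default 52.
#' @param birth_rate Yule speciation rate (1/My); default 0.1.
#' @param height tree height (My); default 60.
#' @param components core component names (10 toxin families).
#' @param lambda per-core-component phylogenetic signal in \[0,1\].
#' @param total_var total latent variance per component; default 2.
#' @param mu latent mean per core component (sets typical percent ranks).
#' @param n_decoys number of decoy components; default 15.
#' @param decoy_prevalence per-species presence probability of each decoy;
#'   default 0.2.
#' @param zero_threshold latent values more than this many natural-log units
#'   below the row maximum become structural zeros; default 6 (about 0.25%
#'   abundance).
#' @param batch_levels,batch_probs technology labels and their frequencies.
#' @param batch_effect_sd SD of additive latent-scale batch shifts
#'   (independent of phylogeny); default 0.3.
#' @param seed master seed.
#' @return a `venom_scenario` list.
#' @export
venom_scenario <- function(n_tips = 52, birth_rate = 0.1, height = 60,
                           components = c("TFTx", "SVMP", "SVSP", "PLA2",
                                          "CRISP", "KSPI", "LAAO", "CTL",
                                          "NP", "VEGF"),
                           lambda = c(TFTx = 0.8, SVMP = 0.8, SVSP = 0.5,
                                      PLA2 = 0.5, CRISP = 0.8, KSPI = 0.8,
                                      LAAO = 0.5, CTL = 0.5, NP = 0.5,
                                      VEGF = 0.5),
                           total_var = 2,
                           mu = c(TFTx = 2.5, SVMP = 2.5, SVSP = 1.5,
                                  PLA2 = 1.5, CRISP = 0.5, KSPI = 0,
                                  LAAO = 0, CTL = 0.5, NP = 0, VEGF = -0.5),
                           n_decoys = 15, decoy_prevalence = 0.2,
                           zero_threshold = 6,
                           batch_levels = c("illumina", "roche454", "iontorrent"),
                           batch_probs = c(0.6, 0.25, 0.15),
                           batch_effect_sd = 0.3, seed = 1) {
  stopifnot(length(lambda) == length(components),
            length(mu) == length(components),
            all(lambda >= 0), all(lambda <= 1))
  m <- length(components)
  G <- diag(lambda * total_var, m); R <- diag((1 - lambda) * total_var, m)
  dimnames(G) <- dimnames(R) <- list(components, components)
  structure(list(n_tips = n_tips, birth_rate = birth_rate, height = height,
                 components = components, lambda = setNames(lambda, components),
                 G = G, R = R, mu = setNames(mu, components),
                 n_decoys = n_decoys, decoy_prevalence = decoy_prevalence,
                 zero_threshold = zero_threshold,
                 batch_levels = batch_levels, batch_probs = batch_probs,
                 batch_effect_sd = batch_effect_sd, seed = seed),
            class = "venom_scenario")
}

#' Simulate a venom-like compositional dataset
#'
#' Latent multivariate Brownian-plus-noise values (see
#' [simulate_bm_traits()]) receive additive batch shifts, are thresholded
#' into structural zeros (detection limit relative to the row maximum),
#' joined by sparsely present decoy components, and pushed through a softmax
#' so each species' retained components sum to 100%.
#'
#' @param scenario a [venom_scenario()].
#' @return list with `table` (a [toxin_table()] including decoys and batch
#'   labels), `tree` (the simulated phylogeny) and `truth` (all latent
#'   parameters, for recovery tests).
#' @export
simulate_venom_dataset <- function(scenario = venom_scenario()) {
  stopifnot(inherits(scenario, "venom_scenario"))
  sc <- scenario
  tree <- simulate_yule_tree(sc$n_tips, sc$birth_rate,
                             seed = derive_seed(sc$seed, 1), height = sc$height)
  latent <- simulate_bm_traits(tree, sc$G, sc$R, mu = sc$mu,
                               seed = derive_seed(sc$seed, 2))
  n <- nrow(latent); m <- ncol(latent)

  set.seed(derive_seed(sc$seed, 3))
  batch <- sample(sc$batch_levels, n, replace = TRUE, prob = sc$batch_probs)
  names(batch) <- rownames(latent)
  batch_shift <- matrix(rnorm(length(sc$batch_levels) * m,
                              sd = sc$batch_effect_sd),
                        length(sc$batch_levels), m,
                        dimnames = list(sc$batch_levels, sc$components))
  latent_obs <- latent + batch_shift[batch, , drop = FALSE]

  rowmax <- apply(latent_obs, 1, max)
  present <- latent_obs >= (rowmax - sc$zero_threshold)

  decoy_names <- sprintf("decoy%02d", seq_len(sc$n_decoys))
  decoy_present <- matrix(runif(n * sc$n_decoys) < sc$decoy_prevalence,
                          n, sc$n_decoys,
                          dimnames = list(rownames(latent), decoy_names))
  decoy_latent <- matrix(rowmax, n, sc$n_decoys) - 4.5 +
    matrix(rnorm(n * sc$n_decoys, sd = 0.5), n, sc$n_decoys)

  all_latent <- cbind(latent_obs, decoy_latent)
  all_present <- cbind(present, decoy_present)
  values <- matrix(0, n, m + sc$n_decoys,
                   dimnames = list(rownames(latent),
                                   c(sc$components, decoy_names)))
  for (i in seq_len(n)) {
    idx <- which(all_present[i, ])
    values[i, idx] <- 100 * softmax(all_latent[i, idx])
  }
  list(table = toxin_table(values, batch), tree = tree,
       truth = list(scenario = sc, latent = latent, latent_obs = latent_obs,
                    batch = batch, batch_shift = batch_shift,
                    present = all_present))
}
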