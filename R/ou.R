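# Hansen (Ornstein-Uhlenbeck) machinery and the stepwise convergence search:
# regimes are painted onto branches, each painting implies a design matrix of
# exponentially weighted regime exposures, and trait optima are estimated by
# GLS under the OU covariance. A greedy forward phase adds regime shifts and
# a backward phase collapses regimes, both under AICc.

# ---- internal tree context ------------------------------------------------

# Precomputes everything the Hansen likelihood needs; all edge indices refer
# to the cladewise ("preorder") edge order of the reordered tree.
tree_context <- function(tree, tol = 1e-6) {
  validate_phylogeny(tree)
  tree <- stats::reorder(tree, "cladewise")
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  Tmax <- max(depth[seq_len(n)])
  if ((Tmax - min(depth[seq_len(n)])) > tol * Tmax)
    stop("tree is not ultrametric within tolerance ", tol, call. = FALSE)
  s <- ape::vcv.phylo(tree)
  d <- outer(diag(s), diag(s), "+") - 2 * s
  edge_to_child <- tree$edge[, 2]
  child_to_edge <- integer(max(tree$edge))
  child_to_edge[edge_to_child] <- seq_along(edge_to_child)
  root <- n + 1L
  paths <- lapply(seq_len(n), function(tip) {
    path <- integer(0)
    node <- tip
    while (node != root) {
      e <- child_to_edge[node]
      path <- c(e, path)
      node <- tree$edge[e, 1]
    }
    path
  })
  n_edges <- nrow(tree$edge)
  incidence <- matrix(0, n, n_edges)   # tip x edge: edge on root-to-tip path
  for (tip in seq_len(n)) incidence[tip, paths[[tip]]] <- 1
  list(tree = tree, n = n, s = s, d = d, depth = depth, height = Tmax,
       paths = paths, child_to_edge = child_to_edge, root = root,
       n_edges = n_edges, incidence = incidence,
       edge_t0 = depth[tree$edge[, 1]], edge_t1 = depth[tree$edge[, 2]])
}

# ---- regime paintings -----------------------------------------------------

#' Paint adaptive regimes onto the branches of a tree
#'
#' A painting assigns a regime id to every branch: the root's lineages start
#' in a basal regime, and each entry of `shifts` places a new regime at the
#' rootward end of a branch, inherited by all descendant branches until
#' overridden by a later shift. Shift locations are structural — a shift
#' whose regime equals its parent branch's regime (a reversion) still counts
#' as a shift. Edge indices refer to the cladewise edge order of the tree.
#'
#' @param tree a `phylo` object.
#' @param shifts data.frame with integer columns `edge` and `regime`, or
#'   `NULL` for the basal-only painting.
#' @param basal basal regime id; default 1.
#' @return a `regime_painting` list: `shifts`, `basal`, `edge_regime`
#'   (regime per edge), `n_edges`.
#' @export
paint_regimes <- function(tree, shifts = NULL, basal = 1L) {
  ctx_tree <- stats::reorder(tree, "cladewise")
  edge <- ctx_tree$edge
  n_edges <- nrow(edge)
  if (is.null(shifts))
    shifts <- data.frame(edge = integer(0), regime = integer(0))
  stopifnot(all(c("edge", "regime") %in% names(shifts)))
  if (anyDuplicated(shifts$edge)) stop("multiple shifts on one edge")
  if (length(shifts$edge) && (min(shifts$edge) < 1 || max(shifts$edge) > n_edges))
    stop("shift edge index out of range")
  child_to_edge <- integer(max(edge))
  child_to_edge[edge[, 2]] <- seq_len(n_edges)
  root <- ape::Ntip(ctx_tree) + 1L
  shift_map <- integer(n_edges)
  shift_map[shifts$edge] <- shifts$regime
  edge_regime <- integer(n_edges)
  for (e in seq_len(n_edges)) {   # cladewise: parent edge precedes child edge
    if (shift_map[e] > 0) {
      edge_regime[e] <- shift_map[e]
    } else {
      pn <- edge[e, 1]
      edge_regime[e] <- if (pn == root) basal else edge_regime[child_to_edge[pn]]
    }
  }
  structure(list(shifts = shifts, basal = as.integer(basal),
                 edge_regime = edge_regime, n_edges = n_edges),
            class = "regime_painting")
}

#' @rdname paint_regimes
#' @export
basal_painting <- function(tree) paint_regimes(tree, NULL)

#' @export
print.regime_painting <- function(x, ...) {
  cm <- convergence_metrics(x)
  cat("regime_painting: k =", cm$k, "placements, k' =", cm$kprime,
      "distinct regimes, c =", cm$c, "\n")
  invisible(x)
}

validate_painting <- function(painting, ctx) {
  stopifnot(inherits(painting, "regime_painting"))
  if (painting$n_edges != ctx$n_edges)
    stop("painting does not match tree (edge count differs)")
  if (any(painting$edge_regime < 1)) stop("unpainted branch in painting")
  invisible(painting)
}

#' Convergence metrics of a regime painting
#'
#' Counts the regime placements of a painting: `k` = 1 (basal) + number of
#' shifts; `kprime` = number of distinct regime ids among placements;
#' `delta_k = k - kprime`, the amount by which convergence compresses the
#' regime count; `c` = total number of placements into regimes reached by at
#' least two placements (the basal placement counts, so reversions to the
#' basal regime are convergent with it); `n_convergent_regimes` = number of
#' regimes with two or more placements.
#'
#' @param painting a `regime_painting`.
#' @return list with `k`, `kprime`, `delta_k`, `c`, `n_convergent_regimes`.
#' @export
convergence_metrics <- function(painting) {
  stopifnot(inherits(painting, "regime_painting"))
  placements <- c(painting$basal, painting$shifts$regime)
  tab <- table(placements)
  k <- length(placements)
  kprime <- length(tab)
  conv <- tab[tab >= 2]
  list(k = k, kprime = kprime, delta_k = k - kprime,
       c = as.integer(sum(conv)), n_convergent_regimes = length(conv))
}

# ---- OU covariance and Hansen design -------------------------------------

#' Ornstein-Uhlenbeck trait covariance among tips
#'
#' For tips i, j at patristic distance `d_ij` with shared root-to-MRCA time
#' `s_ij` on an ultrametric tree,
#' `V_ij = sigma2/(2*alpha) * exp(-alpha*d_ij) * (1 - exp(-2*alpha*s_ij))`.
#' As `alpha -> 0` this approaches the Brownian covariance `sigma2 * s_ij`,
#' which is used directly when `alpha * height < 1e-8`.
#'
#' @param tree ultrametric `phylo` (tolerance 1e-6 x height).
#' @param alpha selection strength (1/My), >= 0.
#' @param sigma2 diffusion rate, > 0.
#' @return symmetric PSD tip x tip covariance matrix.
#' @export
ou_vcv <- function(tree, alpha, sigma2) {
  stopifnot(alpha >= 0, sigma2 > 0)
  ctx <- tree_context(tree)
  sigma2 * ou_vcv_unit(ctx, alpha)
}

# unit-sigma2 OU covariance from a precomputed context
ou_vcv_unit <- function(ctx, alpha) {
  if (alpha * ctx$height < 1e-8) return(ctx$s)
  exp(-alpha * ctx$d) * (1 - exp(-2 * alpha * ctx$s)) / (2 * alpha)
}

#' Hansen regime-exposure weight matrix
#'
#' Row i gives, for each regime, the exponentially discounted fraction of
#' tip i's history spent in that regime:
#' `W_ir = sum over root-to-tip segments painted r of
#' exp(-alpha*(T_i - t_end)) - exp(-alpha*(T_i - t_start))`, with
#' `exp(-alpha*T_i)` added to the basal regime's column (the ancestral state
#' is assumed to sit at the basal optimum). Rows sum to 1, and the expected
#' tip values under the Hansen model are `W %*% theta`.
#'
#' @param tree ultrametric `phylo`.
#' @param painting a `regime_painting` on `tree`.
#' @param alpha selection strength, > 0.
#' @return tip x regime matrix with tip-label rownames.
#' @export
hansen_weights <- function(tree, painting, alpha) {
  stopifnot(alpha > 0)
  ctx <- tree_context(tree)
  hansen_weights_ctx(ctx, painting, alpha)
}

hansen_weights_ctx <- function(ctx, painting, alpha) {
  validate_painting(painting, ctx)
  regimes <- sort(unique(c(painting$basal, painting$edge_regime)))
  K <- length(regimes)
  # per-edge exposure (ultrametric, so all tips share height T)
  a <- exp(-alpha * (ctx$height - ctx$edge_t1)) -
       exp(-alpha * (ctx$height - ctx$edge_t0))
  A <- matrix(0, ctx$n_edges, K)
  A[cbind(seq_len(ctx$n_edges), match(painting$edge_regime, regimes))] <- a
  W <- ctx$incidence %*% A
  bcol <- match(painting$basal, regimes)
  W[, bcol] <- W[, bcol] + exp(-alpha * ctx$height)
  dimnames(W) <- list(ctx$tree$tip.label, regimes)
  W
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2*lnL + 2p + 2p(p+1)/(n - p - 1)`.
#'
#' @param lnL log-likelihood.
#' @param p parameter count.
#' @param n observation count; requires `n - p - 1 > 0`.
#' @export
aicc <- function(lnL, p, n) {
  if (n - p - 1 <= 0) stop("AICc undefined: n - p - 1 <= 0")
  -2 * lnL + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

# profile log-likelihood of one trait at given alpha: theta by GLS, sigma2
# by its ML value (compiled kernel). Returns lnL and the estimates.
hansen_profile <- function(ctx, painting, alpha, y) {
  regimes <- sort(unique(c(painting$basal, painting$edge_regime)))
  res <- hansen_profile_cpp(ctx$s, ctx$d, ctx$height, ctx$incidence,
                            ctx$edge_t0, ctx$edge_t1,
                            match(painting$edge_regime, regimes),
                            length(regimes), match(painting$basal, regimes),
                            alpha, y)
  if (!isTRUE(res$ok))
    stop("collinear regime design or singular OU covariance")
  list(lnL = res$lnL, theta = setNames(drop(res$theta), regimes),
       sigma2 = res$sigma2)
}

#' Fit a Hansen model for a given regime painting
#'
#' Per trait, the selection strength `alpha` and diffusion rate `sigma2` are
#' shared across regimes while each regime has its own optimum `theta`.
#' `alpha` is optimised by bounded scalar search on the log scale with
#' `theta` (GLS) and `sigma2` (ML) profiled out; the joint log-likelihood is
#' the sum over traits. The parameter count is `m * (2 + kprime)` where
#' `kprime` is the number of distinct regimes.
#'
#' @param traits species x trait numeric matrix with tip-label rownames
#'   (typically the first two phylomorphospace axes).
#' @param tree ultrametric `phylo`.
#' @param painting a `regime_painting`; default basal-only.
#' @param alpha optional fixed alpha (one value, or one per trait); `NULL`
#'   (default) optimises per trait.
#' @param alpha_bounds search bounds on `alpha * height`; default
#'   `c(1e-3, 50)`.
#' @param n_obs observation count used in AICc; default `nrow * ncol` of
#'   `traits`.
#' @return a `hansen_fit` list: per-trait `alpha`, `sigma2`, `theta`
#'   (regime x trait), `lnL` per trait, joint `lnL`, `p`, `n_obs`, `aicc`.
#' @export
fit_hansen <- function(traits, tree, painting = NULL, alpha = NULL,
                       alpha_bounds = c(1e-3, 50), n_obs = NULL) {
  traits <- as.matrix(traits)
  ctx <- if (inherits(tree, "list") && !is.null(tree$paths)) tree
         else tree_context(tree)
  if (is.null(painting)) painting <- basal_painting(ctx$tree)
  validate_painting(painting, ctx)
  if (!is.null(rownames(traits))) {
    if (!setequal(rownames(traits), ctx$tree$tip.label))
      stop("trait rownames do not match tree tips")
    traits <- traits[ctx$tree$tip.label, , drop = FALSE]
  } else if (nrow(traits) != ctx$n) {
    stop("traits must have one row per tip")
  }
  m <- ncol(traits)
  regimes <- sort(unique(c(painting$basal, painting$edge_regime)))
  kprime <- length(regimes)
  if (is.null(n_obs)) n_obs <- ctx$n * m
  if (!is.null(alpha) && length(alpha) == 1L) alpha <- rep(alpha, m)

  lo <- log(alpha_bounds[1] / ctx$height)
  hi <- log(alpha_bounds[2] / ctx$height)
  ridx <- match(painting$edge_regime, regimes)
  bcol <- match(painting$basal, regimes)
  prof_fun <- function(a, y)
    hansen_profile_cpp(ctx$s, ctx$d, ctx$height, ctx$incidence,
                       ctx$edge_t0, ctx$edge_t1, ridx, kprime, bcol, a, y)
  alpha_hat <- sigma2_hat <- lnL_trait <- numeric(m)
  theta <- matrix(NA_real_, kprime, m, dimnames = list(regimes, colnames(traits)))
  for (j in seq_len(m)) {
    y <- traits[, j]
    if (is.null(alpha)) {
      opt <- optimize(function(la) {
        r <- prof_fun(exp(la), y)
        if (isTRUE(r$ok)) r$lnL else -1e300
      }, interval = c(lo, hi), maximum = TRUE, tol = 1e-3)
      aj <- exp(opt$maximum)
    } else {
      aj <- alpha[j]
    }
    prof <- prof_fun(aj, y)
    if (!isTRUE(prof$ok))
      stop("collinear regime design or singular OU covariance")
    alpha_hat[j] <- aj
    sigma2_hat[j] <- prof$sigma2
    theta[, j] <- prof$theta
    lnL_trait[j] <- prof$lnL
  }
  lnL <- sum(lnL_trait)
  p <- m * (2 + kprime)
  structure(list(alpha = alpha_hat, sigma2 = sigma2_hat, theta = theta,
                 lnL_trait = lnL_trait, lnL = lnL, p = p, n_obs = n_obs,
                 aicc = aicc(lnL, p, n_obs), painting = painting,
                 regimes = regimes),
            class = "hansen_fit")
}

#' @export
print.hansen_fit <- function(x, ...) {
  cat("hansen_fit:", ncol(x$theta), "trait(s),", nrow(x$theta),
      "regime(s); lnL =", round(x$lnL, 3), "AICc =", round(x$aicc, 3), "\n")
  invisible(x)
}

# ---- stepwise search ------------------------------------------------------

#' Forward phase: greedy addition of regime shifts under AICc
#'
#' Starting from the basal-only Hansen model, every branch without a shift is
#' evaluated as the origin of a new regime (inherited by its descendants
#' until overridden); the single placement with the best AICc is accepted if
#' it improves AICc by more than `threshold`, and the procedure repeats until
#' no placement improves. Deterministic: ties are broken by preorder branch
#' index.
#'
#' Because each step selects the best of roughly `2n` candidate branches,
#' the expected chance improvement of the best candidate is about
#' `2 * log(candidates)` deviance units (~9 for 50 tips), which a plain
#' AICc comparison does not absorb; the default threshold of 10 is this
#' multiplicity allowance rounded up, and suppresses the spurious singleton
#' regimes a threshold of 0 accepts freely. Set `threshold = 0` for the
#' unguarded stepwise rule.
#'
#' @param traits species x trait matrix (>= 10 species recommended).
#' @param tree ultrametric `phylo`.
#' @param threshold minimum AICc improvement to accept a shift; default 10
#'   (see above).
#' @param max_shifts safety cap on accepted shifts; default `Inf`.
#' @param scan `"fast"` (default) evaluates candidate placements at the
#'   current model's per-trait `alpha` and re-optimises `alpha` only for the
#'   selected placement (the acceptance test always uses the fully
#'   re-optimised AICc); `"full"` re-optimises `alpha` for every candidate.
#' @param verbose print one line per accepted step.
#' @return list with the final `painting`, the final `fit`, and `history`
#'   (data.frame: step, edge, k, kprime, aicc).
#' @export
surface_forward <- function(traits, tree, threshold = 10, max_shifts = Inf,
                            scan = c("fast", "full"), verbose = FALSE) {
  scan <- match.arg(scan)
  ctx <- tree_context(tree)
  painting <- basal_painting(ctx$tree)
  fit <- fit_hansen(traits, ctx, painting)
  history <- data.frame(phase = "forward", step = 0L, edge = NA_integer_,
                        k = 1L, kprime = 1L, aicc = fit$aicc)
  step <- 0L
  repeat {
    if (nrow(painting$shifts) >= max_shifts) break
    step <- step + 1L
    next_id <- max(c(painting$basal, painting$shifts$regime)) + 1L
    candidates <- setdiff(seq_len(ctx$n_edges), painting$shifts$edge)
    scan_alpha <- if (scan == "fast") fit$alpha else NULL
    cand_sh <- rbind(painting$shifts,
                     data.frame(edge = NA_integer_, regime = next_id))
    best <- NULL
    for (e in candidates) {
      cand_sh$edge[nrow(cand_sh)] <- e
      cand <- paint_regimes(ctx$tree, cand_sh)
      cfit <- tryCatch(fit_hansen(traits, ctx, cand, alpha = scan_alpha),
                       error = function(err) NULL)
      if (is.null(cfit)) next
      if (is.null(best) || cfit$aicc < best$fit$aicc)
        best <- list(edge = e, painting = cand, fit = cfit)
    }
    if (!is.null(best) && scan == "fast")
      best$fit <- tryCatch(fit_hansen(traits, ctx, best$painting),
                           error = function(err) best$fit)
    if (is.null(best) || (fit$aicc - best$fit$aicc) <= threshold) break
    painting <- best$painting
    fit <- best$fit
    cm <- convergence_metrics(painting)
    history <- rbind(history,
                     data.frame(phase = "forward", step = step,
                                edge = best$edge, k = cm$k,
                                kprime = cm$kprime, aicc = fit$aicc))
    if (verbose)
      message(sprintf("forward step %d: shift on edge %d, AICc %.3f",
                      step, best$edge, fit$aicc))
  }
  list(painting = painting, fit = fit, history = history)
}

#' Backward phase: greedy collapse of regimes under AICc
#'
#' Evaluates merging every pair of regimes into one shared regime, accepts
#' the merge with the best AICc improvement, and repeats until none improves.
#' Shift locations are unchanged — only regime identities collapse — so `k`
#' stays fixed while `kprime` shrinks; the gap `delta_k` and the convergent
#' shift count `c` quantify convergence.
#'
#' @param traits species x trait matrix.
#' @param tree ultrametric `phylo`.
#' @param forward result of [surface_forward()] (or a list with `painting`,
#'   `fit`, `history`).
#' @param threshold minimum AICc improvement to accept a merge; default 0.
#' @param scan see [surface_forward()].
#' @param verbose print one line per accepted merge.
#' @return a `surface_result` list: final `painting`, `fit`, convergence
#'   metrics (`k`, `kprime`, `delta_k`, `c`, `n_convergent_regimes`),
#'   `history` with forward and backward AICc traces, and per-regime member
#'   species.
#' @export
surface_backward <- function(traits, tree, forward, threshold = 0,
                             scan = c("fast", "full"), verbose = FALSE) {
  scan <- match.arg(scan)
  ctx <- tree_context(tree)
  painting <- forward$painting
  fit <- forward$fit %||% fit_hansen(traits, ctx, painting)
  history <- forward$history
  step <- 0L
  repeat {
    regimes <- sort(unique(c(painting$basal, painting$shifts$regime)))
    if (length(regimes) < 2L) break
    step <- step + 1L
    pairs <- utils::combn(regimes, 2)
    scan_alpha <- if (scan == "fast") fit$alpha else NULL
    best <- NULL
    for (q in seq_len(ncol(pairs))) {
      keep <- pairs[1, q]; drop <- pairs[2, q]
      sh <- painting$shifts
      sh$regime[sh$regime == drop] <- keep
      basal <- if (painting$basal == drop) keep else painting$basal
      cand <- paint_regimes(ctx$tree, sh, basal = basal)
      cfit <- tryCatch(fit_hansen(traits, ctx, cand, alpha = scan_alpha),
                       error = function(err) NULL)
      if (is.null(cfit)) next
      if (is.null(best) || cfit$aicc < best$fit$aicc)
        best <- list(pair = pairs[, q], painting = cand, fit = cfit)
    }
    if (!is.null(best) && scan == "fast")
      best$fit <- tryCatch(fit_hansen(traits, ctx, best$painting),
                           error = function(err) best$fit)
    if (is.null(best) || (fit$aicc - best$fit$aicc) <= threshold) break
    painting <- best$painting
    fit <- best$fit
    cm <- convergence_metrics(painting)
    history <- rbind(history,
                     data.frame(phase = "backward", step = step,
                                edge = NA_integer_, k = cm$k,
                                kprime = cm$kprime, aicc = fit$aicc))
    if (verbose)
      message(sprintf("backward step %d: merged regimes %d+%d, AICc %.3f",
                      step, best$pair[1], best$pair[2], fit$aicc))
  }
  cm <- convergence_metrics(painting)
  members <- split(ctx$tree$tip.label,
                   painting$edge_regime[ctx$child_to_edge[seq_len(ctx$n)]])
  structure(c(list(painting = painting, fit = fit, history = history,
                   members = members), cm),
            class = "surface_result")
}

#' @export
print.surface_result <- function(x, ...) {
  cat("surface_result: k =", x$k, "k' =", x$kprime, "delta_k =", x$delta_k,
      "c =", x$c, "| final AICc =", round(x$fit$aicc, 3), "\n")
  invisible(x)
}

#' Run the full stepwise convergence analysis
#'
#' Convenience wrapper: [surface_forward()] then [surface_backward()]. The
#' two phases guard different errors: the forward threshold absorbs the
#' multiplicity of scanning every branch (default 10), while the backward
#' threshold accepts any AICc-improving merge (default 0) so genuine
#' convergence among the retained regimes is found.
#'
#' @inheritParams surface_forward
#' @param forward_threshold AICc improvement needed to accept a shift;
#'   default 10.
#' @param backward_threshold AICc improvement needed to accept a merge;
#'   default 0.
#' @param verbose print progress lines.
#' @return a `surface_result`; see [surface_backward()].
#' @export
run_surface <- function(traits, tree, forward_threshold = 10,
                        backward_threshold = 0, max_shifts = Inf,
                        scan = c("fast", "full"), verbose = FALSE) {
  scan <- match.arg(scan)
  fwd <- surface_forward(traits, tree, threshold = forward_threshold,
                         max_shifts = max_shifts, scan = scan,
                         verbose = verbose)
  surface_backward(traits, tree, fwd, threshold = backward_threshold,
                   scan = scan, verbose = verbose)
}

#' Add-one permutation-style p-value
#'
#' `p = (number of null values >= observed + 1) / (n + 1)`; never exactly
#' zero, reported to three decimals by the pipeline.
#'
#' @param observed observed statistic.
#' @param null_values vector of null statistics.
#' @export
surface_pvalue <- function(observed, null_values) {
  (sum(null_values >= observed) + 1) / (length(null_values) + 1)
}

#' Null distribution of the convergence metrics
#'
#' Simulates traits under a fitted Hansen model in which every shift has its
#' own unique regime (a model with regime shifts but no true convergence),
#' reruns the full forward + backward search on each simulated dataset, and
#' records `c` and `delta_k`. Comparing the observed metrics against this
#' distribution asks whether the detected convergence exceeds what stepwise
#' over-merging produces by chance.
#'
#' @param fit a `hansen_fit` whose painting has all-unique regimes (see
#'   [surface_null_test()] for the wrapper that builds it).
#' @param tree ultrametric `phylo`.
#' @param n_sim number of simulations (>= 50).
#' @param seed RNG seed.
#' @param forward_threshold,backward_threshold acceptance thresholds for the
#'   two search phases; see [run_surface()].
#' @return a `null_distribution` list: data.frame `stats` with per-iteration
#'   `c` and `delta_k`, plus `n_sim` and `seed`.
#' @export
simulate_null <- function(fit, tree, n_sim = 500, seed = 1,
                          forward_threshold = 10, backward_threshold = 0,
                          scan = c("fast", "full")) {
  scan <- match.arg(scan)
  stopifnot(inherits(fit, "hansen_fit"), n_sim >= 50)
  ctx <- tree_context(tree)
  stats_df <- data.frame(c = integer(n_sim), delta_k = integer(n_sim))
  for (b in seq_len(n_sim)) {
    sim <- simulate_ou_traits(ctx$tree, fit$painting, fit$alpha, fit$sigma2,
                              fit$theta, seed = derive_seed(seed, b))
    res <- run_surface(sim, ctx$tree, forward_threshold = forward_threshold,
                       backward_threshold = backward_threshold, scan = scan)
    stats_df$c[b] <- res$c
    stats_df$delta_k[b] <- res$delta_k
  }
  structure(list(stats = stats_df, n_sim = n_sim, seed = seed),
            class = "null_distribution")
}

#' Test observed convergence against the simulated null
#'
#' Builds the no-convergence null model from an observed `surface_result`
#' (same shift locations, every shift relabelled to its own regime), refits
#' it to the observed traits, simulates the null distribution, and returns
#' add-one p-values for `c` and `delta_k`.
#'
#' @param result a `surface_result` from [run_surface()].
#' @param traits the observed species x trait matrix.
#' @param tree ultrametric `phylo`.
#' @param n_sim number of null simulations; default 500 (the study-scale
#'   setting); >= 50.
#' @param seed RNG seed.
#' @param forward_threshold,backward_threshold search acceptance thresholds.
#' @return list with `null` (the `null_distribution`), `observed` metrics,
#'   `p_c`, and `p_delta_k`.
#' @export
surface_null_test <- function(result, traits, tree, n_sim = 500, seed = 1,
                              forward_threshold = 10, backward_threshold = 0,
                              scan = c("fast", "full")) {
  scan <- match.arg(scan)
  stopifnot(inherits(result, "surface_result"))
  sh <- result$painting$shifts
  if (nrow(sh)) sh$regime <- seq_len(nrow(sh)) + 1L
  null_painting <- paint_regimes(stats::reorder(tree, "cladewise"), sh,
                                 basal = 1L)
  null_fit <- fit_hansen(traits, tree, null_painting)
  null <- simulate_null(null_fit, tree, n_sim = n_sim, seed = seed,
                        forward_threshold = forward_threshold,
                        backward_threshold = backward_threshold, scan = scan)
  list(null = null,
       observed = list(c = result$c, delta_k = result$delta_k),
       p_c = surface_pvalue(result$c, null$stats$c),
       p_delta_k = surface_pvalue(result$delta_k, null$stats$delta_k))
}

#' Export a painted tree as annotated Newick plus a branch table
#'
#' Writes the tree with regime ids as node labels of each branch's child
#' node (tips get `label#regime`), and a TSV of edge index, child node and
#' regime.
#'
#' @param tree `phylo` used for the painting.
#' @param painting a `regime_painting`.
#' @param file path for the Newick; `paste0(file, ".tsv")` gets the table.
#' @export
write_painted_newick <- function(tree, painting, file) {
  tr <- stats::reorder(tree, "cladewise")
  stopifnot(painting$n_edges == nrow(tr$edge))
  child <- tr$edge[, 2]
  node_regime <- integer(max(tr$edge))
  node_regime[child] <- painting$edge_regime
  ntip <- ape::Ntip(tr)
  tr$tip.label <- paste0(tr$tip.label, "#", node_regime[seq_len(ntip)])
  tr$node.label <- c("", as.character(node_regime[(ntip + 2L):max(tr$edge)]))
  write_phylogeny(tr, file)
  write.table(data.frame(edge = seq_len(painting$n_edges), child = child,
                         regime = painting$edge_regime),
              paste0(file, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
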