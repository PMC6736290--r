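test_that("ou_vcv reproduces the Brownian limit and the stationary diagonal", {
  t1 <- tree_abc()
  expect_lt(max(abs(ou_vcv(t1, 1e-12, 1) - ape::vcv.phylo(t1))), 1e-6)
  a <- 0.5
  V <- ou_vcv(t1, a, 1)
  expect_equal(V["C", "C"], (1 / (2 * a)) * (1 - exp(-2 * a * 1.5)))
  # symmetric PSD across a parameter sweep
  tr <- simulate_yule_tree(15, 0.2, seed = 3)
  for (al in c(1e-10, 0.01, 0.1, 1)) {
    V <- ou_vcv(tr, al, 2)
    expect_equal(V, t(V))
    expect_gt(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
              -1e-9 * max(V))
  }
  ne <- tr; ne$edge.length[1] <- ne$edge.length[1] * 3
  expect_error(ou_vcv(ne, 0.1, 1), "ultrametric")
})

test_that("ou_vcv matches an exact branch-wise OU simulation oracle", {
  # process started at the root value, optimum = start: simulate transitions
  # x_child = x_par * exp(-a t) + N(0, s2/(2a) (1 - exp(-2a t))) per branch
  t1 <- tree_abc()
  a <- 0.5; s2 <- 1; N <- 1e5
  set.seed(77)
  tv <- function(t) s2 / (2 * a) * (1 - exp(-2 * a * t))
  xI <- rnorm(N, 0, sqrt(tv(0.5)))
  xA <- xI * exp(-a * 1) + rnorm(N, 0, sqrt(tv(1)))
  xB <- xI * exp(-a * 1) + rnorm(N, 0, sqrt(tv(1)))
  xC <- rnorm(N, 0, sqrt(tv(1.5)))
  emp <- cov(cbind(A = xA, B = xB, C = xC))
  V <- ou_vcv(t1, a, s2)[c("A", "B", "C"), c("A", "B", "C")]
  se <- sqrt((outer(diag(V), diag(V)) + V^2) / N)
  expect_true(all(abs(emp - V) < 3 * se + 1e-12))
})

test_that("hansen_weights telescopes to one and localises at large alpha", {
  tr <- simulate_yule_tree(12, 0.2, seed = 6, height = 1)
  W1 <- hansen_weights(tr, basal_painting(tr), 0.7)
  expect_equal(unname(rowSums(W1)), rep(1, 12), tolerance = 1e-9)
  expect_equal(unname(W1[, 1]), rep(1, 12), tolerance = 1e-9)

  # alpha*T = 40: weight concentrates on each tip's terminal-branch regime
  ctx_tree <- stats::reorder(tr, "cladewise")
  term_edge <- which(ctx_tree$edge[, 2] == 1L)  # terminal edge of tip s01
  p2 <- paint_regimes(ctx_tree, data.frame(edge = term_edge, regime = 2L))
  W2 <- hansen_weights(ctx_tree, p2, 40)
  expect_equal(unname(rowSums(W2)), rep(1, 12), tolerance = 1e-9)
  expect_equal(W2["s01", "2"], 1, tolerance = 1e-6)
  expect_equal(unname(W2[rownames(W2) != "s01", "2"]), rep(0, 11),
               tolerance = 1e-6)
})

test_that("hansen_weights matches the hand-evaluated segment formula", {
  # shift regime starts at depth 0.5 on the path to A (depth 1, alpha 1):
  # weight = exp(-1*(1-1)) - exp(-1*(1-0.5)) = 1 - exp(-0.5)
  tr <- read_phylogeny("((A:0.5,B:0.5):0.5,C:1);")
  ctx_tree <- stats::reorder(tr, "cladewise")
  eA <- which(ctx_tree$edge[, 2] == which(ctx_tree$tip.label == "A"))
  p <- paint_regimes(ctx_tree, data.frame(edge = eA, regime = 2L))
  W <- hansen_weights(ctx_tree, p, 1)
  expect_equal(W["A", "2"], 1 - exp(-0.5), tolerance = 1e-12)
  expect_equal(W["B", "2"], 0)
  expect_equal(W["A", "1"], exp(-0.5), tolerance = 1e-12)
})

test_that("aicc implements the small-sample correction", {
  expect_equal(aicc(-100, 5, 1e9), 210, tolerance = 1e-6)
  expect_equal(aicc(-100, 5, 52), 210 + 60 / 46)
  expect_error(aicc(-100, 51, 52), "n - p - 1")
})

test_that("fit_hansen recovers single-regime OU parameters and degenerates sanely", {
  ths <- c(); als <- c()
  for (s in 1:5) {
    tr <- simulate_yule_tree(100, 1, seed = 500 + s, height = 1)
    y <- simulate_ou_traits(tr, basal_painting(tr), alpha = 2, sigma2 = 1,
                            theta = 5, seed = 600 + s)
    f <- fit_hansen(y, tr)
    ths <- c(ths, f$theta[1, 1]); als <- c(als, f$alpha)
  }
  # stationary SD is 0.5 here; the acceptance suite runs the full
  # 20-replicate version of this recovery check
  expect_lt(abs(median(ths) - 5), 0.75)
  expect_lt(abs(log2(median(als) / 2)), 1)  # within a factor of 2

  tr <- simulate_yule_tree(20, 0.3, seed = 7, height = 1)
  ctx_tree <- stats::reorder(tr, "cladewise")
  p2 <- paint_regimes(ctx_tree, data.frame(edge = 3L, regime = 2L))
  yconst <- matrix(4, 20, 1, dimnames = list(ctx_tree$tip.label, "t"))
  fc <- fit_hansen(yconst, ctx_tree, p2, alpha = 1)
  expect_equal(unname(fc$theta[, 1]), c(4, 4), tolerance = 1e-8)
  expect_lte(fc$sigma2, 1e-10)
})

test_that("fit_hansen at the Brownian limit equals the closed-form BM likelihood", {
  tr <- simulate_yule_tree(30, 0.3, seed = 5, height = 1)
  y <- simulate_bm_traits(tr, matrix(1), matrix(1e-4), seed = 6)
  f <- fit_hansen(y, tr, alpha = 1e-9)
  C <- ape::vcv.phylo(tr)
  yo <- y[rownames(C), 1]
  Ci <- solve(C)
  mu <- sum(Ci %*% yo) / sum(Ci)
  rc <- yo - mu
  s2 <- drop(t(rc) %*% Ci %*% rc) / 30
  lnL_bm <- -0.5 * (30 * log(2 * pi * s2) + determinant(C)$modulus + 30)
  expect_equal(f$lnL, as.numeric(lnL_bm), tolerance = 1e-4)
})

test_that("the optimiser's accepted optimum beats random (alpha, sigma2) probes", {
  tr <- simulate_yule_tree(40, 0.3, seed = 15, height = 1)
  y <- simulate_ou_traits(tr, basal_painting(tr), 3, 1, 0, seed = 16)
  f <- fit_hansen(y, tr)
  C <- ape::vcv.phylo(tr)
  W <- matrix(1, 40, 1)
  set.seed(17)
  for (k in 1:100) {
    al <- exp(runif(1, log(1e-3), log(50)))
    V0 <- ou_vcv(tr, al, 1)[rownames(C), rownames(C)]
    yy <- y[rownames(C), 1]
    th <- drop(solve(t(W) %*% solve(V0, W), t(W) %*% solve(V0, yy)))
    r <- yy - th
    s2 <- drop(t(r) %*% solve(V0, r)) / 40
    lnL <- -0.5 * (40 * log(2 * pi * s2) + determinant(V0)$modulus + 40)
    expect_gte(f$lnL + 1e-6, as.numeric(lnL))
  }
})

test_that("convergence_metrics counts placements including the basal one", {
  tr <- simulate_yule_tree(10, 0.3, seed = 8)
  ctx_tree <- stats::reorder(tr, "cladewise")
  internal <- which(ctx_tree$edge[, 2] > 10)[1:3]
  m1 <- convergence_metrics(paint_regimes(ctx_tree,
    data.frame(edge = internal, regime = c(2L, 2L, 3L))))
  expect_equal(m1[c("k", "kprime", "delta_k", "c")],
               list(k = 4L, kprime = 3L, delta_k = 1L, c = 2L))

  m2 <- convergence_metrics(paint_regimes(ctx_tree,
    data.frame(edge = internal, regime = 2:4)))
  expect_equal(m2$delta_k, 0L)
  expect_equal(m2$c, 0L)

  # reversions to the basal regime are convergent with the basal placement
  m3 <- convergence_metrics(paint_regimes(ctx_tree,
    data.frame(edge = internal[1:2], regime = c(1L, 1L))))
  expect_equal(m3[c("k", "kprime", "delta_k", "c")],
               list(k = 3L, kprime = 1L, delta_k = 2L, c = 3L))
})

test_that("surface_pvalue uses the add-one convention", {
  null_c <- c(rep(0, 482), rep(6, 18))
  expect_equal(surface_pvalue(6, null_c), 19 / 501)
  expect_equal(round(surface_pvalue(6, null_c), 3), 0.038)
  expect_equal(surface_pvalue(0, null_c), 1)
  expect_equal(surface_pvalue(7, c(rep(0, 500))), 1 / 501)
})

test_that("forward AICc trace is monotone and backward never worsens it", {
  aT <- 5; H <- 1; ssd <- sqrt(1 / (2 * aT))
  tr <- simulate_yule_tree(30, 1, seed = 18, height = H)
  ctx <- phylovenom:::tree_context(tr)
  ndesc <- colSums(ctx$incidence)
  sh <- which(ndesc >= 3 & ndesc <= 8)[1:2]
  pl <- paint_regimes(ctx$tree, data.frame(edge = sh, regime = 2L))
  y <- simulate_ou_traits(ctx$tree, pl, aT, 1, rbind(c(0, 0), c(8, 8) * ssd),
                          seed = 19)
  fwd <- surface_forward(y, ctx$tree)
  expect_true(all(diff(fwd$history$aicc) < 0))
  res <- surface_backward(y, ctx$tree, fwd)
  expect_lte(res$fit$aicc, fwd$fit$aicc)
  expect_gte(res$k, res$kprime)
  expect_gte(res$kprime, 1)
})

test_that("backward merges near-identical optima but keeps separated ones", {
  aT <- 5; H <- 1; ssd <- sqrt(1 / (2 * aT))
  tr <- simulate_yule_tree(40, 1, seed = 28, height = H)
  ctx <- phylovenom:::tree_context(tr)
  ndesc <- colSums(ctx$incidence)
  cand <- which(ndesc >= 4 & ndesc <= 10)
  sh <- cand[c(1, length(cand))]
  # same true optimum -> convergent, should merge
  pl_conv <- paint_regimes(ctx$tree, data.frame(edge = sh, regime = 2L))
  y1 <- simulate_ou_traits(ctx$tree, pl_conv, aT, 1,
                           rbind(c(0, 0), c(10, 10) * ssd), seed = 29)
  res1 <- run_surface(y1, ctx$tree)
  expect_gte(res1$delta_k, 1)

  # well-separated optima -> no merge
  pl_dist <- paint_regimes(ctx$tree, data.frame(edge = sh, regime = 2:3))
  y2 <- simulate_ou_traits(ctx$tree, pl_dist, aT, 1,
                           rbind(c(0, 0), c(10, 0) * ssd, c(0, 10) * ssd),
                           seed = 30)
  res2 <- run_surface(y2, ctx$tree)
  expect_equal(res2$delta_k, 0L)
  expect_equal(res2$c, 0L)
})

test_that("simulate_null reruns the search and returns configured counts", {
  aT <- 5; H <- 1; ssd <- sqrt(1 / (2 * aT))
  tr <- simulate_yule_tree(20, 1, seed = 38, height = H)
  ctx <- phylovenom:::tree_context(tr)
  ndesc <- colSums(ctx$incidence)
  sh <- which(ndesc >= 3 & ndesc <= 8)[1]
  pl <- paint_regimes(ctx$tree, data.frame(edge = sh, regime = 2L))
  y <- simulate_ou_traits(ctx$tree, pl, aT, 1, rbind(c(0, 0), c(8, 8) * ssd),
                          seed = 39)
  nf <- fit_hansen(y, ctx$tree, pl)
  nd <- simulate_null(nf, ctx$tree, n_sim = 50, seed = 40)
  expect_equal(nrow(nd$stats), 50)
  expect_true(all(nd$stats$delta_k >= 0))
  p <- surface_pvalue(2, nd$stats$c)
  expect_gt(p, 0); expect_lte(p, 1)
  expect_error(simulate_null(nf, ctx$tree, n_sim = 10), "n_sim")
})
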