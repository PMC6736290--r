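test_that("simulate_yule_tree builds valid ultrametric trees", {
  t2 <- simulate_yule_tree(2, 0.5, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_true(is_ultrametric(t2))

  for (s in 1:25) {
    tr <- simulate_yule_tree(52, 0.1, seed = s)
    expect_equal(tr$Nnode, 51L)          # strictly binary
    expect_true(is_ultrametric(tr))
    expect_equal(tree_height(tr), 60, tolerance = 1e-9)
    expect_true(all(tr$edge.length >= 0))
  }
  raw <- simulate_yule_tree(10, 0.3, seed = 2, height = NULL)
  expect_equal(tree_height(raw), attr(raw, "raw_height"), tolerance = 1e-9)
  # reproducibility
  expect_equal(write_phylogeny(simulate_yule_tree(20, 0.2, seed = 9)),
               write_phylogeny(simulate_yule_tree(20, 0.2, seed = 9)))
})

test_that("yule waiting times are exponential with rate k * birth_rate", {
  b <- 0.4
  z <- unlist(lapply(1:500, function(s) {
    w <- attr(simulate_yule_tree(6, b, seed = 1000 + s), "waiting_times")
    w$wait * w$k * b   # standardised: should be iid Exp(1)
  }))
  ks <- suppressWarnings(stats::ks.test(z, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulate_bm_traits has the advertised degenerate and Monte-Carlo moments", {
  tr <- simulate_yule_tree(10, 0.3, seed = 3)
  y0 <- simulate_bm_traits(tr, matrix(0), matrix(0), mu = 2.5, seed = 4)
  expect_equal(unname(y0[, 1]), rep(2.5, 10))

  # G = 0, R = I: pooled tip values are iid with identity covariance
  acc <- matrix(0, 2, 2)
  for (s in 1:1000) {
    y <- simulate_bm_traits(tr, 0 * diag(2), diag(2), seed = 4000 + s)
    acc <- acc + crossprod(y) / nrow(y)
  }
  expect_true(all(abs(acc / 1000 - diag(2)) < 0.1))

  # G = I, R = 0: sister-pair covariance equals shared scaled depth
  t3 <- tree_abc()
  C <- phylo_vcv(t3)
  ab <- vapply(1:1000, function(s) {
    y <- simulate_bm_traits(t3, matrix(1), matrix(0), seed = 8000 + s)
    y["A", 1] * y["B", 1]
  }, numeric(1))
  expect_equal(mean(ab), C["A", "B"], tolerance = 4 * sd(ab) / sqrt(1000))

  expect_error(simulate_bm_traits(tr, matrix(-1), matrix(0), seed = 1),
               "semidefinite")
})

test_that("simulate_ou_traits matches the stationary distribution at large alpha*T", {
  tr <- simulate_yule_tree(5, 1, seed = 5, height = 1)
  p0 <- basal_painting(tr)
  vals <- vapply(1:1000, function(s)
    simulate_ou_traits(tr, p0, alpha = 20, sigma2 = 4, theta = 3,
                       seed = 9000 + s)[1, 1], numeric(1))
  expect_equal(mean(vals), 3, tolerance = 0.05)
  expect_equal(var(vals), 4 / (2 * 20), tolerance = 0.02)
})

test_that("simulate_ou_traits approaches Brownian motion as alpha -> 0", {
  tr <- simulate_yule_tree(5, 1, seed = 6, height = 1)
  p0 <- basal_painting(tr)
  C <- ape::vcv.phylo(tr)
  ou <- t(vapply(1:500, function(s)
    simulate_ou_traits(tr, p0, alpha = 1e-6, sigma2 = 2, theta = 0,
                       seed = 10000 + s)[, 1], numeric(5)))
  for (tip in 1:5) {
    ks <- suppressWarnings(
      stats::ks.test(ou[, tip], "pnorm", 0, sqrt(2 * C[tip, tip])))
    expect_gt(ks$p.value, 0.005)
  }
})

test_that("a strongly shifted clade tracks its own optimum", {
  tr <- simulate_yule_tree(30, 1, seed = 7, height = 1)
  ctx <- phylovenom:::tree_context(tr)
  ndesc <- colSums(ctx$incidence)
  e <- which(ndesc >= 5 & ndesc <= 10)[1]
  pl <- paint_regimes(ctx$tree, data.frame(edge = e, regime = 2L))
  aT <- 5; ssd <- sqrt(1 / (2 * aT))
  clade <- which(ctx$incidence[, e] == 1)
  hits <- vapply(1:200, function(s) {
    y <- simulate_ou_traits(ctx$tree, pl, aT, 1,
                            rbind(0, 10 * ssd), seed = 11000 + s)
    all(abs(y[clade, 1] - 10 * ssd) < abs(y[clade, 1] - 0))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("simulate_venom_dataset yields a closed, zero-inflated, batched table", {
  sim <- simulate_venom_dataset(venom_scenario(seed = 3))
  v <- sim$table$values
  expect_equal(dim(v), c(52, 25))
  expect_equal(unname(rowSums(v)), rep(100, 52), tolerance = 1e-6)
  expect_true(any(v == 0))
  expect_equal(length(sim$table$batch), 52)
  expect_equal(ape::Ntip(sim$tree), 52)

  # bit-reproducible given the scenario
  sim2 <- simulate_venom_dataset(venom_scenario(seed = 3))
  expect_identical(sim$table$values, sim2$table$values)

  # decoys at 20% prevalence are removed at threshold 0.5; the 10 core
  # components are retained
  f <- prevalence_filter(sim$table, 0.5)
  expect_setequal(attr(f, "retained"), venom_scenario()$components)
})

test_that("retention count matches the column-counting oracle across seeds", {
  for (s in 1:3) {
    sim <- simulate_venom_dataset(venom_scenario(seed = 20 + s))
    f <- prevalence_filter(sim$table, 0.5)
    oracle <- sum(colMeans(sim$table$values > 1e-6) >= 0.5)
    expect_equal(length(attr(f, "retained")), oracle)
    expect_equal(length(attr(f, "retained")), 10)
  }
})

test_that("high-lambda components keep higher estimated signal than low-lambda ones", {
  # desk-scale version of the generator/model round trip: 3 of 6 components
  # simulated at lambda 0.85, 3 at 0.3
  ok <- vapply(1:3, function(s) {
    tr <- simulate_yule_tree(40, 0.15, seed = 700 + s)
    lam <- c(0.85, 0.85, 0.85, 0.3, 0.3, 0.3)
    Y <- simulate_bm_traits(tr, diag(lam), diag(1 - lam), seed = 800 + s)
    fit <- fit_pglmm(Y, tr, pglmm_config(n_iterations = 20000, burnin = 4000,
                                         thin = 10, seed = 900 + s,
                                         response_scaling = FALSE))
    le <- lambda_estimates(fit)
    mean(le$mean[1:3]) > mean(le$mean[4:6])
  }, logical(1))
  expect_gte(mean(ok), 2 / 3)
})
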