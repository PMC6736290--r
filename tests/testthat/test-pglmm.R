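# a fabricated fit with known draw arrays, for the summary operations
fake_fit <- function(Gd, Rd, components = NULL) {
  m <- dim(Gd)[1]
  components <- components %||% paste0("c", seq_len(m))
  structure(list(G = Gd, R = Rd, components = components),
            class = "pglmm_fit")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("fit_pglmm is deterministic given the seed and validates inputs", {
  tr <- simulate_yule_tree(12, 0.2, seed = 4)
  Y <- simulate_bm_traits(tr, diag(3), 0.3 * diag(3), seed = 5)
  cfg <- pglmm_config(n_iterations = 3000, burnin = 500, thin = 10, seed = 9,
                      response_scaling = FALSE)
  f1 <- fit_pglmm(Y, tr, cfg)
  f2 <- fit_pglmm(Y, tr, cfg)
  expect_identical(f1$G, f2$G)
  expect_identical(f1$deviance, f2$deviance)

  expect_error(fit_pglmm(Y[1:2, ], tr, cfg), "at least 3 species")
  Ybad <- Y; rownames(Ybad)[1] <- "not_a_tip"
  expect_error(fit_pglmm(Ybad, tr, cfg), "not_a_tip")
})

test_that("every stored G and R draw is symmetric positive definite", {
  tr <- simulate_yule_tree(12, 0.2, seed = 4)
  Y <- simulate_bm_traits(tr, diag(3), 0.3 * diag(3), seed = 5)
  f <- fit_pglmm(Y, tr, pglmm_config(n_iterations = 3000, burnin = 500,
                                     thin = 10, seed = 1,
                                     response_scaling = FALSE))
  ok <- vapply(seq_len(dim(f$G)[3]), function(s) {
    g <- f$G[, , s]; r <- f$R[, , s]
    isTRUE(all.equal(g, t(g))) && isTRUE(all.equal(r, t(r))) &&
      !inherits(try(chol(g), silent = TRUE), "try-error") &&
      !inherits(try(chol(r), silent = TRUE), "try-error")
  }, logical(1))
  expect_true(all(ok))
})

test_that("posterior_pcov summarises degenerate and synthetic posteriors correctly", {
  m <- 3; S <- 150
  M <- matrix(c(1, 0.5, 0, 0.5, 1, 0, 0, 0, 1), 3, 3)
  Gd <- array(M, dim = c(m, m, S))
  Rd <- array(diag(m), dim = c(m, m, S))
  pc <- posterior_pcov(fake_fit(Gd, Rd))
  expect_equal(pc$mean_G, M, ignore_attr = TRUE)
  expect_equal(pc$hpd_G[1, 2, ], c(0.5, 0.5), ignore_attr = TRUE)
  expect_true(pc$significant[1, 2])    # nonzero with zero-width HPD
  expect_false(pc$significant[1, 3])   # exactly zero draws: not flagged
  expect_false(any(diag(pc$significant)))
  expect_equal(pc$significant, t(pc$significant))

  # off-diagonal draws symmetric around 0 are not flagged;
  # draws centred well away from 0 with small spread are
  set.seed(7)
  Gd2 <- array(0, dim = c(2, 2, 400))
  Gd2[1, 1, ] <- Gd2[2, 2, ] <- 1
  shifted <- rnorm(400, 0.5, 0.1)
  centred <- rnorm(400, 0.05, 0.5)
  Gd2[1, 2, ] <- Gd2[2, 1, ] <- shifted
  pc2 <- posterior_pcov(fake_fit(Gd2, array(diag(2), dim = c(2, 2, 400))))
  expect_true(pc2$significant[1, 2])
  Gd2[1, 2, ] <- Gd2[2, 1, ] <- centred
  pc3 <- posterior_pcov(fake_fit(Gd2, array(diag(2), dim = c(2, 2, 400))))
  expect_false(pc3$significant[1, 2])

  expect_error(posterior_pcov(fake_fit(Gd[, , 1:50], Rd[, , 1:50])), "100")
})

test_that("lambda_estimates implements G_ii/(G_ii+R_ii) with its limits", {
  m <- 2; S <- 120
  Gd <- array(diag(c(0.8, 0.8)), dim = c(m, m, S))
  Rd <- array(diag(c(0.2, 0.2)), dim = c(m, m, S))
  lam <- lambda_estimates(fake_fit(Gd, Rd))
  expect_equal(lam$mean, c(0.8, 0.8))
  expect_true(all(lam$significant))

  lam1 <- lambda_estimates(fake_fit(Gd, array(0 * diag(m), dim = c(m, m, S))))
  expect_equal(lam1$mean, c(1, 1))

  Gd0 <- array(0 * diag(m), dim = c(m, m, S))
  expect_error(lambda_estimates(fake_fit(Gd0, Gd0)), "undefined")
})

test_that("effective_sample_size matches iid and AR(1) expectations", {
  for (s in 1:5) {
    set.seed(s)
    expect_gt(effective_sample_size(rnorm(10000)), 8000)
  }
  for (s in 1:5) {
    set.seed(100 + s)
    x <- as.numeric(arima.sim(list(ar = 0.5), 10000))
    expect_equal(effective_sample_size(x), 10000 / 3, tolerance = 0.2)
  }
  expect_equal(effective_sample_size(rep(2, 500)), 1)
  expect_lte(effective_sample_size(rnorm(200)), 200)
})

test_that("effective_sample_size agrees with an independent implementation", {
  skip_if_not_installed("coda")
  set.seed(11)
  x <- as.numeric(arima.sim(list(ar = 0.8), 5000))
  expect_equal(effective_sample_size(x),
               unname(coda::effectiveSize(coda::mcmc(x))), tolerance = 0.25)
})

test_that("autocorrelation returns exact lag-0 and closed-form AR(1) values", {
  set.seed(2)
  x <- rnorm(10000)
  expect_equal(autocorrelation(x, 0), 1)
  expect_lt(abs(autocorrelation(x, 1)), 0.05)
  y <- as.numeric(arima.sim(list(ar = 0.9), 10000))
  expect_equal(autocorrelation(y, 1), 0.9, tolerance = 0.05)
  expect_error(autocorrelation(rep(1, 100), 1), "constant")
  expect_error(autocorrelation(x, 6000))
})

test_that("dic equals 2*mean(deviance) - deviance at the posterior mean", {
  tr <- simulate_yule_tree(10, 0.2, seed = 21)
  Y <- simulate_bm_traits(tr, diag(2), 0.5 * diag(2), seed = 22)
  f <- fit_pglmm(Y, tr, pglmm_config(n_iterations = 2000, burnin = 500,
                                     thin = 10, seed = 3,
                                     response_scaling = FALSE))
  Gbar <- apply(f$G, c(1, 2), mean); Rbar <- apply(f$R, c(1, 2), mean)
  Bbar <- matrix(colMeans(f$beta), ncol = 2)
  resid <- f$rotated$Y - f$rotated$X %*% Bbar
  dev_mean <- -2 * sum(vapply(seq_len(nrow(resid)), function(i)
    oracle_ldmvnorm(resid[i, ], rep(0, 2), f$rotated$d[i] * Gbar + Rbar),
    numeric(1)))
  expect_equal(dic(f), 2 * mean(f$deviance) - dev_mean, tolerance = 1e-8)
})

test_that("a nested lower-noise model attains lower DIC on the same data", {
  tr <- simulate_yule_tree(25, 0.2, seed = 31)
  Y <- simulate_bm_traits(tr, diag(2), 0.1 * diag(2), seed = 32)
  Ynoisy <- Y + matrix(rnorm(length(Y), sd = 2), nrow(Y), ncol(Y))
  cfg <- pglmm_config(n_iterations = 5000, burnin = 1000, thin = 10, seed = 5,
                      response_scaling = FALSE)
  expect_lt(dic(fit_pglmm(Y, tr, cfg)), dic(fit_pglmm(Ynoisy, tr, cfg)))
})

test_that("a phylogeny-independent batch effect leaves the PCOV unchanged", {
  tr <- simulate_yule_tree(40, 0.15, seed = 41)
  Y <- simulate_bm_traits(tr, diag(3), 0.25 * diag(3), seed = 42)
  set.seed(43)
  batch <- setNames(sample(c("hiseq", "novaseq"), 40, replace = TRUE),
                    rownames(Y))
  shift <- c(hiseq = 0, novaseq = 1.5)
  Yb <- Y + shift[batch]
  cfg <- pglmm_config(n_iterations = 20000, burnin = 4000, thin = 10,
                      seed = 6, response_scaling = FALSE)
  g_plain <- posterior_pcov(fit_pglmm(Y, tr, cfg))$mean_G
  g_batch <- posterior_pcov(fit_pglmm(Yb, tr, cfg, batch = batch))$mean_G
  expect_lt(norm(g_batch - g_plain, "F") / norm(g_plain, "F"), 0.25)
})
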