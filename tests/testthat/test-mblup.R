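test_that("relationship matrix matches the hand product and is PSD", {
  B <- matrix(c(1, -1, -1, 1), 2, 2)
  expect_equal(build_relationship(B),
               matrix(c(1, -1, -1, 1), 2, 2), tolerance = 1e-12)
  set.seed(30)
  B2 <- standardize_columns(matrix(rnorm(20 * 6), 20, 6))
  B2 <- rbind(B2, B2[3, ])                      # identical animals
  K <- build_relationship(B2)
  expect_equal(K[21, ], K[3, ], tolerance = 1e-12)
  expect_true(all(eigen(K, symmetric = TRUE, only.values = TRUE)$values >=
                  -1e-10))
  expect_equal(K, t(K))
  expect_error(standardize_columns(cbind(1:5, rep(2, 5))), "zero-variance")
})

test_that("fixed-variance sampler reproduces the ridge/GBLUP posterior mean", {
  set.seed(31)
  n <- 40
  B <- standardize_columns(matrix(rnorm(n * 30), n, 30))
  K <- build_relationship(B)
  eg <- eigen(K, symmetric = TRUE)
  m_true <- drop(eg$vectors %*% (sqrt(pmax(eg$values, 0) * 0.6) * rnorm(n)))
  y <- 1.5 + m_true + rnorm(n, 0, sqrt(0.4))
  sm2 <- 0.6; se2 <- 0.4
  ch <- fit_mblup(y, NULL, K, iterations = 55000, burnin = 5000, thin = 10,
                  seed = 32, fix_sigma = list(m = sm2, e = se2),
                  save_m = TRUE)
  lambda <- se2 / sm2
  bhat <- mean(y - ch$m_mean)
  oracle <- drop(K %*% solve(K + lambda * diag(n), y - bhat))
  expect_lt(max(abs(ch$m_mean - oracle)), 0.05)
  expect_lt(mean(abs(ch$m_mean - oracle)), 0.01)
})

test_that("microbiability draws stay in (0,1) and are scale invariant", {
  set.seed(33)
  n <- 30
  K <- build_relationship(standardize_columns(matrix(rnorm(n * 10), n, 10)))
  y <- rnorm(n)
  ch1 <- suppressWarnings(fit_mblup(y, NULL, K, iterations = 3000,
                                    burnin = 1000, thin = 2, seed = 34))
  expect_true(all(ch1$draws$microbiability > 0 &
                  ch1$draws$microbiability < 1))
  expect_true(all(ch1$draws$sigma_m2 > 0))
  expect_true(all(ch1$draws$sigma_e2 > 0))
  # rescaling the phenotype leaves the variance ratio unchanged
  ch2 <- suppressWarnings(fit_mblup(10 * y, NULL, K, iterations = 3000,
                                    burnin = 1000, thin = 2, seed = 34))
  expect_equal(ch1$draws$microbiability, ch2$draws$microbiability,
               tolerance = 1e-8)
  # reproducibility for a fixed seed
  ch3 <- suppressWarnings(fit_mblup(y, NULL, K, iterations = 3000,
                                    burnin = 1000, thin = 2, seed = 34))
  expect_identical(ch1$draws, ch3$draws)
  expect_equal(nrow(ch1$draws), (3000 - 1000) / 2)
})

test_that("null data keep the posterior median of microbiability low", {
  hits <- vapply(1:5, function(s) {
    e <- generate_experiment(sim_config(n_H = 100, n_L = 100, p = 60,
                                        n_diff = 0, imf_line_diff = 0,
                                        target_microbiability = 0, seed = s))
    a <- quick_alr(e)
    K <- build_relationship(standardize_columns(a))
    ch <- suppressWarnings(fit_mblup(e$meta$imf, NULL, K, iterations = 7000,
                                     burnin = 2000, thin = 10, seed = s))
    summarize_chain(ch)$median < 0.25
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("within-line refits run through the same path", {
  e <- generate_experiment(sim_config(n_H = 30, n_L = 30, p = 40, n_diff = 6, seed = 36))
  a <- quick_alr(e)
  for (l in c("H", "L")) {
    idx <- e$meta$line == l
    K <- build_relationship(standardize_columns(a[idx, , drop = FALSE]))
    ch <- suppressWarnings(fit_mblup(e$meta$imf[idx], NULL, K,
                                     iterations = 7000, burnin = 2000,
                                     thin = 10, seed = 37))
    s <- summarize_chain(ch)
    expect_true(s$hpd[1] >= 0 && s$hpd[2] <= 1)
    expect_true(s$median >= s$hpd[1] && s$median <= s$hpd[2])
  }
})

test_that("chain summaries match brute-force HPD and the analytic uniform", {
  # constant chain
  s <- summarize_chain(rep(0.4, 600), threshold = 0.25)
  expect_equal(s$median, 0.4)
  expect_equal(unname(s$hpd), c(0.4, 0.4))
  expect_equal(s$p_gt_threshold, 1)
  expect_equal(summarize_chain(rep(0.1, 600))$p_gt_threshold, 0)
  # uniform draws: HPD width ~ 0.95
  set.seed(38)
  u <- runif(10000)
  w <- diff(hpd_interval(u, 0.95))
  expect_lt(abs(w - 0.95), 0.02)
  # sliding-window oracle reproduces the bounds exactly
  for (i in 1:5) {
    x <- rgamma(400, shape = 2)
    expect_equal(unname(hpd_interval(x, 0.9)), brute_hpd(x, 0.9),
                 tolerance = 1e-12)
  }
})

test_that("Geweke Z is calibrated on iid chains and catches trends", {
  set.seed(39)
  zs <- vapply(1:60, function(i) geweke_z(rnorm(1000)), numeric(1))
  expect_gte(mean(abs(zs) < 3), 0.95)
  trend <- seq(0, 1, length.out = 2000) + rnorm(2000, 0, 0.02)
  expect_gt(abs(geweke_z(trend)), 5)
  expect_warning(z0 <- geweke_z(rep(1, 200)), "zero variance")
  expect_true(is.na(z0))
})

test_that("Geweke Z broadly agrees with the coda implementation", {
  set.seed(40)
  for (i in 1:5) {
    x <- as.numeric(arima.sim(list(ar = 0.6), 2000))
    ours <- geweke_z(x)
    ref <- unname(coda::geweke.diag(coda::mcmc(x))$z)
    expect_lt(abs(ours - ref), 0.75)
    expect_identical(sign(ours), sign(ref))
  }
})
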