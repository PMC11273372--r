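test_that("prevalence filter applies the undetected-fraction boundary exactly", {
  counts <- matrix(5L, 10, 3, dimnames = list(sprintf("s%02d", 1:10),
                                              c("keep1", "edge", "drop")))
  counts[1, "edge"] <- 0L              # 10% zeros: retained (boundary)
  counts[1:2, "drop"] <- 0L            # 20% zeros: discarded
  f <- filter_prevalence(counts, 0.10)
  expect_identical(colnames(f), c("keep1", "edge"))
  # all-positive table passes unchanged
  pos <- matrix(1:12, 3, 4, dimnames = list(letters[1:3], LETTERS[1:4]))
  expect_identical(filter_prevalence(pos), pos)
  expect_error(filter_prevalence(matrix(0L, 4, 2)), "every taxon")
})

test_that("prevalence filter equals a brute-force zero-fraction scan", {
  set.seed(10)
  counts <- matrix(rpois(40 * 25, 0.8), 40, 25,
                   dimnames = list(sprintf("s%02d", 1:40),
                                   sprintf("t%02d", 1:25)))
  thr <- 0.3
  f <- filter_prevalence(counts, thr)
  keep_oracle <- vapply(seq_len(25), function(j) {
    sum(counts[, j] == 0) / 40 <= thr
  }, logical(1))
  expect_identical(colnames(f), colnames(counts)[keep_oracle])
})

test_that("zero imputation reproduces the hand-evaluated replacement", {
  counts <- matrix(c(0L, 5L, 5L), 1, 3,
                   dimnames = list("s1", c("a", "b", "c")))
  comp <- impute_zeros(counts, prior_strength = 1)
  # s*t_j/(n+s) = 1*(1/3)/(10+1) = 0.030303; others (5/10)*(1-0.030303)
  expect_equal(unname(comp[1, ]), c(0.030303, 0.484848, 0.484848),
               tolerance = 1e-5)
  expect_equal(sum(comp), 1)
})

test_that("rows without zeros come out as exact count proportions", {
  counts <- matrix(c(2L, 3L, 5L, 1L, 1L, 2L), 2, 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  comp <- impute_zeros(counts)
  expect_equal(comp[1, ], counts[1, ] / 10, ignore_attr = TRUE)
  expect_equal(comp[2, ], counts[2, ] / 4, ignore_attr = TRUE)
})

test_that("imputation closes every row to 1 with strictly positive entries", {
  e <- quick_experiment(seed = 11)
  f <- filter_prevalence(e$counts)
  comp <- impute_zeros(f)
  expect_true(all(comp > 0))
  expect_equal(rowSums(comp), rep(1, nrow(comp)), ignore_attr = TRUE)
  expect_error(impute_zeros(rbind(c(0L, 0L), c(1L, 2L))), "all-zero")
})

test_that("filter + impute retain at least 99% of the original count mass", {
  e <- generate_experiment(sim_config(seed = 12))
  f <- filter_prevalence(e$counts)
  expect_gte(sum(f) / sum(e$counts), 0.99)
})

test_that("alr transformation matches its closed form and inverts exactly", {
  comp <- matrix(c(2, 4, 8) / 14, 1, 3, dimnames = list("s1", c("a", "b", "c")))
  X <- alr_transform(comp, "c")
  expect_equal(unname(X[1, ]), c(log(2 / 8), log(4 / 8)), tolerance = 1e-9)
  expect_equal(unname(X[1, ]), c(-1.386294, -0.693147), tolerance = 1e-6)
  expect_identical(attr(X, "reference"), "c")
  # scale invariance: alr of any positive rescaling is identical
  X2 <- alr_transform(comp * 3, "c")
  expect_equal(X, X2, tolerance = 1e-12)
  # two-taxon symmetric composition gives coordinate 0
  c2 <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("s", c("a", "b")))
  expect_equal(unname(alr_transform(c2, "b")[1, 1]), 0)
  expect_error(alr_transform(comp, "zz"), "not found")
  # round trip through the inverse recovers the composition
  big <- toy_composition(15, 6, seed = 13)
  back <- alr_inverse(alr_transform(big, "t03"))
  expect_equal(back[, colnames(big)], big, tolerance = 1e-9)
})

test_that("Procrustes correlation is 1 under similarity transforms and low on noise", {
  set.seed(14)
  X <- matrix(rnorm(50 * 3), 50, 3)
  expect_equal(procrustes_correlation(X, X), 1, tolerance = 1e-12)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Y <- 2.5 * X %*% R + matrix(c(1, -2, 3), 50, 3, byrow = TRUE)
  expect_equal(procrustes_correlation(X, Y), 1, tolerance = 1e-10)
  # independent Gaussian configurations decorrelate
  hits <- vapply(1:20, function(s) {
    set.seed(100 + s)
    procrustes_correlation(matrix(rnorm(100), 50, 2),
                           matrix(rnorm(100), 50, 2)) < 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  expect_error(procrustes_correlation(matrix(1, 5, 2), matrix(rnorm(10), 5, 2)),
               "zero-variance")
})

test_that("Procrustes correlation agrees with the vegan symmetric statistic", {
  set.seed(15)
  X <- matrix(rnorm(30 * 4), 30, 4)
  Y <- X %*% matrix(rnorm(16), 4, 4) + 0.3 * matrix(rnorm(120), 30, 4)
  ours <- procrustes_correlation(X, Y)
  ref <- sqrt(1 - vegan::procrustes(X, Y, symmetric = TRUE)$ss)
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("alr reference diagnostics match brute force on three taxa", {
  comp <- toy_composition(20, 3, seed = 16)
  sel <- select_alr_reference(comp, tolerance = 0.005)
  lg <- log(comp)
  clr <- lg - rowMeans(lg)
  # clr configuration against itself is exactly 1 (geometry oracle)
  expect_equal(procrustes_correlation(clr, clr), 1, tolerance = 1e-12)
  for (j in 1:3) {
    alr_j <- lg[, -j, drop = FALSE] - lg[, j]
    expect_equal(sel$diagnostics$procrustes_r[j],
                 procrustes_correlation(alr_j, clr), tolerance = 1e-10)
    expect_equal(sel$diagnostics$log_variance[j], var(lg[, j]),
                 tolerance = 1e-12)
  }
  expect_true(all(sel$diagnostics$procrustes_r >= 0 &
                  sel$diagnostics$procrustes_r <= 1))
})

test_that("a planted low-variance taxon is chosen as alr reference", {
  set.seed(17)
  n <- 40
  lg <- matrix(rnorm(n * 6, sd = 1), n, 6,
               dimnames = list(sprintf("s%02d", 1:n), sprintf("t%02d", 1:6)))
  lg[, 4] <- rnorm(n, sd = 0.05)    # near-constant candidate
  sel <- select_alr_reference(comp_from_log(lg))
  expect_identical(sel$reference, "t04")
})

test_that("batch correction equals group-mean subtraction and zeroes batch means", {
  set.seed(18)
  X <- matrix(rnorm(24 * 4), 24, 4,
              dimnames = list(sprintf("s%02d", 1:24), letters[1:4]))
  batch <- rep(c("b1", "b2"), 12)
  X[batch == "b2", 1] <- X[batch == "b2", 1] + 5
  Xc <- correct_batch(X, batch)
  expect_equal(max(abs(rowsum(Xc, batch))), 0, tolerance = 1e-10)
  # within-batch deviations preserved
  for (b in c("b1", "b2")) {
    idx <- batch == b
    expect_equal(sweep(X[idx, ], 2, colMeans(X[idx, ])), Xc[idx, ],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # oracle: explicit per-column per-batch centering
  oracle <- X
  for (j in 1:4) {
    for (b in c("b1", "b2")) {
      idx <- batch == b
      oracle[idx, j] <- X[idx, j] - mean(X[idx, j])
    }
  }
  expect_equal(Xc, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # batch-constant column becomes all zeros
  X[, 2] <- ifelse(batch == "b1", 1, 7)
  expect_equal(unname(correct_batch(X, batch)[, 2]), rep(0, 24))
  expect_error(correct_batch(X, c("x", rep("y", 23))), "singleton")
})

test_that("PCA diagnostic sees a planted batch shift vanish after correction", {
  set.seed(19)
  n <- 30
  X <- matrix(rnorm(n * 8, sd = 0.5), n, 8)
  rownames(X) <- sprintf("s%02d", 1:n)
  batch <- rep(c("b1", "b2"), each = 15)
  X[batch == "b2", ] <- X[batch == "b2", ] + 2
  before <- pca_batch_diagnostic(X)
  after <- pca_batch_diagnostic(correct_batch(X, batch))
  share_before <- micsel:::between_batch_share(before$PC1, batch)
  share_after <- micsel:::between_batch_share(after$PC1, batch)
  expect_gt(share_before, 0.8)
  expect_lt(share_after, 0.2)
  expect_lt(share_after, share_before)
  expect_equal(colMeans(as.matrix(before)), c(PC1 = 0, PC2 = 0),
               tolerance = 1e-10)
  expect_true(all(diff(attr(before, "sdev")) <= 1e-12))
})
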