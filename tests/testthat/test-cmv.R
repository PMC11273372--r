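# Selection operating characteristics of the two-step cross-model
# validation. Resampling sizes are reduced (8 folds x 2-3 reps) to keep the
# suite fast; the acceptance tests run the fuller design.

test_that("pure-noise predictors leave the final selection (almost) empty", {
  empties <- vapply(1:3, function(s) {
    set.seed(400 + s)
    X <- matrix(rnorm(60 * 50), 60, 50,
                dimnames = list(sprintf("n%02d", 1:60),
                                sprintf("v%02d", 1:50)))
    y <- rep(c("A", "B"), 30)
    sel <- suppressWarnings(
      cmv_select(X, y, "discriminant", folds = 8, reps = 2, seed = s))
    length(sel$final) <= 2
  }, logical(1))
  expect_gte(mean(empties), 2 / 3)
})

test_that("planted informative taxa are recovered with few false positives", {
  set.seed(57)
  n <- 89; p <- 60
  cls <- rep(c("H", "L"), c(47, 42))
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("t%02d", 1:p)))
  truth <- paste0("t", sprintf("%02d", 1:6))
  for (j in 1:6) X[, j] <- X[, j] + ifelse(cls == "H", 0.5, -0.5) *
    ifelse(j %% 2, 1, -1) * 1.2
  sel <- cmv_select(X, cls, "discriminant", folds = 8, reps = 3, seed = 58)
  expect_gte(sum(sel$final %in% truth), 5)
  expect_lte(sum(!sel$final %in% truth), 3)
  # frequencies are proper fractions and the final rule is freq > threshold
  expect_true(all(sel$frequency >= 0 & sel$frequency <= 1))
  expect_setequal(sel$final,
                  names(sel$frequency)[sel$frequency > sel$freq_threshold])
})

test_that("duplicated informative columns share their selection frequency", {
  set.seed(59)
  n <- 64
  cls <- rep(c("A", "B"), each = 32)
  signal <- ifelse(cls == "A", 1, -1) * 0.9 + rnorm(n, 0, 0.8)
  X <- cbind(d1 = signal, d2 = signal,
             matrix(rnorm(n * 20), n, 20,
                    dimnames = list(NULL, paste0("z", 1:20))))
  rownames(X) <- sprintf("s%03d", 1:n)
  sel <- suppressWarnings(
    cmv_select(X, cls, "discriminant", folds = 8, reps = 3, seed = 60))
  expect_lt(abs(sel$frequency["d1"] - sel$frequency["d2"]), 0.15)
})

test_that("selection is invariant to taxon column order", {
  set.seed(61)
  n <- 48; p <- 15
  cls <- rep(c("A", "B"), each = 24)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("v%02d", 1:p)))
  X[, 2] <- X[, 2] + ifelse(cls == "A", 1, -1)
  sel1 <- suppressWarnings(
    cmv_select(X, cls, "discriminant", folds = 8, reps = 2, seed = 62))
  perm <- sample(p)
  sel2 <- suppressWarnings(
    cmv_select(X[, perm], cls, "discriminant", folds = 8, reps = 2,
               seed = 62))
  expect_identical(sel1$final, sel2$final)
  expect_equal(sel1$frequency[sort(names(sel1$frequency))],
               sel2$frequency[sort(names(sel2$frequency))])
})

test_that("step-2 evaluation separates real effects from permuted labels", {
  set.seed(63)
  n <- 89
  cls <- rep(c("H", "L"), c(47, 42))
  X <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(sprintf("s%03d", 1:n), paste0("v", 1:20)))
  for (j in 1:4) X[, j] <- X[, j] + ifelse(cls == "H", 0.5, -0.5) * 1.2
  ev <- cmv_evaluate(X, cls, paste0("v", 1:4), "discriminant", folds = 8,
                     reps = 3, seed = 64)
  pm <- cmv_permutation(X, cls, paste0("v", 1:4), "discriminant", folds = 8,
                        reps = 3, seed = 64)
  expect_gt(ev$mean, 0.8)
  expect_lt(abs(pm$mean - 0.5), 0.12)
  expect_gt(ev$mean - pm$mean, 0.25)
})

test_that("Q2 behaves as defined: null responses give Q2 at or below zero", {
  set.seed(65)
  n <- 60
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(sprintf("s%02d", 1:n), paste0("v", 1:10)))
  y <- rnorm(n)
  ev <- cmv_evaluate(X, y, paste0("v", 1:10), "regression", folds = 8,
                     reps = 3, seed = 66)
  expect_lte(ev$mean, 0.05)
  # informative regression recovers positive Q2
  y2 <- drop(X[, 1:3] %*% c(1, 1, 1)) + rnorm(n, 0, 0.8)
  ev2 <- cmv_evaluate(X, y2, paste0("v", 1:3), "regression", folds = 8,
                      reps = 3, seed = 66)
  expect_gt(ev2$mean, 0.4)
  pm2 <- cmv_permutation(X, y2, paste0("v", 1:3), "regression", folds = 8,
                         reps = 3, seed = 66)
  expect_lt(pm2$mean, 0.05)
})

test_that("overlap rule returns the sorted intersection", {
  expect_identical(overlap_taxa(c("b", "a", "c"), c("c", "d", "a")),
                   c("a", "c"))
  expect_identical(overlap_taxa(character(0), c("a")), character(0))
})

test_that("input contracts are enforced", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(cmv_select(X, rep(c("A", "B", "C"), length.out = 20),
                          "discriminant"), "two classes")
  expect_error(cmv_select(X, rep(c("A", "B"), c(17, 3)), "discriminant",
                          folds = 8), "at least")
  expect_error(cmv_evaluate(X, rep(c("A", "B"), 10), taxa = "zz",
                            task = "discriminant"))
})
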