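# Internal helpers: seeded evaluation, posterior summaries, fold assignment.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All exported stochastic functions route
# their randomness through this so results are reproducible per call.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic sub-seed derived from a master seed and integer tags, so
# independent stages (fold assignment, sampling, permutation) consume
# independent streams. Kept below 2^31 - 1.
substream_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) h <- (h * 7919 + as.double(t) + 104729) %% 2147483629
  as.integer(h)
}

#' Shortest highest-posterior-density interval
#'
#' Computes the shortest empirical interval containing a fraction `prob` of
#' the draws, by sliding a window over the sorted sample.
#'
#' @param x numeric vector of posterior draws.
#' @param prob coverage probability, default 0.95.
#' @return numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  stopifnot(is.numeric(x), length(x) >= 2, prob > 0, prob < 1)
  x <- sort(x)
  n <- length(x)
  k <- min(n, max(2L, ceiling(prob * n)))
  starts <- seq_len(n - k + 1L)
  widths <- x[starts + k - 1L] - x[starts]
  i <- starts[which.min(widths)]
  c(lower = x[i], upper = x[i + k - 1L])
}

#' Geweke convergence diagnostic
#'
#' Z-score comparing the mean of the first `frac1` of a chain against the
#' mean of the last `frac2`, standardized by spectral-density estimates of
#' the variance at frequency zero (autoregressive estimator).
#'
#' @param x numeric vector of MCMC draws (at least 100).
#' @param frac1 fraction of draws in the early segment (default 0.1).
#' @param frac2 fraction of draws in the late segment (default 0.5).
#' @return a single Z value; `NA` (with a warning) when a segment has zero
#'   variance, where the diagnostic is undefined.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  stopifnot(is.numeric(x), length(x) >= 100, frac1 > 0, frac2 > 0,
            frac1 + frac2 <= 1)
  n <- length(x)
  a <- x[seq_len(max(2L, floor(frac1 * n)))]
  b <- x[seq.int(n - floor(frac2 * n) + 1L, n)]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("Geweke Z undefined: zero variance in a chain segment")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(spectrum0_ar(a) / length(a) +
                             spectrum0_ar(b) / length(b))
}

# Spectral density at frequency zero via an AIC-selected AR fit.
spectrum0_ar <- function(x) {
  x <- x - mean(x)
  ord_max <- min(30L, floor(length(x) / 5))
  fit <- try(stats::ar(x, aic = TRUE, order.max = ord_max), silent = TRUE)
  if (inherits(fit, "try-error") || length(fit$ar) == 0) return(stats::var(x))
  fit$var.pred / (1 - sum(fit$ar))^2
}

# Stratified k-fold assignment keyed to sample ids: the assignment depends
# only on (ids, strata, k, seed), not on the row order of the data, so
# resampling results are invariant to input permutation.
make_folds <- function(ids, strata, k, seed) {
  stopifnot(length(ids) == length(strata), k >= 2)
  ord <- order(as.character(ids))
  fold <- integer(length(ids))
  with_seed(seed, {
    for (s in unique(as.character(strata[ord]))) {
      idx <- ord[as.character(strata[ord]) == s]
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

# Draw from the scaled inverse-chi-square conditional S / chisq(df), bounded
# to (0, upper] by rejection (the flat-prior bound; acceptance ~ 1).
rinvchisq_bounded <- function(S, df, upper) {
  stopifnot(df >= 1, S > 0)
  for (i in 1:1000) {
    v <- S / stats::rchisq(1L, df = df)
    if (v > 0 && v <= upper) return(v)
  }
  upper
}

# Simple order-dependent checksum of a serialized-to-JSON object; used to
# stamp output files with the configuration they came from.
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10))
  b <- utf8ToInt(s)
  sprintf("%08x", as.integer(sum(b * (seq_along(b) %% 97 + 1)) %% 2147483647))
}
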