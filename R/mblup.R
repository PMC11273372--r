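# Microbiability of a host phenotype via a Bayesian microbiome-BLUP
# (MBLUP): y = Xb + m + e with m ~ N(0, K sigma_m^2), e ~ N(0, I sigma_e^2),
# K the microbiome relationship matrix. Variance components are sampled by
# Gibbs under bounded flat priors; microbiability is the per-draw ratio
# sigma_m^2 / (sigma_m^2 + sigma_e^2).

#' Column-standardize an alr matrix
#'
#' Centers and scales every column to mean 0, unit variance (sample SD with
#' divisor n - 1). Fails on zero-variance columns.
#'
#' @param B samples x taxa numeric matrix.
#' @return standardized matrix.
#' @export
standardize_columns <- function(B) {
  B <- as.matrix(B)
  sds <- apply(B, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(B)[sds == 0], collapse = ", "))
  }
  scale(B, center = TRUE, scale = sds)
}

#' Microbiome relationship matrix
#'
#' Computes \eqn{K = \frac{1}{p} B B^T} from an n x p matrix of
#' (standardized) alr-transformed abundances, an analogue of the genomic
#' relationship matrix with taxa in place of markers. K is symmetric and
#' positive semi-definite by construction.
#'
#' @param B n x p matrix (standardize first with [standardize_columns()]).
#' @return n x n relationship matrix.
#' @export
build_relationship <- function(B) {
  B <- as.matrix(B)
  stopifnot(ncol(B) >= 1)
  K <- tcrossprod(B) / ncol(B)
  (K + t(K)) / 2
}

#' Fit the microbiome-BLUP model by Gibbs sampling
#'
#' Samples from the posterior of `y = Xb + m + e`, with flat priors on the
#' fixed effects `b` and bounded flat priors on the variance components
#' (upper bound `1e6 * var(y)`). The microbiome effect `m` is sampled in the
#' eigenbasis of `K`; coordinates with eigenvalue below
#' `1e-10 * max(eigenvalue)` are fixed at 0 (K is singular whenever p < n or
#' B is column-centered). Full conditionals: normal for `b` and the
#' eigen-coordinates of `m`; scaled inverse-chi-square for both variances.
#' Per saved draw the microbiability
#' \eqn{\sigma_m^2 / (\sigma_m^2 + \sigma_e^2)} is recorded. Convergence is
#' checked with the Geweke Z criterion; `|Z| > 3` on any monitored parameter
#' raises a warning (analysis proceeds).
#'
#' @param y phenotype vector (e.g. IMF in g/100 g).
#' @param X fixed-effect incidence matrix (default intercept only). Must
#'   have full column rank.
#' @param K microbiome relationship matrix from [build_relationship()].
#' @param iterations,burnin,thin MCMC protocol; defaults 120000 / 20000 /
#'   10. Saved draws = (iterations - burnin) / thin.
#' @param seed integer seed; the chain is reproducible given the seed.
#' @param fix_sigma optional list `list(m =, e =)` of fixed variance values;
#'   when supplied the variance updates are skipped (used for closed-form
#'   validation against the ridge/GBLUP solution).
#' @param save_m logical; accumulate the posterior mean of `m`.
#' @return an object of class `mblup_chain`: list with `draws` (data.frame
#'   of saved `sigma_m2`, `sigma_e2`, `microbiability` and fixed effects),
#'   `m_mean` (when `save_m`), `geweke` (Z per monitored parameter),
#'   `iterations`, `burnin`, `thin`, `seed`.
#' @export
fit_mblup <- function(y, X = NULL, K, iterations = 120000, burnin = 20000,
                      thin = 10, seed = 1, fix_sigma = NULL, save_m = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(n >= 10, nrow(K) == n, ncol(K) == n,
            iterations > burnin, thin >= 1)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect matrix is rank deficient")

  eg <- eigen(K, symmetric = TRUE)
  keep <- eg$values > 1e-10 * max(eg$values)
  if (sum(keep) < 3) stop("relationship matrix rank < 3; cannot sample variances")
  U <- eg$vectors[, keep, drop = FALSE]
  d <- eg$values[keep]
  k <- length(d)

  XtX <- crossprod(X)
  XtX_inv <- solve(XtX)
  R_b <- chol(XtX_inv)
  vy <- stats::var(y)
  upper <- 1e6 * vy
  fixed_var <- !is.null(fix_sigma)
  if (fixed_var) stopifnot(is.numeric(fix_sigma$m), is.numeric(fix_sigma$e))

  n_save <- (iterations - burnin) %/% thin
  stopifnot(n_save >= 1)
  draws <- matrix(NA_real_, n_save, 3 + ncol(X))
  colnames(draws) <- c("sigma_m2", "sigma_e2", "microbiability",
                       paste0("b_", seq_len(ncol(X))))
  m_sum <- numeric(n)

  with_seed(seed, {
    sm2 <- if (fixed_var) fix_sigma$m else vy / 2
    se2 <- if (fixed_var) fix_sigma$e else vy / 2
    alpha <- numeric(k)
    m <- numeric(n)
    s_idx <- 0L
    for (it in seq_len(iterations)) {
      # b | m, se2  (flat prior)
      bhat <- XtX_inv %*% crossprod(X, y - m)
      b <- drop(bhat + sqrt(se2) * (t(R_b) %*% stats::rnorm(ncol(X))))
      resid_f <- y - drop(X %*% b)
      # alpha | b, variances: eigenbasis coordinates of m
      r <- drop(crossprod(U, resid_f))
      v_post <- 1 / (1 / se2 + 1 / (d * sm2))
      alpha <- stats::rnorm(k, v_post * r / se2, sqrt(v_post))
      m <- drop(U %*% alpha)
      if (!fixed_var) {
        # sigma_m2 | alpha : scaled inv-chi-square, bounded flat prior
        sm2 <- rinvchisq_bounded(sum(alpha^2 / d), k - 2, upper)
        # sigma_e2 | b, m
        se2 <- rinvchisq_bounded(sum((resid_f - m)^2), n - 2, upper)
      }
      if (it > burnin && (it - burnin) %% thin == 0) {
        s_idx <- s_idx + 1L
        draws[s_idx, ] <- c(sm2, se2, sm2 / (sm2 + se2), b)
        if (save_m) m_sum <- m_sum + m
      }
    }
  })

  draws <- as.data.frame(draws)
  gw <- vapply(draws[, c("sigma_m2", "sigma_e2", "microbiability")],
               function(col) {
                 if (length(col) >= 100 && stats::var(col) > 0) {
                   suppressWarnings(geweke_z(col))
                 } else NA_real_
               }, numeric(1))
  if (any(abs(gw) > 3, na.rm = TRUE)) {
    warning("Geweke |Z| > 3 for: ",
            paste(names(gw)[abs(gw) > 3 & !is.na(gw)], collapse = ", "),
            " - chain may not have converged")
  }
  structure(list(draws = draws,
                 m_mean = if (save_m) m_sum / n_save else NULL,
                 geweke = gw, iterations = iterations, burnin = burnin,
                 thin = thin, seed = seed),
            class = "mblup_chain")
}

#' Summarize a microbiability posterior
#'
#' Posterior median, shortest 95% highest-posterior-density interval, and
#' the posterior probability that microbiability exceeds `threshold`.
#'
#' @param chain an `mblup_chain` object (or a numeric vector of
#'   microbiability draws).
#' @param threshold exceedance threshold, default 0.25.
#' @param prob HPD coverage, default 0.95.
#' @return list with `median`, `hpd` (lower, upper), `p_gt_threshold`,
#'   `threshold`, `n_draws`.
#' @export
summarize_chain <- function(chain, threshold = 0.25, prob = 0.95) {
  x <- if (inherits(chain, "mblup_chain")) chain$draws$microbiability
       else as.numeric(chain)
  stopifnot(length(x) >= 500)
  list(median = stats::median(x), hpd = hpd_interval(x, prob),
       p_gt_threshold = mean(x > threshold), threshold = threshold,
       n_draws = length(x))
}

#' @export
print.mblup_chain <- function(x, ...) {
  cat("MBLUP posterior chain:", nrow(x$draws), "saved draws",
      sprintf("(%d iterations, %d burn-in, thin %d)\n",
              x$iterations, x$burnin, x$thin))
  s <- summarize_chain(x)
  cat(sprintf("  microbiability median %.3f, HPD95%% [%.3f, %.3f], P(>%.2f) = %.2f\n",
              s$median, s$hpd[1], s$hpd[2], s$threshold, s$p_gt_threshold))
  cat("  Geweke Z:", paste(sprintf("%s=%.2f", names(x$geweke), x$geweke),
                           collapse = ", "), "\n")
  invisible(x)
}
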