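# Per-taxon Bayesian effect sizes: the correlated response of each selected
# taxon is quantified as the posterior H - L line difference of its
# alr-transformed abundance, expressed in residual-SD units, with HPD95%
# and the posterior sign probability P0.

#' Gibbs sampler for one taxon's line/sex linear model
#'
#' Fits `x = intercept + line + sex + e` with flat priors by Gibbs sampling:
#' the coefficient vector from its conditional multivariate normal, the
#' residual variance from its scaled inverse-chi-square conditional. The
#' per-draw line difference is the H-minus-L contrast.
#'
#' @param x per-sample alr-transformed abundance of one taxon.
#' @param line per-sample line labels (exactly two levels; the difference
#'   reported is `sorted level 1 - sorted level 2`, i.e. H - L for labels
#'   H/L).
#' @param sex per-sample sex labels (two levels, both present in each line;
#'   a line entirely of one sex is a confounded design and is rejected).
#' @param iterations,burnin,thin MCMC protocol; defaults 60000 / 10000 / 10.
#' @param seed integer seed (chain reproducible given seed).
#' @return list with `diff` (line-difference draws), `sigma` (residual SD
#'   draws), `geweke` (Z for the difference), `n_draws`.
#' @export
fit_taxon_model <- function(x, line, sex, iterations = 60000,
                            burnin = 10000, thin = 10, seed = 1) {
  x <- as.numeric(x)
  line <- as.character(line); sex <- as.character(sex)
  n <- length(x)
  stopifnot(length(line) == n, length(sex) == n, iterations > burnin)
  lev_l <- sort(unique(line)); lev_s <- sort(unique(sex))
  if (length(lev_l) != 2 || length(lev_s) != 2) {
    stop("need two lines and two sexes")
  }
  if (any(table(line, sex) == 0)) {
    stop("confounded design: a line is entirely one sex")
  }
  X <- cbind(intercept = 1,
             line = as.numeric(line == lev_l[1]),
             sex = as.numeric(sex == lev_s[1]))
  XtX <- crossprod(X)
  XtX_inv <- solve(XtX)
  R <- chol(XtX_inv)
  bhat <- drop(XtX_inv %*% crossprod(X, x))
  n_save <- (iterations - burnin) %/% thin
  diff_d <- sig_d <- numeric(n_save)
  with_seed(seed, {
    s2 <- stats::var(x)
    if (s2 == 0) stop("taxon has zero variance")
    idx <- 0L
    for (it in seq_len(iterations)) {
      beta <- bhat + sqrt(s2) * drop(t(R) %*% stats::rnorm(3))
      rss <- sum((x - drop(X %*% beta))^2)
      s2 <- rss / stats::rchisq(1L, df = n - 2)
      if (it > burnin && (it - burnin) %% thin == 0) {
        idx <- idx + 1L
        diff_d[idx] <- beta[2]     # coefficient of the first sorted line
        sig_d[idx] <- sqrt(s2)
      }
    }
  })
  gz <- if (n_save >= 100) suppressWarnings(geweke_z(diff_d)) else NA_real_
  list(diff = diff_d, sigma = sig_d, geweke = gz, n_draws = n_save)
}

#' Standardize a line-difference posterior to residual-SD units
#'
#' Divides the difference draws by the posterior median residual SD, then
#' summarizes the scaled draws: posterior mean, shortest HPD95%, and
#' \eqn{P_0}, the posterior probability that the difference has the sign of
#' its mean (in `[0.5, 1]`).
#'
#' @param diff_draws posterior draws of the line difference.
#' @param sigma_draws posterior draws of the residual SD (same length).
#' @return list with `mean`, `hpd` (lower, upper), `p0`, `residual_sd` (the
#'   median used for scaling), `draws` (the scaled draws).
#' @export
standardize_effect <- function(diff_draws, sigma_draws) {
  stopifnot(length(diff_draws) == length(sigma_draws),
            length(diff_draws) >= 500)
  s <- stats::median(sigma_draws)
  if (s < 1e-12) stop("residual SD is (numerically) zero; cannot standardize")
  d <- diff_draws / s
  m <- mean(d)
  p0 <- if (m >= 0) mean(d > 0) else mean(d < 0)
  list(mean = m, hpd = hpd_interval(d, 0.95), p0 = max(p0, 1 - p0),
       residual_sd = s, draws = d)
}

#' Effect-size table for a set of selected taxa
#'
#' Runs [fit_taxon_model()] and [standardize_effect()] for each taxon
#' (typically the PLS-DA/PLS overlap set) and returns one row per taxon.
#'
#' @param alr samples x taxa alr matrix.
#' @param line,sex per-sample labels.
#' @param taxa taxa to analyze (default: all columns).
#' @param iterations,burnin,thin MCMC protocol per taxon.
#' @param seed master seed; each taxon gets its own derived stream.
#' @return data.frame: `taxon`, `mean` (SD units), `hpd_lower`, `hpd_upper`,
#'   `p0`, `residual_sd`, `geweke_z`.
#' @export
taxon_effects <- function(alr, line, sex, taxa = colnames(alr),
                          iterations = 60000, burnin = 10000, thin = 10,
                          seed = 1) {
  alr <- as.matrix(alr)
  stopifnot(all(taxa %in% colnames(alr)))
  rows <- lapply(seq_along(taxa), function(i) {
    fit <- fit_taxon_model(alr[, taxa[i]], line, sex, iterations, burnin,
                           thin, seed = substream_seed(seed, 37L, i))
    s <- standardize_effect(fit$diff, fit$sigma)
    data.frame(taxon = taxa[i], mean = s$mean, hpd_lower = s$hpd[1],
               hpd_upper = s$hpd[2], p0 = s$p0, residual_sd = s$residual_sd,
               geweke_z = fit$geweke, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
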