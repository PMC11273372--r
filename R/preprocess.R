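# Compositional preprocessing: prevalence filtering, Bayesian-multiplicative
# zero imputation, alr transformation with data-driven reference selection,
# and sequencer-batch correction.

#' Prevalence filter on a count table
#'
#' Retains exactly the taxa whose fraction of zero-count samples is at most
#' `max_undetected_frac` (default: undetected in more than 10% of samples is
#' discarded). Column order is preserved.
#'
#' @param counts samples x taxa non-negative integer matrix.
#' @param max_undetected_frac maximum tolerated fraction of samples in which
#'   a taxon is undetected.
#' @return the filtered count matrix.
#' @export
filter_prevalence <- function(counts, max_undetected_frac = 0.10) {
  counts <- validate_counts(counts)
  zf <- colMeans(counts == 0)
  keep <- zf <= max_undetected_frac + 1e-12
  if (!any(keep)) stop("prevalence filter removed every taxon")
  counts[, keep, drop = FALSE]
}

#' Bayesian-multiplicative zero imputation
#'
#' Replaces zero counts by small positive proportions and closes each sample
#' to 1. For sample i with total \eqn{n_i}, prior strength \eqn{s} and prior
#' proportions \eqn{t_j}, a zero cell receives
#' \eqn{\pi_{ij} = s t_j / (n_i + s)} and each non-zero cell receives
#' \eqn{(c_{ij}/n_i)(1 - \sum_{k \in zeros} \pi_{ik})}, the multiplicative
#' adjustment that preserves the observed ratios between detected taxa.
#'
#' @param counts filtered samples x taxa count matrix; every sample must
#'   have at least one positive entry.
#' @param prior_strength total prior mass \eqn{s}; default `0.5 * p`
#'   (a Jeffreys-like uniform prior of 1/2 per taxon).
#' @param prior `"uniform"` for \eqn{t_j = 1/p}, or `"frequency"` to use the
#'   overall taxon proportions of the table.
#' @return samples x taxa matrix of strictly positive proportions, rows
#'   summing to 1 (a composition).
#' @export
impute_zeros <- function(counts, prior_strength = NULL,
                         prior = c("uniform", "frequency")) {
  counts <- validate_counts(counts)
  prior <- match.arg(prior)
  p <- ncol(counts)
  if (is.null(prior_strength)) prior_strength <- 0.5 * p
  stopifnot(prior_strength > 0)
  ni <- rowSums(counts)
  if (any(ni == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(rownames(counts)[ni == 0], collapse = ", "))
  }
  tj <- if (prior == "uniform") rep(1 / p, p) else colSums(counts) / sum(counts)
  comp <- counts / ni
  zero <- counts == 0
  repl <- outer(prior_strength / (ni + prior_strength), tj)
  zmass <- rowSums(repl * zero)
  comp <- comp * (1 - zmass)   # multiplicative shrink of observed taxa
  comp[zero] <- repl[zero]
  comp / rowSums(comp)
}

#' Additive log-ratio transformation
#'
#' Maps a strictly positive composition to `p - 1` real coordinates
#' \eqn{x_j = \ln(\rho_j / \rho_{ref})}. The reference taxon identity is kept
#' as the `"reference"` attribute of the result.
#'
#' @param comp samples x taxa composition (strictly positive rows summing
#'   to 1; any positive rescaling gives the same result).
#' @param reference taxon label (or column index) used as denominator.
#' @return samples x (p-1) matrix with attribute `reference`.
#' @export
alr_transform <- function(comp, reference) {
  comp <- validate_composition(comp, closed = FALSE)
  ref <- resolve_taxon(reference, colnames(comp))
  X <- log(comp[, -ref, drop = FALSE] / comp[, ref])
  attr(X, "reference") <- colnames(comp)[ref]
  X
}

#' Invert an additive log-ratio matrix back to a composition
#'
#' Appends a zero coordinate for the reference taxon and softmax-normalizes
#' each row; `alr_inverse(alr_transform(comp, ref))` recovers `comp`.
#'
#' @param X alr matrix carrying a `reference` attribute (or with `reference`
#'   supplied).
#' @param reference reference taxon label; defaults to the attribute.
#' @return composition matrix with the reference column restored.
#' @export
alr_inverse <- function(X, reference = attr(X, "reference")) {
  stopifnot(!is.null(reference))
  E <- cbind(exp(X), 1)
  colnames(E) <- c(colnames(X), reference)
  E / rowSums(E)
}

#' Procrustes correlation between two configurations
#'
#' Trace-norm Procrustes correlation: after column-centering both
#' configurations, the sum of singular values of \eqn{X^T Y} divided by
#' \eqn{\sqrt{\mathrm{tr}(X^T X)\,\mathrm{tr}(Y^T Y)}}. Equals 1 when one
#' configuration is a rotation/translation/uniform scaling of the other.
#'
#' @param X,Y numeric matrices with equal row counts.
#' @return a correlation in `[0, 1]`.
#' @export
procrustes_correlation <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 3)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sx <- sum(Xc^2); sy <- sum(Yc^2)
  if (sx <= 0 || sy <= 0) stop("zero-variance configuration")
  min(1, sum(svd(crossprod(Xc, Yc), nu = 0, nv = 0)$d) / sqrt(sx * sy))
}

#' Select an alr reference taxon by low variance and geometry preservation
#'
#' For every candidate taxon, computes (a) the variance of its
#' log-abundance across samples and (b) the Procrustes correlation between
#' the alr configuration using that candidate as denominator and the exact
#' pairwise-logratio geometry (represented by the clr configuration, whose
#' inter-sample distances equal the pairwise-logratio distances up to the
#' constant \eqn{\sqrt{p}}). The chosen reference is the candidate with the
#' smallest log-variance among those whose Procrustes correlation is within
#' `tolerance` of the maximum, so the reference distorts the sample geometry
#' as little as possible while contributing minimal variance of its own to
#' the log-ratios.
#'
#' @param comp strictly positive composition, `p >= 3` taxa.
#' @param tolerance slack below the maximum Procrustes correlation within
#'   which candidates compete on variance (default 0.005).
#' @return a list with `diagnostics` (data.frame: taxon, log_variance,
#'   procrustes_r) and `reference` (the chosen taxon label).
#' @export
select_alr_reference <- function(comp, tolerance = 0.005) {
  comp <- validate_composition(comp, closed = FALSE)
  p <- ncol(comp)
  stopifnot(p >= 3)
  logm <- log(comp)
  clr <- logm - rowMeans(logm)
  lv <- apply(logm, 2, stats::var)
  pr <- vapply(seq_len(p), function(j) {
    procrustes_correlation(logm[, -j, drop = FALSE] - logm[, j], clr)
  }, numeric(1))
  ok <- pr >= max(pr) - tolerance
  chosen <- which(ok)[which.min(lv[ok])]
  list(diagnostics = data.frame(taxon = colnames(comp), log_variance = lv,
                                procrustes_r = pr, row.names = NULL),
       reference = colnames(comp)[chosen])
}

#' Remove a sequencer-batch effect from alr coordinates
#'
#' Fits, per taxon coordinate, the one-way model `x = batch mean + residual`
#' and returns the residuals, so that the batch means of every column are 0
#' afterwards while within-batch deviations are preserved.
#'
#' @param X samples x coordinates matrix (e.g. an alr matrix).
#' @param batch per-sample batch labels; at least two batches with at least
#'   two samples each.
#' @return the corrected matrix (attributes preserved).
#' @export
correct_batch <- function(X, batch) {
  X <- as.matrix(X)
  batch <- as.character(batch)
  stopifnot(nrow(X) == length(batch))
  tb <- table(batch)
  if (length(tb) < 2) stop("batch correction needs at least two batches")
  if (any(tb < 2)) {
    stop("singleton batch(es): ", paste(names(tb)[tb < 2], collapse = ", "))
  }
  gm <- rowsum(X, batch) / as.vector(tb)
  out <- X - gm[batch, , drop = FALSE]
  dimnames(out) <- dimnames(X)
  attr(out, "reference") <- attr(X, "reference")
  out
}

#' PCA scores for a batch-effect diagnostic
#'
#' Centered principal component scores (first two components) of an alr
#' matrix, used to check visually or numerically whether samples separate by
#' sequencer batch before correction and mix after it.
#'
#' @param X samples x coordinates matrix, `n >= 3`.
#' @return data.frame with `PC1`, `PC2` scores (sample ids as row names) and
#'   attribute `sdev` (all component standard deviations, non-increasing).
#' @export
pca_batch_diagnostic <- function(X) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 3)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  out <- as.data.frame(pc$x[, 1:2, drop = FALSE])
  colnames(out) <- c("PC1", "PC2")
  attr(out, "sdev") <- pc$sdev
  out
}

# Share of variance of a score vector explained by between-batch differences.
between_batch_share <- function(scores, batch) {
  gm <- tapply(scores, batch, mean)
  n <- tapply(scores, batch, length)
  ss_b <- sum(n * (gm - mean(scores))^2)
  ss_t <- sum((scores - mean(scores))^2)
  if (ss_t == 0) return(0)
  ss_b / ss_t
}

# ---- input validation helpers -------------------------------------------

validate_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("t%03d", seq_len(ncol(counts)))
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be finite non-negative integers")
  }
  counts
}

validate_composition <- function(comp, closed = TRUE) {
  comp <- as.matrix(comp)
  if (any(!is.finite(comp)) || any(comp <= 0)) {
    stop("composition must be strictly positive and finite")
  }
  if (closed && any(abs(rowSums(comp) - 1) > 1e-9)) {
    stop("composition rows must sum to 1")
  }
  comp
}

resolve_taxon <- function(taxon, labels) {
  if (is.numeric(taxon)) {
    ref <- as.integer(taxon)
    if (ref < 1 || ref > length(labels)) stop("reference index out of range")
    return(ref)
  }
  ref <- match(taxon, labels)
  if (is.na(ref)) stop("reference taxon not found: ", taxon)
  ref
}
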