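# Compositional balance biomarker: greedy forward search for the smallest
# log-contrast (isometric log-ratio between two disjoint taxon sets) that
# classifies the lines, evaluated by cross-validated logit regression.

#' Balance (isometric log-contrast) scores
#'
#' For disjoint non-empty taxon sets of sizes \eqn{k_1} (numerator) and
#' \eqn{k_2} (denominator), the per-sample score is
#' \deqn{\sqrt{k_1 k_2 / (k_1 + k_2)}\,(\overline{\ln x}_{num} -
#'   \overline{\ln x}_{den})}
#' the normalized difference of mean log-abundances (equivalently, the log
#' of the ratio of geometric means). Scores are invariant to any positive
#' rescaling of the composition and are negated when the sets are swapped.
#'
#' @param comp strictly positive samples x taxa relative-abundance matrix.
#' @param num,den disjoint non-empty character vectors of taxon labels.
#' @return per-sample numeric score vector.
#' @export
balance_value <- function(comp, num, den) {
  comp <- validate_composition(comp, closed = FALSE)
  stopifnot(length(num) >= 1, length(den) >= 1)
  if (length(intersect(num, den)) > 0) {
    stop("numerator and denominator sets overlap")
  }
  miss <- setdiff(c(num, den), colnames(comp))
  if (length(miss)) stop("taxa not in composition: ", paste(miss, collapse = ", "))
  k1 <- length(num); k2 <- length(den)
  lg <- log(comp)
  sqrt(k1 * k2 / (k1 + k2)) *
    (rowMeans(lg[, num, drop = FALSE]) - rowMeans(lg[, den, drop = FALSE]))
}

#' Cross-validated logit classification accuracy of a score
#'
#' Stratified `kfold`-fold cross-validation repeated `reps` times: a
#' maximum-likelihood logistic regression of the class on the score is fit
#' on each training part and the held-out samples are classified at
#' probability 0.5. Complete separation (divergent coefficients) is handled
#' by the bounded iteration count of the fitter and flagged.
#'
#' @param scores per-sample balance scores.
#' @param line per-sample two-level class labels.
#' @param kfold,reps cross-validation design (defaults 8 and 20).
#' @param seed fold-assignment seed (keyed to sample ids when `scores` is
#'   named).
#' @return list with `mean`, `sd`, `per_fold` (length `kfold * reps`), and
#'   `separation` flag.
#' @export
logit_cv_accuracy <- function(scores, line, kfold = 8, reps = 20, seed = 1) {
  scores <- drop(scores)
  line <- as.character(line)
  n <- length(scores)
  stopifnot(length(line) == n)
  if (stats::var(scores) == 0) stop("constant scores: logit fit undefined")
  lev <- sort(unique(line))
  if (length(lev) != 2) stop("need exactly two classes")
  if (any(table(line) < kfold)) {
    stop("each class needs at least `kfold` members")
  }
  ids <- if (!is.null(names(scores))) names(scores) else sprintf("r%04d", 1:n)
  ycls <- as.numeric(line == lev[2])
  acc <- numeric(kfold * reps)
  sep <- FALSE
  i <- 0L
  for (r in seq_len(reps)) {
    fold <- make_folds(ids, line, kfold, substream_seed(seed, 41L, r))
    for (f in seq_len(kfold)) {
      i <- i + 1L
      te <- fold == f
      fit <- fit_logit(scores[!te], ycls[!te])
      sep <- sep || fit$separation
      p <- stats::plogis(fit$coef[1] + fit$coef[2] * scores[te])
      acc[i] <- mean((p > 0.5) == (ycls[te] == 1))
    }
  }
  list(mean = mean(acc), sd = stats::sd(acc), per_fold = acc,
       separation = sep)
}

# Maximum-likelihood logistic regression of a 0/1 class on one score
# (intercept + slope), by iteratively reweighted least squares with a
# bounded step count so complete separation yields large finite
# coefficients, flagged. Lean 2 x 2 solve: the search evaluates many
# thousands of candidate balances.
fit_logit <- function(s, y01) {
  b0 <- 0; b1 <- 0
  sep <- FALSE
  for (it in 1:30) {
    eta <- pmin(30, pmax(-30, b0 + b1 * s))
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y01 - p) / w
    sw <- sum(w); sws <- sum(w * s); swss <- sum(w * s * s)
    det <- sw * swss - sws^2
    if (det < 1e-12) { sep <- TRUE; break }
    swz <- sum(w * z); swsz <- sum(w * s * z)
    nb0 <- (swss * swz - sws * swsz) / det
    nb1 <- (sw * swsz - sws * swz) / det
    if (!is.finite(nb0) || !is.finite(nb1)) { sep <- TRUE; break }
    done <- max(abs(nb0 - b0), abs(nb1 - b1)) < 1e-8
    b0 <- nb0; b1 <- nb1
    if (done) break
    if (it == 30) sep <- TRUE
  }
  if (abs(b1) > 1e3 || abs(b0) > 1e3) sep <- TRUE
  list(coef = c(b0, b1), separation = sep)
}

#' Greedy search for a discriminating microbial balance
#'
#' A selbal-style forward search over a candidate set of taxa: every
#' unordered taxon pair is first evaluated as a 1-vs-1 balance by
#' cross-validated logit classification error; starting from the best pair,
#' the single taxon (added to either the numerator or the denominator) that
#' most reduces the cross-validated error is added iteratively. The search
#' stops when no addition strictly improves the error or when `max_taxa` is
#' reached, so the returned balance is the smallest attaining the minimum
#' cross-validated error. The final balance is then re-evaluated with a
#' fresh `kfold x reps` cross-validation ([logit_cv_accuracy()]).
#'
#' @param comp strictly positive relative abundances restricted to the
#'   candidate taxa (at least 2 columns), e.g. the PLS-DA/PLS overlap set.
#' @param line per-sample two-level labels; each class needs at least
#'   `kfold` members.
#' @param kfold,reps outer cross-validation design for the accuracy
#'   estimate (defaults 8 and 20; `kfold * reps` outer folds, each with its
#'   own training-only search).
#' @param max_taxa optional cap on the total number of taxa in the balance.
#' @param search_reps repetitions of the k-fold partition used inside each
#'   search (default 1; the search error surface is evaluated on a fixed
#'   partition so candidate comparisons are paired).
#' @param seed master seed.
#' @return list of class `biomarker_result`: `num`, `den` (taxon sets of
#'   the full-data balance, numerator oriented toward the second sorted
#'   class), `scores`, `accuracy_mean`, `accuracy_sd`, `per_fold`,
#'   `cv_error_path` (search error after each accepted addition),
#'   `separation` flag.
#' @details The reported classification accuracy is a nested
#'   cross-validation estimate: within each of the `kfold * reps` outer
#'   folds the greedy search is re-run on the training part only, a logit
#'   model is fit to the training scores of the balance found there, and
#'   the held-out samples are classified. This keeps the accuracy free of
#'   selection bias — on uninformative candidates it stays at chance level.
#' @export
selbal_search <- function(comp, line, kfold = 8, reps = 20, max_taxa = NULL,
                          search_reps = 1, seed = 1) {
  comp <- validate_composition(comp, closed = FALSE)
  line <- as.character(line)
  stopifnot(ncol(comp) >= 2, nrow(comp) == length(line))
  lev <- sort(unique(line))
  if (length(lev) != 2) stop("need exactly two classes")
  if (any(table(line) < kfold)) {
    stop("each class needs at least `kfold` members")
  }
  if (is.null(max_taxa)) max_taxa <- ncol(comp)
  stopifnot(max_taxa >= 2)
  lg <- log(comp)
  ycls <- as.numeric(line == lev[2])
  ids <- rownames(comp)
  if (is.null(ids)) ids <- rownames(lg) <- sprintf("r%04d", seq_len(nrow(comp)))

  # full-data search: the reported biomarker
  full <- greedy_balance(lg, ycls, line, ids, kfold, search_reps, max_taxa,
                         substream_seed(seed, 43L))
  num <- full$num; den <- full$den

  # nested CV accuracy: re-run the search inside every outer training fold
  acc <- numeric(kfold * reps)
  sep <- FALSE
  i <- 0L
  for (r in seq_len(reps)) {
    fold <- make_folds(ids, line, kfold, substream_seed(seed, 47L, r))
    for (f in seq_len(kfold)) {
      i <- i + 1L
      te <- fold == f
      sub <- greedy_balance(lg[!te, , drop = FALSE], ycls[!te], line[!te],
                            ids[!te], kfold, search_reps, max_taxa,
                            substream_seed(seed, 53L, r, f))
      sc_tr <- balance_score_log(lg[!te, , drop = FALSE], sub$num, sub$den)
      fit <- fit_logit(sc_tr, ycls[!te])
      sep <- sep || fit$separation
      sc_te <- balance_score_log(lg[te, , drop = FALSE], sub$num, sub$den)
      p <- stats::plogis(fit$coef[1] + fit$coef[2] * sc_te)
      acc[i] <- mean((p > 0.5) == (ycls[te] == 1))
    }
  }

  # orient the balance so its logit slope for the second sorted class is
  # positive (numerator elevated in that class)
  sc <- balance_score_log(lg, num, den)
  full_fit <- fit_logit(sc, ycls)
  if (is.finite(full_fit$coef[2]) && full_fit$coef[2] < 0) {
    tmp <- num; num <- den; den <- tmp
    sc <- -sc
  }
  names(sc) <- ids
  structure(list(num = sort(num), den = sort(den), scores = sc,
                 accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
                 per_fold = acc, cv_error_path = full$path,
                 separation = sep || full_fit$separation),
            class = "biomarker_result")
}

# Balance score from a log-abundance matrix (no validation; search inner
# loop).
balance_score_log <- function(lg, num, den) {
  k1 <- length(num); k2 <- length(den)
  sqrt(k1 * k2 / (k1 + k2)) *
    (rowMeans(lg[, num, drop = FALSE]) - rowMeans(lg[, den, drop = FALSE]))
}

# Greedy forward balance search on one data set: best 1-vs-1 pair by CV
# logit error, then additions to either side while the error strictly
# decreases (ties keep the smaller balance).
greedy_balance <- function(lg, ycls, strata, ids, kfold, search_reps,
                           max_taxa, seed) {
  taxa <- sort(colnames(lg))   # candidate order fixed: results do not
                               # depend on input column order
  folds <- lapply(seq_len(search_reps), function(r) {
    make_folds(ids, strata, kfold, substream_seed(seed, r))
  })
  cv_err <- function(num, den) {
    sc <- balance_score_log(lg, num, den)
    err <- 0
    for (fold in folds) {
      for (f in seq_len(kfold)) {
        te <- fold == f
        fit <- fit_logit(sc[!te], ycls[!te])
        p <- stats::plogis(fit$coef[1] + fit$coef[2] * sc[te])
        err <- err + sum((p > 0.5) != (ycls[te] == 1))
      }
    }
    err / (length(folds) * length(ycls))
  }
  pairs <- utils::combn(taxa, 2)
  pair_err <- apply(pairs, 2, function(pr) cv_err(pr[1], pr[2]))
  best <- which.min(pair_err)
  num <- pairs[1, best]; den <- pairs[2, best]
  err <- pair_err[best]
  path <- err
  while (length(num) + length(den) < max_taxa) {
    remaining <- setdiff(taxa, c(num, den))
    if (length(remaining) == 0) break
    cand <- expand.grid(taxon = remaining, side = c("num", "den"),
                        stringsAsFactors = FALSE)
    errs <- vapply(seq_len(nrow(cand)), function(i) {
      if (cand$side[i] == "num") cv_err(c(num, cand$taxon[i]), den)
      else cv_err(num, c(den, cand$taxon[i]))
    }, numeric(1))
    j <- which.min(errs)
    if (errs[j] >= err - 1e-12) break   # parsimony: ties keep the smaller balance
    if (cand$side[j] == "num") num <- c(num, cand$taxon[j])
    else den <- c(den, cand$taxon[j])
    err <- errs[j]
    path <- c(path, err)
  }
  list(num = num, den = den, path = path)
}

#' @export
print.biomarker_result <- function(x, ...) {
  cat("Microbial balance biomarker:\n")
  cat("  numerator  :", paste(x$num, collapse = ", "), "\n")
  cat("  denominator:", paste(x$den, collapse = ", "), "\n")
  cat(sprintf("  CV accuracy: %.3f (SD %.3f) over %d folds\n",
              x$accuracy_mean, x$accuracy_sd, length(x$per_fold)))
  invisible(x)
}
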