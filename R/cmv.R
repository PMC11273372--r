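# Two-step cross-model validation (CMV) for PLS-DA / PLS taxon selection:
# an outer resampling loop (folds x reps models) around an inner 8-fold CV
# that picks the component count and the VIP cutoff, with jackknife
# confidence intervals on the regression coefficients. Selection and
# performance estimation never share data.

# Regression coefficients of a fitted pls_model truncated to its first a
# components (NIPALS components are nested).
coef_for_components <- function(model, a) {
  W <- model$W[, seq_len(a), drop = FALSE]
  P <- model$P[, seq_len(a), drop = FALSE]
  drop(W %*% solve(crossprod(P, W), model$c_load[seq_len(a)]))
}

# Predictions (original y scale) for every component count 1..model$A.
predict_all_components <- function(model, newdata) {
  newdata <- as.matrix(newdata)[, model$var_names, drop = FALSE]
  Xs <- scale(newdata, model$x_center, model$x_scale)
  out <- vapply(seq_len(model$A), function(a) {
    model$y_center + drop(Xs %*% coef_for_components(model, a)) * model$y_scale
  }, numeric(nrow(newdata)))
  matrix(out, nrow = nrow(newdata), ncol = model$A)
}

# Inner cross-validation over component counts. Returns per-A performance
# (classification accuracy or Q^2), the per-fold fitted models (at the
# maximum component count; nested truncation gives all smaller A), and the
# chosen A: the smallest component count whose pooled performance is within
# one standard error (across folds) of the best, the usual guard against
# overfitting a flat inner-CV profile; exact ties also resolve to the
# smaller A.
cv_components <- function(X, y, task, fold, a_max) {
  n <- nrow(X)
  y_num <- if (task == "discriminant") {
    lev <- sort(unique(as.character(y)))
    as.numeric(as.character(y) == lev[2])
  } else as.numeric(y)
  ks <- sort(unique(fold))
  a_cap <- min(a_max, ncol(X))
  preds <- matrix(NA_real_, n, a_cap)
  tss <- numeric(n)
  models <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    te <- fold == ks[i]
    a_fold <- min(a_cap, sum(!te) - 1L)
    fit <- fit_pls(X[!te, , drop = FALSE], y[!te], a_fold)
    models[[i]] <- fit
    pr <- predict_all_components(fit, X[te, , drop = FALSE])
    pr <- as.matrix(pr)
    preds[te, seq_len(fit$A)] <- pr
    if (fit$A < a_cap) {    # pad with the largest available component count
      preds[te, seq.int(fit$A + 1L, a_cap)] <- pr[, fit$A]
    }
    tss[te] <- (y_num[te] - mean(y_num[!te]))^2
  }
  perf <- vapply(seq_len(a_cap), function(a) {
    if (task == "discriminant") {
      mean((preds[, a] > 0.5) == (y_num == 1))
    } else {
      1 - sum((y_num - preds[, a])^2) / sum(tss)
    }
  }, numeric(1))
  # per-fold performance of the best A gives the SE for the one-SE rule
  a_best <- which.max(perf)
  fold_perf <- vapply(ks, function(k) {
    te <- fold == k
    if (task == "discriminant") {
      mean((preds[te, a_best] > 0.5) == (y_num[te] == 1))
    } else {
      1 - sum((y_num[te] - preds[te, a_best])^2) / sum(tss[te])
    }
  }, numeric(1))
  se <- stats::sd(fold_perf) / sqrt(length(ks))
  if (!is.finite(se)) se <- 0
  best_a <- which(perf >= perf[a_best] - se)[1]
  list(perf = perf, best_a = best_a, models = models, folds = ks,
       fold = fold)
}

# One CMV step-1 training model: choose A by inner CV, compute VIP on the
# full training fit, jackknife 95% CIs of the coefficients across the inner
# folds, then pick the VIP cutoff (grid) that maximizes inner-CV
# performance of the restricted model. Returns the selected taxon names.
cmv_fit_one <- function(X, y, task, inner_k, vip_grid, a_max, strata, seed) {
  ids <- rownames(X)
  fold <- make_folds(ids, strata, inner_k, seed)
  cv <- cv_components(X, y, task, fold, a_max)
  A <- cv$best_a
  full <- fit_pls(X, y, A)
  vip <- vip_scores(full)
  if (all(is.na(vip))) return(character(0))
  # jackknife CI across the inner-fold coefficient vectors at A components
  cf <- sapply(cv$models, function(m) coef_for_components(m, min(A, m$A)))
  g <- ncol(cf)
  cbar <- rowMeans(cf)
  se <- sqrt((g - 1) / g * rowSums((cf - cbar)^2))
  tq <- stats::qt(0.975, g - 1)
  eligible <- (cbar - tq * se > 0) | (cbar + tq * se < 0)
  names(eligible) <- colnames(X)
  if (!any(eligible)) return(character(0))
  # VIP cutoff by inner-CV performance of the restricted model
  sets <- lapply(vip_grid, function(cut) names(which(eligible & vip >= cut)))
  keys <- vapply(sets, paste, character(1), collapse = "|")
  best_perf <- -Inf; best_idx <- 0L
  perf_cache <- list()
  for (i in seq_along(sets)) {
    vars <- sets[[i]]
    if (length(vars) == 0) next
    key <- keys[i]
    if (is.null(perf_cache[[key]])) {
      sub <- cv_components(X[, vars, drop = FALSE], y, task, fold,
                           min(A, length(vars)))
      perf_cache[[key]] <- max(sub$perf)
    }
    pf <- perf_cache[[key]]
    if (pf >= best_perf - 1e-12) {  # ties resolved toward the larger cutoff
      best_perf <- max(pf, best_perf); best_idx <- i
    }
  }
  if (best_idx == 0L) return(character(0))
  sets[[best_idx]]
}

#' CMV step 1: cross-model-validated taxon selection
#'
#' Runs `reps` replicates of stratified `folds`-fold resampling (default
#' 8 x 20 = 160 training models). In each model, the component count is
#' chosen by an inner 8-fold CV, a taxon is selected iff the jackknife 95%
#' confidence interval of its regression coefficient (across the inner
#' folds) excludes 0 AND its VIP reaches the cutoff (grid over
#' `[0.8, 1.1]`) that maximizes inner-CV performance. The final set
#' contains the taxa selected in more than `freq_threshold` of the models.
#'
#' @param X samples x taxa matrix (alr coordinates), row names = sample ids.
#' @param y two-level class labels (task `"discriminant"`, PLS-DA) or a
#'   numeric response (task `"regression"`, PLS).
#' @param task `"discriminant"` or `"regression"`.
#' @param folds,reps outer resampling design (default 8-fold, 20 reps).
#' @param vip_grid candidate VIP cutoffs.
#' @param freq_threshold selection-frequency threshold for the final set
#'   (strictly greater than; default 0.70).
#' @param inner_k inner CV folds for component/cutoff choice (default 8).
#' @param a_max maximum number of PLS components considered (default 10).
#' @param strata per-sample stratification labels for fold assignment; by
#'   default the class labels (discriminant) or response quartiles
#'   (regression).
#' @param seed master seed; fold assignment is keyed to sample ids, so
#'   results are invariant to row and column order.
#' @return list of class `cmv_selection`: `frequency` (named, sorted),
#'   `final` (character vector; empty with a warning when nothing passes),
#'   `models` (per-model selected sets), `n_models`, and the call
#'   parameters.
#' @export
cmv_select <- function(X, y, task = c("discriminant", "regression"),
                       folds = 8, reps = 20,
                       vip_grid = seq(0.8, 1.1, by = 0.05),
                       freq_threshold = 0.70, inner_k = 8, a_max = 10,
                       strata = NULL, seed = 1) {
  task <- match.arg(task)
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- sprintf("r%04d", seq_len(nrow(X)))
  strata <- default_strata(strata, y, task)
  check_task_inputs(y, task, folds)
  sets <- vector("list", folds * reps)
  i <- 0L
  for (r in seq_len(reps)) {
    fold <- make_folds(rownames(X), strata, folds,
                       substream_seed(seed, 11L, r))
    for (f in seq_len(folds)) {
      i <- i + 1L
      tr <- fold != f
      sets[[i]] <- cmv_fit_one(X[tr, , drop = FALSE], subset_y(y, tr), task,
                               inner_k, vip_grid, a_max, strata[tr],
                               substream_seed(seed, 13L, r, f))
    }
  }
  counts <- table(unlist(sets))
  freq <- stats::setNames(rep(0, ncol(X)), colnames(X))
  freq[names(counts)] <- as.numeric(counts) / length(sets)
  final <- names(freq)[freq > freq_threshold]
  if (length(final) == 0) {
    warning("no taxon exceeded the selection-frequency threshold; ",
            "final set is empty")
  }
  structure(list(frequency = sort(freq, decreasing = TRUE),
                 final = sort(final), models = sets, n_models = length(sets),
                 task = task, folds = folds, reps = reps,
                 freq_threshold = freq_threshold, seed = seed),
            class = "cmv_selection")
}

#' CMV step 2: performance of the final model on the selected taxa
#'
#' Re-runs the outer resampling (independent fold seed stream from step 1)
#' restricted to the selected taxa, choosing the component count per model
#' by inner CV, and reports per-model performance: cross-validated
#' classification accuracy (discriminant; class by thresholding the 0/1
#' code at 0.5) or \eqn{Q^2 = 1 - PRESS / TSS} (regression, with TSS around
#' the training mean), aggregated as mean and SD over the
#' `folds x reps` models.
#'
#' @inheritParams cmv_select
#' @param taxa non-empty character vector of selected taxa (columns of `X`).
#' @return list with `mean`, `sd`, `per_model`, `task`, `n_models`.
#' @export
cmv_evaluate <- function(X, y, taxa, task = c("discriminant", "regression"),
                         folds = 8, reps = 20, inner_k = 8, a_max = 10,
                         strata = NULL, seed = 1) {
  task <- match.arg(task)
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- sprintf("r%04d", seq_len(nrow(X)))
  stopifnot(length(taxa) >= 1, all(taxa %in% colnames(X)))
  strata <- default_strata(strata, y, task)
  check_task_inputs(y, task, folds)
  Xs <- X[, taxa, drop = FALSE]
  per_model <- numeric(folds * reps)
  i <- 0L
  for (r in seq_len(reps)) {
    fold <- make_folds(rownames(X), strata, folds,
                       substream_seed(seed, 17L, r))
    for (f in seq_len(folds)) {
      i <- i + 1L
      per_model[i] <- evaluate_one(Xs, y, task, fold, f, inner_k, a_max,
                                   strata, substream_seed(seed, 19L, r, f))
    }
  }
  list(mean = mean(per_model), sd = stats::sd(per_model),
       per_model = per_model, task = task, n_models = length(per_model))
}

#' Permutation null for the final CMV model
#'
#' Repeats the step-2 evaluation with the response permuted independently
#' for each of the `folds x reps` final models, giving the chance-level
#' performance distribution (about 0.5 accuracy for balanced two-class
#' labels; about 0 or negative \eqn{Q^2} for regression).
#'
#' @inheritParams cmv_evaluate
#' @return list with `mean`, `sd`, `per_model`, `task`, `n_models`.
#' @export
cmv_permutation <- function(X, y, taxa,
                            task = c("discriminant", "regression"),
                            folds = 8, reps = 20, inner_k = 8, a_max = 10,
                            strata = NULL, seed = 1) {
  task <- match.arg(task)
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- sprintf("r%04d", seq_len(nrow(X)))
  stopifnot(length(taxa) >= 1, all(taxa %in% colnames(X)))
  strata <- default_strata(strata, y, task)
  check_task_inputs(y, task, folds)
  Xs <- X[, taxa, drop = FALSE]
  per_model <- numeric(folds * reps)
  i <- 0L
  for (r in seq_len(reps)) {
    for (f in seq_len(folds)) {
      i <- i + 1L
      yp <- with_seed(substream_seed(seed, 23L, r, f),
                      subset_y(y, sample.int(length(strata))))
      # strata follow the permuted response so stratified folds remain valid
      sp <- default_strata(NULL, yp, task)
      fold <- make_folds(rownames(X), sp, folds, substream_seed(seed, 29L, r, f))
      per_model[i] <- evaluate_one(Xs, yp, task, fold, f, inner_k, a_max,
                                   sp, substream_seed(seed, 31L, r, f))
    }
  }
  list(mean = mean(per_model), sd = stats::sd(per_model),
       per_model = per_model, task = task, n_models = length(per_model))
}

#' Taxa retained by both the discriminant and the regression CMV
#'
#' The overlap rule for calling a correlated response: a taxon must appear
#' in the final PLS-DA selection (classifies the lines) and in the final
#' PLS selection (predicts the phenotype).
#'
#' @param plsda_taxa,pls_taxa character vectors of selected taxa.
#' @return sorted intersection.
#' @export
overlap_taxa <- function(plsda_taxa, pls_taxa) {
  sort(intersect(plsda_taxa, pls_taxa))
}

# ---- shared internals ----------------------------------------------------

evaluate_one <- function(Xs, y, task, fold, f, inner_k, a_max, strata, seed) {
  te <- fold == f
  trX <- Xs[!te, , drop = FALSE]
  try_y <- subset_y(y, !te)
  ifold <- make_folds(rownames(trX), strata[!te], inner_k, seed)
  cv <- cv_components(trX, try_y, task, ifold, min(a_max, ncol(Xs)))
  fit <- fit_pls(trX, try_y, min(cv$best_a, sum(!te) - 1L))
  pred <- predict(fit, Xs[te, , drop = FALSE])
  if (task == "discriminant") {
    lev <- sort(unique(as.character(y)))
    y_te <- as.numeric(as.character(subset_y(y, te)) == lev[2])
    mean((pred > 0.5) == (y_te == 1))
  } else {
    y_te <- as.numeric(subset_y(y, te))
    1 - sum((y_te - pred)^2) / sum((y_te - mean(try_y))^2)
  }
}

subset_y <- function(y, idx) if (is.factor(y)) droplevels(y[idx]) else y[idx]

default_strata <- function(strata, y, task) {
  if (!is.null(strata)) return(as.character(strata))
  if (task == "discriminant") return(as.character(y))
  q <- stats::quantile(as.numeric(y), c(0.25, 0.5, 0.75))
  as.character(findInterval(as.numeric(y), unique(q)))
}

check_task_inputs <- function(y, task, folds) {
  if (task == "discriminant") {
    tb <- table(as.character(y))
    if (length(tb) != 2) stop("discriminant task needs exactly two classes")
    if (any(tb < folds)) {
      stop("each class needs at least `folds` members for stratified CV")
    }
  } else if (!is.numeric(y)) stop("regression task needs a numeric response")
  invisible(TRUE)
}
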