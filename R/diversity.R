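# Within-sample (alpha) diversity: adjusted Shannon index and its
# nonparametric comparison between selection lines.

#' Adjusted Shannon index of one sample
#'
#' For a vector of strictly positive relative abundances summing to 1 over
#' the S taxa detected in the sample, computes the Shannon index
#' \eqn{H' = -\sum_j \rho_j \ln \rho_j} (nats), its maximum
#' \eqn{H'_{max} = \ln S} (attained when all taxa are equally abundant) and
#' the adjusted index \eqn{H'_{adj} = H'/H'_{max} \in [0, 1]}.
#'
#' @param p_row strictly positive proportions summing to 1; `S >= 2`.
#' @return named numeric vector `c(H, Hmax, Hadj)`.
#' @export
shannon_adjusted <- function(p_row) {
  p_row <- as.numeric(p_row)
  stopifnot(all(is.finite(p_row)), all(p_row > 0))
  if (abs(sum(p_row) - 1) > 1e-9) stop("proportions must sum to 1")
  S <- length(p_row)
  if (S < 2) stop("adjusted Shannon undefined for a single taxon (H'max = 0)")
  H <- -sum(p_row * log(p_row))
  Hmax <- log(S)
  c(H = H, Hmax = Hmax, Hadj = H / Hmax)
}

#' Per-sample adjusted Shannon diversity of a count table
#'
#' @param counts samples x taxa count matrix.
#' @param mode `"drop_zeros"` (default): undetected taxa are excluded per
#'   sample and the detected counts are closed to proportions (a zero taxon
#'   contributes 0 to H' in the limit). `"imputed"`: zeros are first
#'   replaced by [impute_zeros()] so every taxon contributes.
#' @param ... passed to [impute_zeros()] when `mode = "imputed"`.
#' @return data.frame with one row per sample: `H`, `Hmax`, `Hadj`, `S`.
#' @export
alpha_diversity <- function(counts, mode = c("drop_zeros", "imputed"), ...) {
  mode <- match.arg(mode)
  counts <- validate_counts(counts)
  if (mode == "imputed") {
    comp <- impute_zeros(counts, ...)
    res <- t(apply(comp, 1, shannon_adjusted))
    S <- rep(ncol(comp), nrow(comp))
  } else {
    res <- t(apply(counts, 1, function(r) {
      r <- r[r > 0]
      shannon_adjusted(r / sum(r))
    }))
    S <- rowSums(counts > 0)
  }
  data.frame(sample_id = rownames(counts), H = res[, "H"],
             Hmax = res[, "Hmax"], Hadj = res[, "Hadj"], S = S,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare alpha diversity between lines (Kruskal-Wallis)
#'
#' Batch-mean-corrects the per-sample adjusted Shannon values (when `batch`
#' is given), then compares the two lines with a Kruskal-Wallis rank test
#' (tie-corrected statistic, chi-square p-value). For small samples an
#' exact permutation p-value (enumeration of all label splits) is also
#' reported.
#'
#' @param hadj per-sample diversity values.
#' @param line per-sample line labels (two levels).
#' @param batch optional per-sample batch labels; when given, values are
#'   corrected by [correct_batch()] group-mean removal first.
#' @param exact_max largest total n for which the exact enumeration p-value
#'   is computed (default 12; `choose(12, 6) = 924` splits).
#' @return list with `per_line` (mean, SE, n per line), `statistic`,
#'   `p_chisq`, `p_exact` (NA when not enumerated), `corrected` values, and
#'   `all_tied` flag (statistic undefined when all corrected values tie).
#' @export
compare_alpha_diversity <- function(hadj, line, batch = NULL, exact_max = 12) {
  hadj <- as.numeric(hadj)
  line <- as.character(line)
  stopifnot(length(hadj) == length(line))
  lev <- sort(unique(line))
  if (length(lev) != 2 || any(table(line) < 2)) {
    stop("need exactly two lines with at least two samples each")
  }
  x <- hadj
  if (!is.null(batch)) {
    x <- drop(correct_batch(matrix(hadj, ncol = 1), batch))
  }
  per_line <- do.call(rbind, lapply(lev, function(l) {
    v <- x[line == l]
    data.frame(line = l, n = length(v), mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)))
  }))
  if (length(unique(x)) == 1) {
    return(list(per_line = per_line, statistic = NA_real_,
                p_chisq = NA_real_, p_exact = NA_real_, corrected = x,
                all_tied = TRUE))
  }
  kw <- stats::kruskal.test(x, factor(line))
  p_exact <- NA_real_
  n <- length(x)
  if (n <= exact_max) {
    n1 <- sum(line == lev[1])
    obs <- kw_statistic(x, line == lev[1])
    splits <- utils::combn(n, n1)
    stats_all <- apply(splits, 2, function(idx) {
      g <- rep(FALSE, n); g[idx] <- TRUE
      kw_statistic(x, g)
    })
    p_exact <- mean(stats_all >= obs - 1e-12)
  }
  list(per_line = per_line, statistic = unname(kw$statistic),
       p_chisq = kw$p.value, p_exact = p_exact, corrected = x,
       all_tied = FALSE)
}

# Tie-corrected Kruskal-Wallis statistic for a two-group split.
kw_statistic <- function(x, in_g1) {
  r <- rank(x)
  n <- length(x)
  grp <- split(r, in_g1)
  H <- 12 / (n * (n + 1)) * sum(vapply(grp, function(g) {
    sum(g)^2 / length(g)
  }, numeric(1))) - 3 * (n + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}
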