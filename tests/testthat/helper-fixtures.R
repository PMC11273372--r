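# Shared fixture builders; everything is generated in code at test time.

# Small strictly positive composition with named taxa and sample ids.
toy_composition <- function(n = 12, p = 5, seed = 1) {
  set.seed(seed)
  lg <- matrix(rnorm(n * p), n, p,
               dimnames = list(sprintf("s%02d", seq_len(n)),
                               sprintf("t%02d", seq_len(p))))
  comp <- exp(lg)
  comp / rowSums(comp)
}

# Composition built from a given log-abundance matrix.
comp_from_log <- function(lg) {
  comp <- exp(lg)
  comp / rowSums(comp)
}

# Quick synthetic experiment at reduced size for structural tests.
quick_experiment <- function(seed = 1, ...) {
  generate_experiment(sim_config(n_H = 24, n_L = 21, p = 60, n_diff = 8,
                                 depth_mean = 2e4, seed = seed, ...))
}

# Preprocess counts up to the corrected alr matrix (pipeline front end).
quick_alr <- function(exp_data) {
  f <- filter_prevalence(exp_data$counts)
  comp <- impute_zeros(f)
  ref <- select_alr_reference(comp)$reference
  correct_batch(alr_transform(comp, ref), exp_data$meta$batch)
}

# Brute-force shortest HPD window, independent of hpd_interval().
brute_hpd <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- min(n, max(2L, ceiling(prob * n)))
  best <- c(-Inf, Inf)
  for (i in seq_len(n - k + 1L)) {
    if (x[i + k - 1L] - x[i] < best[2] - best[1]) best <- c(x[i], x[i + k - 1L])
  }
  best
}
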