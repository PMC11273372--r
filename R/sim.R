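#' Configuration for a synthetic two-line microbiome experiment
#'
#' Builds a validated configuration for [generate_experiment()]. Defaults
#' emulate a divergent-selection design: two rabbit lines (47 H-line vs 42
#' L-line cecal samples), two sequencer batches, 315 genus-level taxa with a
#' strong dominance structure (the most abundant taxon holds about 20% of
#' total relative abundance), a subset of taxa shifted between lines by
#' 0.3-0.7 SD on the log scale, and an intramuscular-fat (IMF) phenotype in
#' g/100 g whose microbiome-explained variance fraction (microbiability) is
#' controlled exactly.
#'
#' @param n_H,n_L animals per line (each at least 2).
#' @param p number of taxa.
#' @param n_diff number of line-differential taxa, `0 <= n_diff <= p`.
#' @param effect_range bounds (SD units of per-taxon log-abundance) for the
#'   absolute line effects; signs are random.
#' @param batch_frac fraction of samples assigned to the second sequencer
#'   batch.
#' @param batch_shift_sd scale (SD units) of per-taxon additive batch shifts
#'   on the log scale.
#' @param depth_mean,depth_dispersion log-normal sequencing-depth model:
#'   depths are `rlnorm(meanlog = log(depth_mean), sdlog = depth_dispersion)`.
#'   Together with the abundance spectrum, depth controls how many sampling
#'   zeros appear in low-abundance taxa.
#' @param target_microbiability fraction of IMF variance explained by the
#'   microbiome, in `[0, 1)`.
#' @param imf_coupling multiplier on the IMF coefficients of the
#'   line-differential taxa. A correlated response arises because selection
#'   on IMF drags the taxa associated with it, so the differential taxa
#'   carry more of the microbiome-IMF link than average taxa; the default
#'   of 3 gives the differential set roughly half of the
#'   microbiome-explained IMF variance at the default design.
#' @param imf_line_diff difference between line means of IMF (g/100 g).
#' @param imf_base mean IMF of the population (g/100 g).
#' @param imf_residual_sd residual SD of IMF (g/100 g).
#' @param top_share target relative abundance of the dominant taxon; the
#'   power-law exponent of the mean abundance spectrum is solved from it.
#' @param tail_frac exponential tail cutoff of the abundance spectrum, as a
#'   fraction of `p` (mean spectrum `rank^-a * exp(-rank/(tail_frac * p))`).
#'   Rank-abundance curves of gut metagenomes fall off faster than a pure
#'   power law; the cutoff makes tail taxa rare enough to produce sampling
#'   zeros while the taxa they sit in carry little total mass. Together
#'   with `depth_mean` this controls the zero fraction.
#' @param sample_log_sd typical per-taxon, per-sample log-normal noise SD
#'   (the "SD unit" in which effects are expressed is each taxon's own SD).
#' @param taxon_sd_spread log-normal spread of per-taxon noise SDs around
#'   `sample_log_sd`, truncated at two spreads; real taxa differ in
#'   inter-host stability but extreme dispersions are not seen at the
#'   genus level.
#' @param n_stable number of low-variance "stable" taxa (noise SD
#'   `stable_sd_frac * sample_log_sd`), emulating the near-constant taxa
#'   that make good additive log-ratio references.
#' @param stable_sd_frac noise-SD fraction for stable taxa.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return a list of class `sim_config`.
#' @seealso [generate_experiment()]
#' @export
sim_config <- function(n_H = 47, n_L = 42, p = 315, n_diff = 50,
                       effect_range = c(0.3, 0.7), batch_frac = 0.5,
                       batch_shift_sd = 0.3, depth_mean = 8e4,
                       depth_dispersion = 0.3, target_microbiability = 0.45,
                       imf_coupling = 3, imf_line_diff = 0.5, imf_base = 1.2,
                       imf_residual_sd = 0.3, top_share = 0.20,
                       tail_frac = 0.30, sample_log_sd = 1.0,
                       taxon_sd_spread = 0.25,
                       n_stable = 3, stable_sd_frac = 0.15, seed = 1) {
  stopifnot(n_H >= 2, n_L >= 2, p >= 3, n_diff >= 0, n_diff <= p,
            length(effect_range) == 2, all(effect_range >= 0),
            effect_range[1] <= effect_range[2],
            batch_frac >= 0, batch_frac <= 1, batch_shift_sd >= 0,
            depth_mean > 0, depth_dispersion >= 0,
            target_microbiability >= 0, target_microbiability < 1,
            imf_coupling >= 0,
            imf_residual_sd > 0, top_share > 0, top_share < 1,
            tail_frac > 0, sample_log_sd > 0, taxon_sd_spread >= 0, n_stable >= 0,
            n_stable <= p, stable_sd_frac > 0)
  cfg <- list(n_H = as.integer(n_H), n_L = as.integer(n_L), p = as.integer(p),
              n_diff = as.integer(n_diff), effect_range = effect_range,
              batch_frac = batch_frac, batch_shift_sd = batch_shift_sd,
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              target_microbiability = target_microbiability,
              imf_coupling = imf_coupling,
              imf_line_diff = imf_line_diff, imf_base = imf_base,
              imf_residual_sd = imf_residual_sd, top_share = top_share,
              tail_frac = tail_frac, sample_log_sd = sample_log_sd,
              taxon_sd_spread = taxon_sd_spread,
              n_stable = as.integer(n_stable),
              stable_sd_frac = stable_sd_frac, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Solve the power-law exponent a of the mean abundance spectrum
# (proportions ~ rank^-a * exp(-rank/tau)) so the top-ranked taxon holds
# `top_share`.
solve_power_exponent <- function(p, top_share, tau) {
  w <- function(a) seq_len(p)^(-a) * exp(-seq_len(p) / tau)
  f <- function(a) { v <- w(a); v[1] / sum(v) - top_share }
  if (f(0.05) > 0) return(0.05)
  stats::uniroot(f, c(0.05, 6), tol = 1e-10)$root
}

#' Generate a synthetic two-line compositional count experiment
#'
#' Draws per-sample latent log-abundances from a heavy-tailed (power-law
#' mean spectrum, log-normal noise) baseline, adds line shifts on the
#' differential taxa and per-taxon batch shifts, closes rows to proportions,
#' and samples counts multinomially at a log-normally drawn depth. The IMF
#' phenotype is `line mean + Z beta + noise` where `Z` is the standardized
#' latent log-abundance matrix and the coefficient scale is solved so that
#' the microbiome-explained variance fraction equals
#' `target_microbiability` exactly with respect to the realized microbiome
#' term.
#'
#' @param config a [sim_config()] object.
#' @return a list with components
#'   \describe{
#'     \item{counts}{integer matrix, samples x taxa, row sums = depths.}
#'     \item{meta}{data.frame with `sample_id`, `line` (H/L), `sex` (M/F),
#'       `batch` (S1/S2), `imf` (g/100 g).}
#'     \item{truth}{ground truth: `diff_taxa`, `true_effects` (SD units; 0
#'       for non-differential taxa), `true_microbiability` (the configured
#'       target), `realized_microbiability` (variance fraction of the
#'       realized microbiome term), `true_coefficients`, `latent_log` (the
#'       latent log-abundance matrix).}
#'   }
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  c0 <- config
  n <- c0$n_H + c0$n_L
  with_seed(c0$seed, {
    sample_id <- sprintf("S%03d", seq_len(n))
    line <- rep(c("H", "L"), c(c0$n_H, c0$n_L))
    # sexes balanced within line, assignment randomized
    sex <- unlist(lapply(c(c0$n_H, c0$n_L), function(k) {
      sample(rep_len(c("M", "F"), k))
    }))
    n2 <- round(c0$batch_frac * n)
    batch <- rep("S1", n)
    batch[sample.int(n, n2)] <- "S2"

    taxa <- sprintf("g%03d", seq_len(c0$p))
    tau <- c0$tail_frac * c0$p
    a <- solve_power_exponent(c0$p, c0$top_share, tau)
    mu <- -a * log(seq_len(c0$p)) - seq_len(c0$p) / tau  # mean log spectrum

    # heterogeneous per-taxon noise SDs (real taxa differ widely in
    # stability); a few mid-abundance taxa are near-constant, emulating
    # the low-variance taxa that serve as alr references
    dev <- stats::rnorm(c0$p, 0, c0$taxon_sd_spread)
    dev <- pmin(pmax(dev, -2 * c0$taxon_sd_spread), 2 * c0$taxon_sd_spread)
    sig_j <- c0$sample_log_sd * exp(dev)
    stable_idx <- integer(0)
    if (c0$n_stable > 0) {
      mid <- seq.int(max(2L, floor(c0$p / 10)),
                     max(c0$n_stable + 1L, floor(c0$p / 2)))
      stable_idx <- sort(sample(mid, min(c0$n_stable, length(mid))))
      sig_j[stable_idx] <- c0$stable_sd_frac * c0$sample_log_sd
    }

    # differential taxa drawn from the detectable range (top 2/3 of the
    # abundance spectrum, excluding stable taxa) so planted effects act on
    # observable taxa
    eligible <- setdiff(seq_len(max(c0$n_diff + c0$n_stable,
                                    floor(2 * c0$p / 3))), stable_idx)
    diff_idx <- if (c0$n_diff > 0) sort(sample(eligible, c0$n_diff)) else integer(0)
    effects <- numeric(c0$p)
    if (c0$n_diff > 0) {
      effects[diff_idx] <- sample(c(-1, 1), c0$n_diff, replace = TRUE) *
        stats::runif(c0$n_diff, c0$effect_range[1], c0$effect_range[2])
    }
    batch_shift <- stats::rnorm(c0$p, 0, c0$batch_shift_sd) * sig_j

    half <- ifelse(line == "H", 0.5, -0.5)
    L <- matrix(mu, n, c0$p, byrow = TRUE) +
      outer(half, effects * sig_j) +
      outer(as.numeric(batch == "S2"), batch_shift) +
      matrix(stats::rnorm(n * c0$p), n, c0$p) %*% diag(sig_j)
    dimnames(L) <- list(sample_id, taxa)

    prop <- exp(L - apply(L, 1, max))
    prop <- prop / rowSums(prop)
    depth <- pmax(1L, round(stats::rlnorm(n, log(c0$depth_mean),
                                          c0$depth_dispersion)))
    counts <- t(vapply(seq_len(n),
                       function(i) stats::rmultinom(1, depth[i], prop[i, ])[, 1],
                       integer(c0$p)))
    dimnames(counts) <- list(sample_id, taxa)
    storage.mode(counts) <- "integer"

    # IMF: line mean + scaled microbiome term + residual noise
    t_m <- c0$target_microbiability
    if (t_m > 0) {
      Z <- scale(L)
      beta <- stats::rnorm(c0$p)
      beta[diff_idx] <- c0$imf_coupling * beta[diff_idx]
      g <- drop(Z %*% beta)
      vg <- stats::var(g)
      scale_c <- sqrt(t_m / (1 - t_m) * c0$imf_residual_sd^2 / vg)
      if (!is.finite(scale_c)) {
        stop("cannot solve microbiome coefficient scale: target ",
             "microbiability too close to 1 or degenerate log-abundances")
      }
      m_term <- scale_c * g
      true_coef <- scale_c * beta
    } else {
      m_term <- numeric(n)
      true_coef <- numeric(c0$p)
    }
    e_term <- stats::rnorm(n, 0, c0$imf_residual_sd)
    imf <- unname(c0$imf_base + half * c0$imf_line_diff + m_term + e_term)
    realized <- if (stats::var(m_term) + stats::var(e_term) > 0) {
      stats::var(m_term) / (stats::var(m_term) + stats::var(e_term))
    } else 0

    meta <- data.frame(sample_id = sample_id, line = line, sex = sex,
                       batch = batch, imf = imf, stringsAsFactors = FALSE)
    truth <- list(diff_taxa = taxa[diff_idx],
                  stable_taxa = taxa[stable_idx],
                  taxon_log_sd = stats::setNames(sig_j, taxa),
                  true_effects = stats::setNames(effects, taxa),
                  true_microbiability = t_m,
                  realized_microbiability = realized,
                  true_coefficients = stats::setNames(true_coef, taxa),
                  latent_log = L)
    list(counts = counts, meta = meta, truth = truth)
  })
}
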