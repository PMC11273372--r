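# File readers/writers (plain TSV exchange format) and the end-to-end
# pipeline driver. Samples are keyed by string id and taxa by label
# throughout; no positional indexing across files. Lines starting with `#`
# are header comments (every file written here carries the configuration
# hash and seed in one).

#' Read a samples x taxa count table from TSV
#'
#' Expects a header row (first field the sample-id column name, remaining
#' fields taxon labels) and one row per sample. Comment lines starting with
#' `#` are skipped. Duplicate sample ids or taxon labels, ragged rows, and
#' non-integer or negative cells are rejected with their location.
#'
#' @param path file path.
#' @return integer matrix with sample ids as row names and taxon labels as
#'   column names.
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("count table needs a header and >= 1 sample row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  taxa <- header[-1]
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon label(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  p <- length(taxa)
  rows <- fields[-1]
  ids <- character(length(rows))
  mat <- matrix(NA_integer_, length(rows), p)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != p + 1) {
      stop(sprintf("ragged row %d: %d fields, expected %d", i + 1,
                   length(r), p + 1))
    }
    ids[i] <- r[1]
    v <- suppressWarnings(as.numeric(r[-1]))
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop(sprintf("row %d (sample %s), column %d (%s): '%s' is not a %s",
                   i + 1, ids[i], bad[1] + 1, taxa[bad[1]], r[bad[1] + 1],
                   "non-negative integer count"))
    }
    mat[i, ] <- as.integer(v)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  dimnames(mat) <- list(ids, taxa)
  mat
}

#' Write a count table (or any sample-keyed matrix) to TSV
#'
#' @param x matrix with sample row names and taxon column names.
#' @param path output path.
#' @param comment optional character vector written as leading `#` lines.
#' @param id_col name of the first (sample id) column.
#' @export
write_count_table <- function(x, path, comment = NULL,
                              id_col = "sample_id") {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c(id_col, colnames(x)), collapse = "\t"), con)
  body <- apply(cbind(rownames(x), format(x, trim = TRUE, scientific = FALSE)),
                1, paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' Requires columns `sample_id`, `line`, `sex`, `batch`, `imf` (comment
#' lines starting with `#` are skipped).
#'
#' @param path file path.
#' @return data.frame with those columns; `imf` numeric.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "line", "sex", "batch", "imf")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample id(s) in metadata")
  df$imf <- as.numeric(df$imf)
  df[, need]
}

#' Pipeline configuration
#'
#' Collects every tunable parameter of [run_pipeline()] with the defaults
#' used throughout the package. Resampling and MCMC sizes default to the
#' full protocol (8 x 20 CMV models; 120000/20000/10 MBLUP chain;
#' 60000/10000/10 per-taxon chains); pass smaller values for quick runs.
#'
#' @param max_undetected_frac prevalence filter threshold.
#' @param prior_strength zero-imputation prior mass (`NULL` = `0.5 * p`).
#' @param reference `"auto"` (data-driven choice via
#'   [select_alr_reference()]) or a taxon label.
#' @param reference_tolerance Procrustes slack for reference selection.
#' @param cmv_folds,cmv_reps,freq_threshold CMV design.
#' @param mblup_iterations,mblup_burnin,mblup_thin MBLUP chain.
#' @param effect_iterations,effect_burnin,effect_thin per-taxon chains.
#' @param biomarker_kfold,biomarker_reps,biomarker_max_taxa balance search.
#' @param line_subset `"all"`, `"H"` or `"L"`: samples used for the
#'   microbiability model.
#' @param seed master seed; every stage derives its own stream from it.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(max_undetected_frac = 0.10,
                            prior_strength = NULL,
                            reference = "auto", reference_tolerance = 0.005,
                            cmv_folds = 8, cmv_reps = 20,
                            freq_threshold = 0.70,
                            mblup_iterations = 120000, mblup_burnin = 20000,
                            mblup_thin = 10,
                            effect_iterations = 60000, effect_burnin = 10000,
                            effect_thin = 10,
                            biomarker_kfold = 8, biomarker_reps = 20,
                            biomarker_max_taxa = NULL,
                            line_subset = c("all", "H", "L"),
                            seed = 1) {
  cfg <- list(max_undetected_frac = max_undetected_frac,
              prior_strength = prior_strength, reference = reference,
              reference_tolerance = reference_tolerance,
              cmv_folds = cmv_folds, cmv_reps = cmv_reps,
              freq_threshold = freq_threshold,
              mblup_iterations = mblup_iterations,
              mblup_burnin = mblup_burnin, mblup_thin = mblup_thin,
              effect_iterations = effect_iterations,
              effect_burnin = effect_burnin, effect_thin = effect_thin,
              biomarker_kfold = biomarker_kfold,
              biomarker_reps = biomarker_reps,
              biomarker_max_taxa = biomarker_max_taxa,
              line_subset = match.arg(line_subset),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes, in order: prevalence filter, zero imputation, alr reference
#' selection, alr transformation, sequencer-batch correction, alpha
#' diversity with line comparison, MBLUP microbiability, CMV taxon
#' selection (PLS-DA and PLS) with step-2 performance and permutation
#' nulls, the PLS-DA/PLS overlap, per-taxon Bayesian effect sizes, and the
#' balance biomarker search. A stage failure aborts with the stage name and
#' cause. When `output_dir` is given, every artifact is written there with
#' the configuration hash and stage seed in a header comment.
#'
#' @param counts samples x taxa integer count matrix (see
#'   [read_count_table()]).
#' @param meta metadata data.frame (see [read_metadata()]); must cover the
#'   same sample ids.
#' @param config a [pipeline_config()].
#' @param output_dir optional directory for artifacts.
#' @return a list report: per-stage results, `stages` (name, n_samples,
#'   n_taxa, seed per stage), `config`, `config_hash`.
#' @export
run_pipeline <- function(counts, meta, config = pipeline_config(),
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  counts <- validate_counts(counts)
  if (!all(rownames(counts) %in% meta$sample_id)) {
    stop("metadata does not cover all count-table samples")
  }
  meta <- meta[match(rownames(counts), meta$sample_id), ]
  hash <- config_hash(unclass(config))
  stages <- list()
  log_stage <- function(name, n_samples, n_taxa, seed = NA) {
    stages[[length(stages) + 1]] <<- data.frame(
      stage = name, n_samples = n_samples, n_taxa = n_taxa, seed = seed)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  filtered <- run_stage("filter", filter_prevalence(
    counts, config$max_undetected_frac))
  log_stage("filter", nrow(filtered), ncol(filtered))

  comp <- run_stage("impute", impute_zeros(filtered, config$prior_strength))
  log_stage("impute", nrow(comp), ncol(comp))

  ref_diag <- NULL
  reference <- config$reference
  if (identical(reference, "auto")) {
    ref_sel <- run_stage("reference", select_alr_reference(
      comp, config$reference_tolerance))
    ref_diag <- ref_sel$diagnostics
    reference <- ref_sel$reference
  }
  alr_raw <- run_stage("alr", alr_transform(comp, reference))
  alr <- run_stage("batch_correction", correct_batch(alr_raw, meta$batch))
  pca_before <- pca_batch_diagnostic(alr_raw)
  pca_after <- pca_batch_diagnostic(alr)
  log_stage("alr", nrow(alr), ncol(alr))

  div <- run_stage("diversity", {
    ad <- alpha_diversity(filtered)
    cmp <- compare_alpha_diversity(ad$Hadj, meta$line, meta$batch)
    list(per_sample = ad, comparison = cmp)
  })
  log_stage("diversity", nrow(div$per_sample), ncol(filtered))

  mb_seed <- substream_seed(config$seed, 101L)
  mb <- run_stage("microbiability", {
    sel <- if (config$line_subset == "all") rep(TRUE, nrow(alr))
           else meta$line == config$line_subset
    B <- standardize_columns(alr[sel, , drop = FALSE])
    K <- build_relationship(B)
    Xf <- cbind(intercept = 1,
                sex = as.numeric(meta$sex[sel] == sort(unique(meta$sex))[1]))
    chain <- fit_mblup(meta$imf[sel], Xf, K,
                       iterations = config$mblup_iterations,
                       burnin = config$mblup_burnin,
                       thin = config$mblup_thin, seed = mb_seed)
    list(chain = chain, summary = summarize_chain(chain))
  })
  log_stage("microbiability", sum(if (config$line_subset == "all")
    nrow(alr) else sum(meta$line == config$line_subset)), ncol(alr), mb_seed)

  cmv_seed_da <- substream_seed(config$seed, 102L)
  cmv_seed_re <- substream_seed(config$seed, 103L)
  plsda <- run_stage("cmv_plsda", {
    sel <- cmv_select(alr, meta$line, "discriminant", config$cmv_folds,
                      config$cmv_reps, freq_threshold = config$freq_threshold,
                      seed = cmv_seed_da)
    perf <- perm <- NULL
    if (length(sel$final) > 0) {
      perf <- cmv_evaluate(alr, meta$line, sel$final, "discriminant",
                           config$cmv_folds, config$cmv_reps,
                           seed = cmv_seed_da)
      perm <- cmv_permutation(alr, meta$line, sel$final, "discriminant",
                              config$cmv_folds, config$cmv_reps,
                              seed = cmv_seed_da)
    }
    list(selection = sel, performance = perf, permutation = perm)
  })
  log_stage("cmv_plsda", nrow(alr), length(plsda$selection$final),
            cmv_seed_da)

  pls <- run_stage("cmv_pls", {
    sel <- cmv_select(alr, meta$imf, "regression", config$cmv_folds,
                      config$cmv_reps, freq_threshold = config$freq_threshold,
                      strata = meta$line, seed = cmv_seed_re)
    perf <- perm <- NULL
    if (length(sel$final) > 0) {
      perf <- cmv_evaluate(alr, meta$imf, sel$final, "regression",
                           config$cmv_folds, config$cmv_reps,
                           strata = meta$line, seed = cmv_seed_re)
      perm <- cmv_permutation(alr, meta$imf, sel$final, "regression",
                              config$cmv_folds, config$cmv_reps,
                              strata = meta$line, seed = cmv_seed_re)
    }
    list(selection = sel, performance = perf, permutation = perm)
  })
  log_stage("cmv_pls", nrow(alr), length(pls$selection$final), cmv_seed_re)

  overlap <- overlap_taxa(plsda$selection$final, pls$selection$final)
  log_stage("overlap", nrow(alr), length(overlap))

  # downstream stages run on the overlap (the correlated-response set); if
  # the overlap is too small to support an effect table and a balance
  # search, they fall back to the PLS-DA final set (the line-discriminating
  # taxa), recorded in the report
  candidate_set <- "overlap"
  candidates <- overlap
  if (length(candidates) < 5 && length(plsda$selection$final) >= 2) {
    candidate_set <- "plsda_final"
    candidates <- plsda$selection$final
  }

  eff_seed <- substream_seed(config$seed, 104L)
  effects <- NULL
  if (length(candidates) > 0) {
    effects <- run_stage("effects", taxon_effects(
      alr, meta$line, meta$sex, candidates, config$effect_iterations,
      config$effect_burnin, config$effect_thin, seed = eff_seed))
  }
  log_stage("effects", nrow(alr), length(candidates), eff_seed)

  bio_seed <- substream_seed(config$seed, 105L)
  biomarker <- NULL
  if (length(candidates) >= 2) {
    biomarker <- run_stage("biomarker", selbal_search(
      comp[, candidates, drop = FALSE], meta$line, config$biomarker_kfold,
      config$biomarker_reps, config$biomarker_max_taxa, seed = bio_seed))
  }
  log_stage("biomarker", nrow(comp), length(candidates), bio_seed)

  report <- list(filtered_counts = filtered, composition = comp,
                 reference = reference, reference_diagnostics = ref_diag,
                 alr = alr, pca_before = pca_before, pca_after = pca_after,
                 diversity = div, microbiability = mb, plsda = plsda,
                 pls = pls, overlap = overlap,
                 candidate_set = candidate_set, candidates = candidates,
                 effects = effects, biomarker = biomarker,
                 stages = do.call(rbind, stages), config = config,
                 config_hash = hash)
  if (!is.null(output_dir)) write_pipeline_artifacts(report, meta, output_dir)
  report
}

# Write the pipeline artifacts as TSV/JSON, each stamped with the config
# hash and master seed.
write_pipeline_artifacts <- function(report, meta, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("micsel config=%s seed=%d", report$config_hash,
                   report$config$seed)
  wn <- function(x, f) write_count_table(
    signif(x, 10), file.path(output_dir, f), comment = stamp)
  wn(report$alr, "alr.tsv")
  if (!is.null(report$reference_diagnostics)) {
    utils::write.table(report$reference_diagnostics,
                       file.path(output_dir, "reference_diagnostics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  div <- report$diversity$per_sample
  utils::write.table(div, file.path(output_dir, "diversity.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  s <- report$microbiability$summary
  jsonlite::write_json(
    list(stamp = stamp, median = s$median,
         hpd_lower = unname(s$hpd[1]), hpd_upper = unname(s$hpd[2]),
         p_gt_threshold = s$p_gt_threshold),
    file.path(output_dir, "microbiability.json"), auto_unbox = TRUE,
    digits = NA)
  if (!is.null(report$effects)) {
    utils::write.table(report$effects, file.path(output_dir, "effects.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$biomarker)) {
    b <- report$biomarker
    jsonlite::write_json(
      list(stamp = stamp, num = b$num, den = b$den,
           accuracy_mean = b$accuracy_mean, accuracy_sd = b$accuracy_sd),
      file.path(output_dir, "balance.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(stamp = stamp, stages = report$stages,
         overlap = report$overlap),
    file.path(output_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}

#' Write a metadata table to TSV
#'
#' @param meta data.frame with `sample_id`, `line`, `sex`, `batch`, `imf`.
#' @param path output path.
#' @param comment optional `#` header comment lines.
#' @export
write_metadata <- function(meta, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(meta, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
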