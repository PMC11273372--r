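# micsel

Correlated responses of a gut microbiome to divergent selection on a host
phenotype.

## The problem

When two animal lines are divergently selected for a trait — here,
rabbit lines selected up and down for intramuscular fat (IMF, g/100 g of
muscle) over ten generations — the selection may drag other systems along
with it. `micsel` asks two questions of a cecal (or any gut) microbiome
count table with per-animal line, sex, sequencer batch and phenotype:

1. **How much of the phenotypic variance does microbiome composition
   explain?** The *microbiability* is estimated from the microbiome-BLUP
   mixed model `y = Xb + m + e` with `m ~ N(0, K σ²_m)`, where
   `K = (1/p) B Bᵀ` is a microbiome relationship matrix built from
   standardized additive-log-ratio (alr) abundances — the microbiome
   analogue of a genomic relationship matrix. A Gibbs sampler with
   bounded flat priors yields the posterior of
   `σ²_m / (σ²_m + σ²_e)`, summarized by its median, shortest HPD95%
   interval, and exceedance probability.
2. **Which taxa responded to selection?** Taxa are selected by a
   two-step cross-model validation (CMV) around PLS-DA (classifying the
   lines) and PLS (predicting IMF): in each of 8 folds × 20 repetitions,
   a taxon is kept when the jackknife 95% CI of its coefficient excludes
   0 and its VIP passes an inner-CV-chosen cutoff in `[0.8, 1.1]`; taxa
   selected in > 70% of models form the final set, evaluated by
   cross-validated accuracy / Q² against permutation nulls. Taxa in both
   final sets are declared to show a correlated response, quantified per
   taxon as a Bayesian line difference in residual-SD units with HPD95%
   and sign probability P₀, and condensed into a compositional *balance*
   biomarker (smallest log-contrast of taxa that classifies the lines,
   greedy search with nested cross-validated logit accuracy).

The pipeline is fronted by compositional preprocessing (prevalence
filter, Bayesian-multiplicative zero imputation, alr transform with
data-driven low-variance/Procrustes reference selection, sequencer-batch
correction) and adjusted Shannon diversity with a Kruskal-Wallis line
comparison. A synthetic-data generator reproduces the study design (47
vs 42 animals, 315 genus-level taxa, dominance structure, zeros, batch
effects, 0.3–0.7 SD line effects, controllable microbiability) with full
ground truth, so every stage is testable.

## Worked example

```r
library(micsel)

exp_data <- generate_experiment(sim_config(seed = 42))   # 89 animals x 315 taxa
cfg <- pipeline_config(cmv_reps = 5,
                       mblup_iterations = 12000, mblup_burnin = 2000,
                       effect_iterations = 6000, effect_burnin = 1000,
                       biomarker_reps = 5, seed = 42)
report <- run_pipeline(exp_data$counts, exp_data$meta, cfg)

report$reference                      # data-chosen alr reference taxon
#> [1] "g038"
report$microbiability$chain
#> MBLUP posterior chain: 1000 saved draws (12000 iterations, 2000 burn-in, thin 10)
#>   microbiability median 0.365, HPD95% [0.016, 0.706], P(>0.25) = 0.70
#>   Geweke Z: sigma_m2=1.02, sigma_e2=-0.70, microbiability=1.30
```

The posterior median says ~37% of IMF variance is attributable to
microbiome composition in this synthetic cohort (generated at a target of
0.45; at n = 89 the HPD is wide, just as for the real-data estimate this
design mimics). The selection stages:

```r
length(report$plsda$selection$final)          # taxa classifying the lines
#> [1] 14
round(100 * report$plsda$performance$mean, 1) # CV accuracy (%)
#> [1] 89.9
round(100 * report$plsda$permutation$mean, 1) # permuted-label null (%)
#> [1] 49.6
head(report$effects[order(-abs(report$effects$mean)), 1:5], 3)
#>    taxon       mean  hpd_lower  hpd_upper p0
#> 12  g157  1.2229281  0.8281374  1.6494789  1
#> 8   g085 -0.9715766 -1.3630388 -0.5289049  1
#> 9   g118  0.9115712  0.5042241  1.3138393  1
report$biomarker
#> Microbial balance biomarker:
#>   numerator  : g013, g021, g058, g084, g085, g170
#>   denominator: g118, g135, g157
#>   CV accuracy: 0.804 (SD 0.141) over 40 folds
```

So the lines are separable from microbiome composition at ~90% CV
accuracy against a ~50% permutation null; the strongest individual
responses are ±0.8–1.2 residual SDs with P₀ = 1; and a 9-taxon balance
classifies the lines at ~80% nested-CV accuracy. The per-taxon effect
signs and magnitudes can be compared against
`exp_data$truth$true_effects`.

## Package layout

| Area | Functions |
| --- | --- |
| Synthetic data | `sim_config()`, `generate_experiment()` |
| Preprocessing | `filter_prevalence()`, `impute_zeros()`, `select_alr_reference()`, `alr_transform()`, `alr_inverse()`, `correct_batch()`, `pca_batch_diagnostic()`, `procrustes_correlation()` |
| Diversity | `shannon_adjusted()`, `alpha_diversity()`, `compare_alpha_diversity()` |
| Microbiability | `standardize_columns()`, `build_relationship()`, `fit_mblup()`, `summarize_chain()`, `geweke_z()`, `hpd_interval()` |
| Taxon selection | `fit_pls()`, `vip_scores()`, `cmv_select()`, `cmv_evaluate()`, `cmv_permutation()`, `overlap_taxa()` |
| Effect sizes | `fit_taxon_model()`, `standardize_effect()`, `taxon_effects()` |
| Biomarker | `balance_value()`, `selbal_search()`, `logit_cv_accuracy()` |
| IO / driver | `read_count_table()`, `read_metadata()`, `write_count_table()`, `write_metadata()`, `pipeline_config()`, `run_pipeline()` |

The methods vignette (`vignettes/micsel-methods.Rmd`) documents the
models, priors, resampling design, generator assumptions, and known
limitations.
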