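# wolbomics

Tissue-specific multi-omics analysis of insulin–Wolbachia interactions in
*Drosophila*.

Long-lived insulin-ligand mutant flies (*dilp2-3,5*) need their
endosymbiont *Wolbachia* for lifespan extension. Asking *which* molecular
responses to reduced insulin/IGF signalling (IIS) depend on the symbiont
turns into a factorial inference problem per tissue (fat body, gut, brain,
thorax): genotype × Wolbachia, measured by label-free proteomics (5
replicates/condition), RNA-seq (3 replicates/condition) and transposon
counts. `wolbomics` implements that inference chain for analysts working
with this kind of design:

- **Proteomics**: per-category validity filtering (≥ 4 valid values),
  down-shifted normal imputation (width 0.3, shift 1.8), per-tissue
  two-factor OLS with empirical-Bayes variance moderation
  (`s̃²g = (d₀s₀² + d·s²g)/(d₀ + d)`, method of moments on log s²), and the
  three contrasts `main_plus` (mutant − control | W+), `main_minus`
  (mutant − control | W−), `interaction = main_plus − main_minus`;
  Benjamini–Hochberg per tissue and contrast, calls at adj. p ≤ 0.1.
- **RNA-seq / transposons**: median-of-ratios size factors and Cox–Reid
  dispersion estimation on the *combined* gene + transposon counts,
  NB GLM likelihood-ratio tests (χ², 1 df) per contrast, separate BH
  families for genes and transposons.
- **Wolbachia classification**: *dependent* = significant main effect and
  interaction; *independent* = significant main effect whose interaction
  is TOST-equivalent to zero (90% CI ⊆ [−t, t]); `t` = mean over tissues
  of median |interaction log₂FC| (medians 0.10/0.06/0.08/0.10 → t = 0.085).
- **Concordance**: transcript–protein pairs classified into
  both-up / both-down / opposite quadrants with per-panel selection gates
  and correlation.
- **Network propagation**: random walk with restart
  (`s ← αWs + (1−α)s₀`, α = 0.8) of absolute log₂FCs over a PPI network,
  hub-bias correction by seed-permutation nulls, cross-model minimum
  consensus, Ward clustering of score profiles.
- **Enrichment**: one-sided Fisher tests against tissue-restricted
  backgrounds (detected proteins; transcripts at median count > 5), term
  sizes 5–1000, redundancy clustering of terms differing by ≤ 5 list
  genes with smallest-annotation primary terms, BH over primaries; mean
  log₂FC signatures with one-sample t-tests.
- **Synthetic data**: a seeded generator emulating the full design with
  known ground truth (effects, interactions, decoupled fraction, modules,
  NB dispersions, intensity-dependent dropout), so the chain's
  sensitivity and FDR are measurable exactly.

## Worked example

```r
library(wolbomics)
res <- run_pipeline(pipeline_config(seed = 1), outdir = "demo_run")
str(res$summary$recovery)
#> List of 4
#>  $ n_called_dependent: int 181
#>  $ sensitivity       : num 0.867
#>  $ fdr               : num 0.0276
#>  $ opposite_fraction : num 0.498
res$summary$t_equivalence
#> [1] 0.2221354
```

Reading: at generator defaults the pipeline called 181 fat-body features
Wolbachia-dependent, recovering 87% of the planted dependent set at an
observed FDR of 2.8%; among protein-significant fat-body genes, 49.8% have
transcript and protein moving in opposite directions, matching the planted
decoupled fraction of 0.5. The data-driven equivalence bound `t` (0.22
here) scales with the simulation's interaction noise; `fixed_t = 0.085`
reproduces the reference constant instead. `demo_run/` receives the
design, matrices, DE tables, calls, network scores, enrichment table and a
`summary.json`.

Individual stages are plain functions (`filter_min_valid`,
`impute_downshifted`, `de_intensity`, `de_counts`, `classify_wolbachia`,
`pair_and_classify`, `propagate`, `bias_correct`, `fisher_term_test`, ...)
usable on your own matrices; `inst/scripts/run_pipeline.R` is a shell
entry point (`Rscript run_pipeline.R --config cfg.yaml --seed 1 --outdir
out/`).

## Package layout

- `R/` — implementation (generator, prep, both DE routes, classification,
  concordance, network propagation, enrichment, pipeline, I/O).
- `tests/testthat/` — unit, property and end-to-end recovery tests with
  independent oracles (dense linear solves, exhaustive hypergeometric
  enumeration, brute-force BH, `limma::squeezeVar` cross-check).
- `vignettes/multiomics-workflow.Rmd` — the models, their assumptions,
  parameter defaults and limitations.
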