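#' Configuration for an end-to-end pipeline run
#'
#' Collects the generator settings and every analysis constant in one named
#' list: significance level 0.1 on BH-adjusted p-values, optional fixed
#' equivalence bound (`fixed_t = 0.085` reproduces the conventional
#' constant; `NULL` recomputes it from the data), minimum of 4 valid values
#' per category, imputation width 0.3 and down-shift 1.8, spreading
#' coefficient 0.8, GO term sizes 5-1000, redundancy difference 5, and
#' transcript-background median count > 5.
#'
#' @param n_genes,n_transposons Generator sizes (demo defaults 2000/100).
#' @param tissues Tissue panel.
#' @param n_rep_protein,n_rep_rna Replicates per condition and assay.
#' @param truth Arguments for [truth_params()].
#' @param network Arguments for [network_params()].
#' @param noise_sd Proteomic noise SD.
#' @param dropout Arguments for [dropout_params()].
#' @param alpha Adjusted-p significance threshold.
#' @param fixed_t Fixed equivalence bound, or `NULL` to recompute.
#' @param min_valid,impute_width,impute_shift Matrix-preparation settings.
#' @param prop_alpha,n_perm,k Propagation settings.
#' @param go_min_size,go_max_size,go_max_diff,min_median_count Enrichment
#'   settings.
#' @param selection Concordance gating side.
#' @param seed Master seed; all stage seeds derive from it.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_genes = 2000L, n_transposons = 100L,
                            tissues = c("fat", "gut", "brain", "thorax"),
                            n_rep_protein = 5L, n_rep_rna = 3L,
                            truth = list(), network = list(),
                            noise_sd = 0.3, dropout = list(),
                            alpha = 0.1, fixed_t = NULL,
                            min_valid = 4L, impute_width = 0.3,
                            impute_shift = 1.8,
                            prop_alpha = 0.8, n_perm = 100L, k = 10L,
                            go_min_size = 5L, go_max_size = 1000L,
                            go_max_diff = 5L, min_median_count = 5,
                            selection = "protein", seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, prop_alpha >= 0, prop_alpha < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full simulated multi-omics analysis chain
#'
#' Generates ground truth, counts, intensities, network and annotations;
#' prepares and models the proteomic matrices per tissue (filter, impute,
#' moderated factorial tests); runs the NB likelihood-ratio tests on gene
#' and transposon counts per tissue; classifies Wolbachia dependence and
#' equivalence; computes transcript-protein concordance in the decoupled
#' tissue; performs bias-corrected network propagation with cross-model
#' minimum consensus (protein- and transcript-derived effect sizes serve as
#' the two models) and Ward clustering; and tests Wolbachia-dependent genes
#' for gene-set enrichment. Deterministic for a fixed config and seed.
#'
#' @param config A [pipeline_config()] list.
#' @param outdir Optional directory for TSV/JSON artifacts and a run log.
#' @return List with all stage outputs and a `summary` list (also written as
#'   JSON when `outdir` is given).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  design <- sim_design(config$tissues, config$n_rep_protein, config$n_rep_rna)
  truth <- generate_truth(config$n_genes, config$n_transposons,
                          params = do.call(truth_params, config$truth),
                          seed = config$seed, tissues = config$tissues)
  counts <- simulate_counts(truth, design, seed = config$seed)
  intens <- simulate_intensities(truth, design, noise_sd = config$noise_sd,
                                 missing_params = do.call(dropout_params,
                                                          config$dropout),
                                 seed = config$seed)
  net <- generate_network_and_annotations(truth,
                                          do.call(network_params,
                                                  config$network),
                                          seed = config$seed)

  de_prot <- list()
  de_rna <- list()
  backgrounds <- list()
  for (tau in config$tissues) {
    dp <- design_subset(design, tissue = tau, assay = "protein")
    m <- intens[, dp$sample_id, drop = FALSE]
    m <- filter_min_valid(m, design, config$min_valid)
    backgrounds[[tau]] <- define_background(m, "protein")
    m <- impute_downshifted(m, config$impute_width, config$impute_shift,
                            seed = derive_seed(config$seed, paste0("imp", tau)))
    de_prot[[tau]] <- de_intensity(m, design, tissue = tau)

    dr <- design_subset(design, tissue = tau, assay = "transcript")
    de_rna[[tau]] <- de_counts(counts[, dr$sample_id, drop = FALSE], design,
                               feature_class = truth$feature_class,
                               tissue = tau)
  }
  de_prot_all <- do.call(rbind, de_prot)
  de_rna_all <- do.call(rbind, de_rna)

  inter <- de_prot_all[de_prot_all$contrast == "interaction", , drop = FALSE]
  t_used <- config$fixed_t %||% equivalence_threshold(inter)
  main <- de_prot_all[de_prot_all$contrast == "main_plus", , drop = FALSE]
  calls <- classify_wolbachia(main, inter, t = t_used, alpha = config$alpha)

  dec_tau <- do.call(truth_params, config$truth)$decoupled_tissue
  tr_side <- de_rna_all[de_rna_all$tissue == dec_tau &
                          de_rna_all$contrast == "main_plus" &
                          de_rna_all$class == "gene", , drop = FALSE]
  pr_side <- de_prot_all[de_prot_all$tissue == dec_tau &
                           de_prot_all$contrast == "main_plus", , drop = FALSE]
  conc <- pair_and_classify(tr_side, pr_side, selection = config$selection,
                            alpha = config$alpha)
  conc_r <- if (conc$n >= 3) concordance_correlation(conc$pairs) else
    list(r = NA_real_, n = conc$n)

  seeds_a <- lapply(config$tissues, function(tau) {
    x <- de_prot[[tau]]
    x <- x[x$contrast == "main_plus", ]
    setNames(abs(x$lfc), x$feature)
  })
  seeds_b <- lapply(config$tissues, function(tau) {
    x <- de_rna[[tau]]
    x <- x[x$contrast == "main_plus" & x$class == "gene", ]
    setNames(abs(x$lfc), x$feature)
  })
  names(seeds_a) <- names(seeds_b) <- config$tissues
  prop <- run_netprop(net, seeds_a, seeds_b, alpha = config$prop_alpha,
                      n_perm = config$n_perm, k = config$k,
                      seed = config$seed)

  dep_genes <- unique(calls$feature[calls$call == "dependent" &
                                      calls$tissue == dec_tau])
  bg <- backgrounds[[dec_tau]]
  dep_genes <- intersect(dep_genes, bg)
  enr <- fisher_term_test(dep_genes, bg, net$genesets,
                          config$go_min_size, config$go_max_size)
  enr <- reduce_redundancy(enr, dep_genes, net$genesets, config$go_max_diff)
  lfc_fat <- setNames(pr_side$lfc, pr_side$feature)
  sig_sets <- Filter(function(s) length(intersect(s, names(lfc_fat))) >= 2,
                     net$genesets)
  sig <- signature_summary(lfc_fat, sig_sets)

  # recovery against quantified truth: only features that survived the
  # validity filter in a tissue can be called there
  truth_dep <- truth$wolbachia_dependent
  called_dep <- calls[calls$call == "dependent", , drop = FALSE]
  is_true <- mapply(function(f, tau) {
    f %in% rownames(truth_dep) && truth_dep[f, tau]
  }, called_dep$feature, called_dep$tissue)
  n_true_dep <- sum(vapply(config$tissues, function(tau) {
    quant <- unique(de_prot[[tau]]$feature)
    sum(truth_dep[intersect(quant, rownames(truth_dep)), tau])
  }, numeric(1)))
  recovery <- list(
    n_called_dependent = nrow(called_dep),
    sensitivity = if (n_true_dep > 0) sum(is_true) / n_true_dep else NA,
    fdr = if (nrow(called_dep) > 0) 1 - sum(is_true) / nrow(called_dep) else 0,
    opposite_fraction = conc$percent[conc$quadrants == "opposite"] / 100
  )

  summary <- list(
    seed = config$seed,
    t_equivalence = t_used,
    de_counts_per_tissue = lapply(split(de_prot_all, de_prot_all$tissue),
      function(x) sum(x$contrast == "main_plus" & x$adjP <= config$alpha,
                      na.rm = TRUE)),
    rna_de_counts_per_tissue = lapply(split(de_rna_all, de_rna_all$tissue),
      function(x) sum(x$contrast == "main_plus" & x$class == "gene" &
                        x$adjP <= config$alpha, na.rm = TRUE)),
    wolbachia_calls = as.list(table(calls$call)),
    quadrant_percent = setNames(as.list(conc$percent), conc$quadrants),
    concordance_r = conc_r$r,
    concordance_n = conc_r$n,
    cluster_sizes = as.list(table(prop$clusters$labels)),
    top_enrichments = head(enr[enr$primary & !is.na(enr$adjP), ][
      order(enr$adjP[enr$primary & !is.na(enr$adjP)]), "term"], 5),
    recovery = recovery
  )

  out <- list(config = config, design = design, truth = truth,
              counts = counts, intensities = intens, network = net,
              de_protein = de_prot_all, de_rna = de_rna_all,
              wolbachia_calls = calls, concordance = conc,
              propagation = prop, enrichment = enr, signatures = sig,
              summary = summary)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(design, file.path(outdir, "design.tsv"))
    write_matrix_tsv(counts, file.path(outdir, "counts.tsv"))
    write_matrix_tsv(intens, file.path(outdir, "intensities.tsv"))
    write_tsv(net$edges, file.path(outdir, "network_edges.tsv"))
    write_gmt(net$genesets, file.path(outdir, "genesets.gmt"))
    write_tsv(de_prot_all, file.path(outdir, "de_protein.tsv"))
    write_tsv(de_rna_all, file.path(outdir, "de_rna.tsv"))
    write_tsv(calls, file.path(outdir, "wolbachia_calls.tsv"))
    write_tsv(enr, file.path(outdir, "enrichment.tsv"))
    write_tsv(sig, file.path(outdir, "signatures.tsv"))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(
      paste("wolbomics", as.character(utils::packageVersion("wolbomics"))),
      paste("R", R.version.string),
      paste("seed", config$seed),
      paste("t_equivalence", format(t_used)),
      paste("alpha", config$alpha),
      paste("prop_alpha", config$prop_alpha),
      paste("n_perm", config$n_perm)
    ), file.path(outdir, "run_log.txt"))
  }
  out
}
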