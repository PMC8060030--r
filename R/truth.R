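#' Parameters for the ground-truth generator
#'
#' Effect-size and class-frequency settings controlling the planted signal.
#' Per tissue, each gene is insulin-responsive (non-zero genotype main
#' effect) with probability `responsive_fraction`; in
#' `wolbachia_dependent_tissue` an additional, mutually exclusive class of
#' genes carries a Wolbachia x genotype interaction (and is forced to be
#' responsive, since dependence is only defined for responsive features).
#' In `decoupled_tissue`, a fraction of the responsive genes gets a protein
#' effect of opposite sign to the transcript effect, emulating the observed
#' post-transcriptional decoupling in the fat body where roughly half of the
#' regulated proteins move against their transcripts.
#'
#' Effect magnitudes are drawn uniformly on \[`min_main_effect`,
#' `max_main_effect`\] (log2 scale) with random sign; interactions likewise on
#' the interaction bounds. Negative-binomial dispersions are log-normal and
#' count baselines log-normal; protein baselines Gaussian on the log2 scale.
#'
#' @param responsive_fraction Probability a gene has a genotype main effect
#'   in a given tissue.
#' @param wolbachia_dependent_fraction Probability a gene is
#'   Wolbachia-dependent in `wolbachia_dependent_tissue`. Must satisfy
#'   `wolbachia_dependent_fraction + responsive_fraction <= 1` (the classes
#'   partition the genes there).
#' @param wolbachia_dependent_tissue Tissue carrying the interaction effects.
#' @param decoupled_fraction Fraction of responsive genes in
#'   `decoupled_tissue` whose protein effect opposes the transcript effect.
#' @param decoupled_tissue Tissue with transcript-protein decoupling.
#' @param min_main_effect,max_main_effect Bounds of |log2 fold change| for
#'   main effects.
#' @param min_interaction_effect,max_interaction_effect Bounds of
#'   |interaction log2 fold change|. Defaults are sqrt(2) times the
#'   main-effect bounds: in a balanced 2x2 the interaction contrast has a
#'   sqrt(2) larger standard error, so equally detectable interactions need
#'   proportionally larger magnitudes.
#' @param n_modules Number of network/annotation modules genes are assigned
#'   to (uniformly).
#' @param dispersion_meanlog,dispersion_sdlog Log-normal parameters of the
#'   per-feature NB dispersion.
#' @param baseline_count_meanlog,baseline_count_sdlog Log-normal parameters
#'   of baseline counts.
#' @param baseline_intensity_mean,baseline_intensity_sd Gaussian parameters
#'   of baseline log2 protein intensity.
#' @return A named list of class `truth_params`.
#' @export
truth_params <- function(responsive_fraction = 0.25,
                         wolbachia_dependent_fraction = 0.10,
                         wolbachia_dependent_tissue = "fat",
                         decoupled_fraction = 0.5,
                         decoupled_tissue = "fat",
                         min_main_effect = 1, max_main_effect = 2,
                         min_interaction_effect = 1.5,
                         max_interaction_effect = 2.5,
                         n_modules = 4L,
                         dispersion_meanlog = log(0.05),
                         dispersion_sdlog = 0.5,
                         baseline_count_meanlog = log(200),
                         baseline_count_sdlog = 1,
                         baseline_intensity_mean = 25,
                         baseline_intensity_sd = 2) {
  p <- as.list(environment())
  fr <- c("responsive_fraction", "wolbachia_dependent_fraction",
          "decoupled_fraction")
  for (f in fr) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop("parameter '", f, "' must be a single value in [0, 1]")
    }
  }
  if (p$wolbachia_dependent_fraction + p$responsive_fraction > 1) {
    stop("inconsistent fractions: wolbachia_dependent_fraction + ",
         "responsive_fraction = ",
         p$wolbachia_dependent_fraction + p$responsive_fraction,
         " exceeds 1 (mutually exclusive gene classes)")
  }
  if (p$min_main_effect < 0 || p$max_main_effect < p$min_main_effect) {
    stop("main-effect bounds must satisfy 0 <= min <= max")
  }
  if (p$min_interaction_effect < 0 ||
      p$max_interaction_effect < p$min_interaction_effect) {
    stop("interaction-effect bounds must satisfy 0 <= min <= max")
  }
  if (p$n_modules < 1L) stop("n_modules must be >= 1")
  structure(p, class = "truth_params")
}

#' Generate the ground truth underlying a simulated study
#'
#' Draws, for every gene and tissue, the transcript and protein main-effect
#' log2 fold changes, the Wolbachia x genotype interaction, and the
#' Wolbachia-dependent and decoupled flags; per-feature NB dispersions and
#' baselines; and a module assignment used by the network generator.
#' Transposon features carry transcript effects and dispersions only.
#'
#' @param n_genes Number of genes (>= 10).
#' @param n_transposons Number of transposon features.
#' @param params A [truth_params()] list.
#' @param seed Integer seed; identical seeds give identical truth.
#' @param tissues Tissue names.
#' @return A `ground_truth` list with elements `genes`, `transposons`,
#'   `features`, `feature_class`, `tissues`, effect matrices `beta_t`
#'   (features x tissues), `beta_p` (genes x tissues), `gamma`
#'   (features x tissues), logical matrices `wolbachia_dependent`
#'   (features x tissues) and `decoupled` (genes x tissues), `module`
#'   (per gene), `phi` and `baseline_count` (per feature),
#'   `baseline_intensity` (per gene), and `params`.
#' @examples
#' tr <- generate_truth(n_genes = 50, n_transposons = 5, seed = 1)
#' colSums(tr$wolbachia_dependent)
#' @export
generate_truth <- function(n_genes, n_transposons = 0L,
                           params = truth_params(), seed = 1L,
                           tissues = c("fat", "gut", "brain", "thorax")) {
  if (!inherits(params, "truth_params")) params <- do.call(truth_params, params)
  if (n_genes < 10L) stop("n_genes must be >= 10")
  set.seed(derive_seed(seed, "truth"))
  genes <- sprintf("g%04d", seq_len(n_genes))
  tes <- if (n_transposons > 0L) sprintf("te%03d", seq_len(n_transposons)) else character()
  features <- c(genes, tes)
  fclass <- c(rep("gene", n_genes), rep("transposon", n_transposons))
  nf <- length(features)
  nt <- length(tissues)

  draw_effect <- function(n, lo, hi) {
    runif(n, lo, hi) * sample(c(-1, 1), n, replace = TRUE)
  }

  beta_t <- matrix(0, nf, nt, dimnames = list(features, tissues))
  beta_p <- matrix(0, n_genes, nt, dimnames = list(genes, tissues))
  gamma <- matrix(0, nf, nt, dimnames = list(features, tissues))
  wdep <- matrix(FALSE, nf, nt, dimnames = list(features, tissues))
  decoupled <- matrix(FALSE, n_genes, nt, dimnames = list(genes, tissues))

  for (tau in tissues) {
    u <- runif(nf)
    is_wdep_tissue <- identical(tau, params$wolbachia_dependent_tissue)
    if (is_wdep_tissue) {
      dep <- u < params$wolbachia_dependent_fraction
      resp <- !dep & u < params$wolbachia_dependent_fraction + params$responsive_fraction
    } else {
      dep <- rep(FALSE, nf)
      resp <- u < params$responsive_fraction
    }
    active <- dep | resp
    na <- sum(active)
    beta_t[active, tau] <- draw_effect(na, params$min_main_effect,
                                       params$max_main_effect)
    if (any(dep)) {
      gamma[dep, tau] <- draw_effect(sum(dep), params$min_interaction_effect,
                                     params$max_interaction_effect)
      wdep[dep, tau] <- TRUE
    }
    # protein effects follow transcripts except for decoupled genes
    ag <- active[seq_len(n_genes)]
    mag <- runif(n_genes, params$min_main_effect, params$max_main_effect)
    sgn <- sign(beta_t[seq_len(n_genes), tau])
    if (identical(tau, params$decoupled_tissue) && params$decoupled_fraction > 0) {
      dec <- ag & (runif(n_genes) < params$decoupled_fraction)
      decoupled[dec, tau] <- TRUE
      sgn[dec] <- -sgn[dec]
    }
    beta_p[ag, tau] <- (mag * sgn)[ag]
  }

  structure(list(
    genes = genes, transposons = tes, features = features,
    feature_class = setNames(fclass, features), tissues = tissues,
    beta_t = beta_t, beta_p = beta_p, gamma = gamma,
    wolbachia_dependent = wdep, decoupled = decoupled,
    module = setNames(sample(seq_len(params$n_modules), n_genes, replace = TRUE),
                      genes),
    phi = setNames(rlnorm(nf, params$dispersion_meanlog,
                          params$dispersion_sdlog), features),
    baseline_count = setNames(rlnorm(nf, params$baseline_count_meanlog,
                                     params$baseline_count_sdlog), features),
    baseline_intensity = setNames(rnorm(n_genes, params$baseline_intensity_mean,
                                        params$baseline_intensity_sd), genes),
    params = params
  ), class = "ground_truth")
}
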