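## Per-sample log2 expected shift for a feature set, given truth effects.
## Model: log2 mu = baseline + (beta - gamma) * mutant + gamma * mutant * Wplus,
## so the mutant-control contrast is beta in Wolbachia-plus samples and
## beta - gamma in Wolbachia-minus samples (interaction = gamma).
truth_log2_shift <- function(beta, gamma, design_rows) {
  mut <- as.numeric(design_rows$genotype == "mutant")
  wp <- as.numeric(design_rows$wolbachia == "plus")
  outer(beta - gamma, mut) + outer(gamma, mut * wp)
}

#' Simulate RNA-seq counts from a ground truth
#'
#' Draws negative-binomial counts for every transcript-assay sample in the
#' design, with mean `size_factor * baseline * 2^shift` where the shift is
#' the design-dependent transcript log2 fold change, and per-feature
#' dispersion from the truth. Transposon features are included and labelled
#' via the returned feature-class attribute.
#'
#' @param truth A [generate_truth()] object.
#' @param design A [sim_design()] table containing transcript samples.
#' @param seed Integer seed.
#' @param size_factors Optional named per-sample scaling (default 1).
#' @return Integer matrix features x samples with attributes
#'   `feature_class` (named character) and `size_factors`.
#' @export
simulate_counts <- function(truth, design, seed = 1L, size_factors = NULL) {
  d <- design_subset(design, assay = "transcript")
  if (nrow(d) == 0L) stop("design contains no transcript-assay samples")
  set.seed(derive_seed(seed, "counts"))
  sf <- rep(1, nrow(d))
  names(sf) <- d$sample_id
  if (!is.null(size_factors)) {
    if (is.null(names(size_factors))) {
      stopifnot(length(size_factors) == nrow(d))
      sf[] <- size_factors
    } else {
      sf[names(size_factors)] <- size_factors
    }
  }
  nf <- length(truth$features)
  out <- matrix(0L, nf, nrow(d), dimnames = list(truth$features, d$sample_id))
  for (tau in unique(d$tissue)) {
    rows <- d[d$tissue == tau, , drop = FALSE]
    shift <- truth_log2_shift(truth$beta_t[, tau], truth$gamma[, tau], rows)
    mu <- truth$baseline_count * 2^shift * rep(sf[rows$sample_id], each = nf)
    phi <- rep(truth$phi, times = nrow(rows))
    y <- ifelse(phi < 1e-10,
                stats::rpois(length(mu), mu),
                rnbinom(length(mu), size = 1 / phi, mu = mu))
    out[, rows$sample_id] <- as.integer(y)
  }
  attr(out, "feature_class") <- truth$feature_class
  attr(out, "size_factors") <- sf
  out
}

#' Dropout-curve parameters for simulated proteomic missingness
#'
#' Missingness probability is `max_rate * plogis((midpoint - x) / scale)`
#' in the true log2 intensity `x`: monotone non-increasing in intensity,
#' approximating the left-censored missingness of label-free quantification
#' that motivates down-shifted imputation. `scale = 0` gives a hard step at
#' `midpoint`. The default midpoint sits 2.5 baseline SDs below the mean
#' baseline abundance, placing the detection limit in the low-abundance tail
#' (overall missingness around 4-10%, concentrated in weak proteins) rather
#' than across the bulk of the distribution.
#'
#' @param midpoint Intensity at which the (scaled) dropout rate is halved.
#' @param scale Logistic steepness (>= 0).
#' @param max_rate Maximal dropout probability, in \[0, 1\].
#' @return A named list of class `dropout_params`.
#' @export
dropout_params <- function(midpoint = 20, scale = 1, max_rate = 0.9) {
  if (!is.numeric(max_rate) || max_rate < 0 || max_rate > 1) {
    stop("max_rate must lie in [0, 1]")
  }
  if (scale < 0) stop("scale must be >= 0")
  structure(list(midpoint = midpoint, scale = scale, max_rate = max_rate),
            class = "dropout_params")
}

dropout_prob <- function(x, mp) {
  if (mp$scale == 0) {
    mp$max_rate * as.numeric(x < mp$midpoint)
  } else {
    mp$max_rate * plogis((mp$midpoint - x) / mp$scale)
  }
}

#' Simulate log2 label-free protein intensities with missingness
#'
#' Intensities are `baseline + protein log2 fold change + N(0, noise_sd)`;
#' cells are then set missing by intensity-dependent Bernoulli dropout
#' (see [dropout_params()]). Only gene features are quantified (transposons
#' have no protein counterpart).
#'
#' @param truth A [generate_truth()] object.
#' @param design A [sim_design()] table containing protein samples.
#' @param noise_sd Gaussian noise SD on the log2 scale (> 0).
#' @param missing_params A [dropout_params()] list.
#' @param seed Integer seed.
#' @return Numeric matrix genes x samples with `NA` for missing cells and a
#'   logical attribute `mask` (TRUE where missing).
#' @export
simulate_intensities <- function(truth, design, noise_sd = 0.3,
                                 missing_params = dropout_params(),
                                 seed = 1L) {
  d <- design_subset(design, assay = "protein")
  if (nrow(d) == 0L) stop("design contains no protein-assay samples")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0")
  if (!inherits(missing_params, "dropout_params")) {
    missing_params <- do.call(dropout_params, missing_params)
  }
  set.seed(derive_seed(seed, "intensities"))
  ng <- length(truth$genes)
  out <- matrix(NA_real_, ng, nrow(d), dimnames = list(truth$genes, d$sample_id))
  for (tau in unique(d$tissue)) {
    rows <- d[d$tissue == tau, , drop = FALSE]
    shift <- truth_log2_shift(truth$beta_p[, tau],
                              truth$gamma[seq_len(ng), tau], rows)
    x <- truth$baseline_intensity + shift +
      rnorm(ng * nrow(rows), sd = noise_sd)
    out[, rows$sample_id] <- x
  }
  truth_mat <- out
  p <- dropout_prob(out, missing_params)
  mask <- matrix(runif(length(out)) < p, ng, dimnames = dimnames(out))
  out[mask] <- NA_real_
  attr(out, "mask") <- mask
  attr(out, "true_values") <- truth_mat
  out
}
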