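#' Filter features on minimum valid values per category
#'
#' Retains features with at least `min_valid` observed (non-missing) values
#' in at least one of the four genotype x Wolbachia categories of a
#' one-tissue intensity matrix, the standard validity filter applied to
#' log2 label-free intensities before imputation.
#'
#' @param m Numeric matrix (features x samples) with `NA` for missing cells.
#' @param design Design table covering `colnames(m)`.
#' @param min_valid Minimum observed values required in some category.
#' @return The filtered matrix (same samples, subset of rows, order kept).
#' @export
filter_min_valid <- function(m, design, min_valid = 4L) {
  d <- design_subset(design)
  d <- d[match(colnames(m), d$sample_id), , drop = FALSE]
  if (anyNA(d$sample_id)) stop("matrix columns missing from design")
  cat4 <- interaction(d$genotype, d$wolbachia, drop = TRUE)
  if (nlevels(cat4) < 4L) {
    stop("design must contain all four genotype x wolbachia categories")
  }
  if (min_valid > max(table(cat4))) {
    stop("min_valid (", min_valid, ") exceeds the largest category size (",
         max(table(cat4)), "); no feature could pass")
  }
  valid_per_cat <- vapply(levels(cat4), function(l) {
    rowSums(!is.na(m[, cat4 == l, drop = FALSE]))
  }, numeric(nrow(m)))
  keep <- apply(valid_per_cat >= min_valid, 1L, any)
  m[keep, , drop = FALSE]
}

#' Impute missing intensities from a down-shifted normal distribution
#'
#' Replaces each missing cell, separately per column, by a draw from
#' `Normal(mean_col - shift * sd_col, width * sd_col)`, where the mean and
#' SD are computed from the column's observed values only. This emulates
#' values below the detection limit of label-free quantification. Defaults
#' (`width = 0.3`, `shift = 1.8`) are the conventional settings. A column
#' whose observed values are constant (zero SD) imputes the constant mean.
#'
#' @param m Numeric matrix with `NA` for missing cells.
#' @param width Imputation SD as a multiple of the column SD.
#' @param shift Downward shift as a multiple of the column SD.
#' @param seed Integer seed for the random draws.
#' @return Matrix without missing cells; observed cells are unchanged.
#' @export
impute_downshifted <- function(m, width = 0.3, shift = 1.8, seed = 1L) {
  stopifnot(is.matrix(m), width >= 0, shift >= 0)
  n_obs <- colSums(!is.na(m))
  if (any(n_obs < 2L)) {
    stop("columns with fewer than 2 observed values: ",
         paste(colnames(m)[n_obs < 2L], collapse = ", "))
  }
  if (!anyNA(m)) return(m)
  set.seed(derive_seed(seed, "impute"))
  out <- m
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (!any(miss)) next
    obs <- m[!miss, j]
    mu <- mean(obs)
    s <- sd(obs)
    out[miss, j] <- rnorm(sum(miss), mean = mu - shift * s, sd = width * s)
  }
  out
}
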