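## The three contrasts of the 2x2 factorial, on treatment coding with
## control / Wolbachia-minus as reference:
##   main_plus   mutant - control within Wolbachia-plus
##   main_minus  mutant - control within Wolbachia-minus
##   interaction main_plus - main_minus
intensity_contrasts <- function() {
  list(main_plus = c(0, 1, 0, 1),
       main_minus = c(0, 1, 0, 0),
       interaction = c(0, 0, 0, 1))
}

factorial_model_matrix <- function(d) {
  cells <- table(d$genotype, d$wolbachia)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)
    stop("rank-deficient design; empty cell(s): ",
         paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
               sep = "/", collapse = ", "))
  }
  mut <- as.numeric(d$genotype == "mutant")
  wp <- as.numeric(d$wolbachia == "plus")
  X <- cbind(intercept = 1, genotype = mut, wolbachia = wp,
             interaction = mut * wp)
  rownames(X) <- d$sample_id
  X
}

#' Fit per-feature two-factor linear models to log2 intensities
#'
#' Ordinary least squares of each feature on genotype, Wolbachia status and
#' their interaction (treatment coding, control/Wolbachia-minus reference),
#' for one tissue. The matrix must be complete (run [impute_downshifted()]
#' first).
#'
#' @param m Complete numeric matrix, features x samples.
#' @param design Design table covering the columns of `m`.
#' @return An `intensity_fit` list: `coefficients` (features x 4), `s2`
#'   (residual variances), `df` (residual degrees of freedom,
#'   `n_samples - 4`), `xtx_inv`, and `design`.
#' @export
fit_intensity_model <- function(m, design) {
  if (anyNA(m)) stop("intensity matrix must be complete (impute first)")
  d <- design_subset(design)
  d <- d[match(colnames(m), d$sample_id), , drop = FALSE]
  if (anyNA(d$sample_id)) stop("matrix columns missing from design")
  X <- factorial_model_matrix(d)
  xtx_inv <- solve(crossprod(X))
  B <- m %*% X %*% xtx_inv
  E <- m - B %*% t(X)
  df <- ncol(m) - ncol(X)
  if (df < 1L) stop("no residual degrees of freedom (need > 4 samples)")
  structure(list(coefficients = B, s2 = rowSums(E^2) / df, df = df,
                 xtx_inv = xtx_inv, design = d),
            class = "intensity_fit")
}

## Newton inversion of the trigamma function (for prior-df estimation).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks per-feature residual variances toward a pooled prior by modelling
#' the sample variances as scaled F draws. The prior degrees of freedom and
#' prior variance are estimated by the method of moments on `log(s2)`:
#' under `s2 ~ s0^2 * F(df, d0)`, `var(log s2) = trigamma(df/2) +
#' trigamma(d0/2)` and `mean(log s2)` pins down `s0^2`, so `d0` is obtained
#' by trigamma inversion. Posterior variances are
#' `(d0 * s0^2 + df * s2) / (d0 + df)`; if the excess variance of `log s2`
#' is non-positive, `d0 = Inf` and every posterior variance equals `s0^2`.
#'
#' @param s2 Per-feature residual variances (>= 10 features).
#' @param df Common residual degrees of freedom.
#' @return List with `var_post`, `df_prior` (`d0`, possibly `Inf`) and
#'   `var_prior` (`s0^2`).
#' @export
moderate_variances <- function(s2, df) {
  if (length(s2) < 10L) stop("need at least 10 features to estimate the prior")
  if (df <= 0) stop("df must be positive")
  pos <- s2 > 0
  if (sum(pos) < 10L) stop("need at least 10 features with positive variance")
  z <- log(s2[pos])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(z) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    var_post <- (d0 * s0 + df * s2) / (d0 + df)
  } else {
    # no excess variability beyond chi-square sampling noise: infinite prior
    # df, pooled variance is the plain mean
    d0 <- Inf
    s0 <- mean(s2)
    var_post <- rep(s0, length(s2))
  }
  names(var_post) <- names(s2)
  list(var_post = var_post, df_prior = d0, var_prior = s0)
}

#' Moderated t-test of a factorial contrast
#'
#' Tests `c' beta = 0` per feature using the moderated variances: the
#' standard error combines the posterior variance with the design's contrast
#' variance factor, and the statistic is referred to a t distribution with
#' `df_residual + df_prior` degrees of freedom (two-sided).
#'
#' @param fit An [fit_intensity_model()] object.
#' @param moderated Result of [moderate_variances()] on `fit$s2`.
#' @param contrast One of `"main_plus"`, `"main_minus"`, `"interaction"`, or
#'   a numeric contrast vector of length 4.
#' @return data.frame with `feature`, `contrast`, `lfc`, `se`, `statistic`,
#'   `df`, `p` (unadjusted).
#' @export
test_contrast <- function(fit, moderated, contrast) {
  if (is.character(contrast)) {
    cname <- match.arg(contrast, names(intensity_contrasts()))
    cvec <- intensity_contrasts()[[cname]]
  } else {
    cvec <- contrast
    cname <- "custom"
  }
  if (length(cvec) != ncol(fit$coefficients)) stop("contrast length mismatch")
  if (all(cvec == 0)) stop("zero contrast vector")
  vf <- drop(t(cvec) %*% fit$xtx_inv %*% cvec)
  lfc <- drop(fit$coefficients %*% cvec)
  df_total <- fit$df + moderated$df_prior
  se <- sqrt(vf * moderated$var_post)
  stat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * pt(abs(stat), df = df_total, lower.tail = FALSE)
  p[stat == 0] <- 1
  data.frame(feature = rownames(fit$coefficients), contrast = cname,
             lfc = lfc, se = se, statistic = stat,
             df = rep(df_total, length(lfc)), p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-tissue moderated differential expression of log2 intensities
#'
#' Runs the full intensity pipeline for one tissue: factorial fit, variance
#' moderation, the three contrasts (genotype effect with and without
#' Wolbachia, and their interaction), and Benjamini-Hochberg adjustment per
#' contrast (one multiplicity family per tissue and contrast).
#'
#' @param m Complete intensity matrix for one tissue.
#' @param design Design table.
#' @param tissue Tissue label recorded in the output.
#' @return data.frame with one row per feature x contrast: `feature`,
#'   `tissue`, `contrast`, `lfc`, `se`, `statistic`, `df`, `p`, `adjP`.
#' @export
de_intensity <- function(m, design, tissue = NA_character_) {
  fit <- fit_intensity_model(m, design)
  mod <- moderate_variances(fit$s2, fit$df)
  res <- do.call(rbind, lapply(names(intensity_contrasts()), function(cn) {
    r <- test_contrast(fit, mod, cn)
    r$adjP <- adjust_bh(r$p)
    r
  }))
  res$tissue <- tissue
  res[, c("feature", "tissue", "contrast", "lfc", "se", "statistic",
          "df", "p", "adjP")]
}
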