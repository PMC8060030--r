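#' Median-of-ratios size factors on combined gene and transposon counts
#'
#' Computes per-sample normalization factors from the ratio of each sample
#' to the per-feature geometric-mean reference, taking the median over
#' features with all-positive counts, and rescales the factors to geometric
#' mean 1. Gene and transposon rows are used jointly, which stabilises the
#' factors for the sparse transposon class.
#'
#' @param counts Integer matrix, features x samples.
#' @return Named numeric vector of positive size factors (geometric mean 1).
#' @export
estimate_size_factors <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no feature with positive counts in all samples")
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(lg, 2L, function(x) exp(median(x - ref)))
  sf / exp(mean(log(sf)))
}

nb_loglik <- function(y, mu, phi) {
  if (phi < 1e-10) {
    sum(stats::dpois(y, mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
}

## IRLS for a negative-binomial GLM with log link, fixed dispersion and
## offsets. Step-halving keeps the likelihood non-decreasing.
nb_irls <- function(y, X, offset, phi, max_iter = 50L, tol = 1e-10) {
  z0 <- log((y + 0.5) / exp(offset))
  beta <- qr.coef(qr(X), z0)
  beta[is.na(beta)] <- 0
  eta <- drop(X %*% beta) + offset
  mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
  ll <- nb_loglik(y, mu, phi)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    xtw <- t(X * w)
    beta_new <- tryCatch(drop(solve(xtw %*% X, xtw %*% z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    step <- beta_new - beta
    fac <- 1
    repeat {
      cand <- beta + fac * step
      eta_c <- drop(X %*% cand) + offset
      mu_c <- pmin(pmax(exp(eta_c), 1e-10), 1e12)
      ll_c <- nb_loglik(y, mu_c, phi)
      if (is.finite(ll_c) && ll_c >= ll - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-8) {
        cand <- beta; eta_c <- eta; mu_c <- mu; ll_c <- ll
        break
      }
    }
    delta <- ll_c - ll
    beta <- cand; eta <- eta_c; mu <- mu_c; ll <- ll_c
    if (abs(delta) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, loglik = ll, converged = converged)
}

## Design matrices for the nested models. The full model parameterizes the
## genotype effect separately within each Wolbachia state, so each test drops
## (or merges) exactly one column:
##   main_plus    drop the mutant-within-Wplus column
##   main_minus   drop the mutant-within-Wminus column
##   interaction  merge the two genotype columns into one common effect
count_model_matrices <- function(d) {
  cells <- table(d$genotype, d$wolbachia)
  if (any(cells == 0L)) stop("empty genotype x wolbachia cell in design")
  mut <- as.numeric(d$genotype == "mutant")
  wp <- as.numeric(d$wolbachia == "plus")
  full <- cbind(intercept = 1, wplus = wp, mut_wp = mut * wp,
                mut_wm = mut * (1 - wp))
  list(
    full = full,
    main_plus = full[, c("intercept", "wplus", "mut_wm"), drop = FALSE],
    main_minus = full[, c("intercept", "wplus", "mut_wp"), drop = FALSE],
    interaction = cbind(intercept = 1, wplus = wp, mut = mut)
  )
}

#' Estimate per-feature NB dispersions with trend shrinkage
#'
#' For each feature the dispersion is estimated by maximising the Cox-Reid
#' adjusted profile likelihood at the factorial cell means (normalized by
#' the size factors): the adjustment `-0.5 * log det(X' W X)` compensates
#' the downward bias of plug-in mean estimates at few replicates. Estimates
#' are then shrunk on the log scale toward a log-linear mean-dispersion
#' trend fitted across all features, with a fixed prior weight, and floored
#' at `floor`. All-zero features are excluded from the trend and assigned
#' the floor. Gene and transposon rows should be supplied jointly.
#'
#' @param counts Integer matrix for one tissue, features x samples.
#' @param design Design table covering the columns (with >= 2 replicates in
#'   at least one genotype x wolbachia cell).
#' @param size_factors Optional precomputed factors
#'   (default [estimate_size_factors()]).
#' @param prior_weight Weight of the trend relative to the per-feature
#'   residual degrees of freedom.
#' @param floor Minimal dispersion.
#' @return Named numeric vector of dispersions.
#' @export
estimate_dispersions <- function(counts, design, size_factors = NULL,
                                 prior_weight = 10, floor = 1e-4) {
  d <- design_subset(design)
  d <- d[match(colnames(counts), d$sample_id), , drop = FALSE]
  if (anyNA(d$sample_id)) stop("count columns missing from design")
  cell <- interaction(d$genotype, d$wolbachia, drop = TRUE)
  if (max(table(cell)) < 2L) {
    stop("dispersion unidentifiable: no cell has replicates")
  }
  sf <- size_factors %||% estimate_size_factors(counts)
  # fitted means from normalized cell means (exact in the Poisson limit)
  mu <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (l in levels(cell)) {
    j <- which(cell == l)
    q <- rowSums(counts[, j, drop = FALSE]) / sum(sf[j])
    mu[, j] <- outer(q, sf[j])
  }
  X <- count_model_matrices(d)$full
  nonzero <- rowSums(counts) > 0
  raw <- rep(floor, nrow(counts))
  names(raw) <- rownames(counts)
  for (g in which(nonzero)) {
    y <- counts[g, ]
    m <- pmax(mu[g, ], 1e-10)
    apl <- function(lp) {
      phi <- exp(lp)
      w <- m / (1 + phi * m)
      cr <- 0.5 * determinant(crossprod(X * sqrt(w)), logarithm = TRUE)$modulus
      -(nb_loglik(y, m, phi) - cr)
    }
    opt <- optimize(apl, interval = c(log(1e-8), log(30)))
    raw[g] <- exp(opt$minimum)
  }
  base_mean <- rowMeans(sweep(counts, 2L, sf, "/"))
  interior <- nonzero & base_mean > 0 & raw > 1e-6
  disp <- raw
  if (sum(interior) >= 10L) {
    # robust log-linear trend: fit on interior estimates, then recenter the
    # intercept on the residual median so the skewed left tail of per-feature
    # estimates does not drag the trend (and hence all tests) liberal
    fit <- lm.fit(cbind(1, log(base_mean[interior])), log(raw[interior]))
    co <- fit$coefficients
    co[1] <- co[1] + median(fit$residuals)
    trend <- drop(cbind(1, log(pmax(base_mean, 1e-8))) %*% co)
    w <- max(ncol(counts) - 4L, 1L)
    est <- nonzero & base_mean > 0
    disp[est] <- exp((prior_weight * trend[est] +
                        w * log(pmax(raw[est], floor))) / (prior_weight + w))
    # boundary estimates carry no usable per-feature signal: use the trend
    disp[est & raw <= 1e-6] <- exp(trend[est & raw <= 1e-6])
  }
  pmax(disp, floor)
}

#' Likelihood-ratio tests for the factorial NB GLM
#'
#' Fits the full two-factor negative-binomial GLM (log link, log size-factor
#' offsets, fixed per-feature dispersion) by iteratively reweighted least
#' squares and compares it to the reduced model lacking the tested term:
#' the genotype effect within Wolbachia-plus (`main_plus`), within
#' Wolbachia-minus (`main_minus`), or the Wolbachia x genotype interaction.
#' The statistic is `2 * (loglik_full - loglik_reduced)`, referred to a
#' chi-square with 1 degree of freedom. Features whose fits do not converge
#' are flagged (`converged = FALSE`) with `NA` statistics rather than
#' raising an error.
#'
#' @param counts Integer matrix for one tissue.
#' @param design Design table covering the columns.
#' @param dispersions Named per-feature dispersions
#'   (see [estimate_dispersions()]).
#' @param size_factors Optional per-sample factors.
#' @param tests Which of the three tests to compute.
#' @return data.frame with `feature`, `contrast`, `lfc` (log2), `statistic`,
#'   `df`, `p`, `converged`.
#' @export
nb_lrt <- function(counts, design, dispersions, size_factors = NULL,
                   tests = c("main_plus", "main_minus", "interaction")) {
  tests <- match.arg(tests, several.ok = TRUE)
  d <- design_subset(design)
  d <- d[match(colnames(counts), d$sample_id), , drop = FALSE]
  if (anyNA(d$sample_id)) stop("count columns missing from design")
  sf <- size_factors %||% estimate_size_factors(counts)
  offset <- log(sf)
  Xs <- count_model_matrices(d)
  feats <- rownames(counts)
  phi <- dispersions[feats]
  if (anyNA(phi)) stop("dispersions missing for some features")

  res <- vector("list", length(feats))
  for (g in seq_along(feats)) {
    y <- counts[g, ]
    full <- nb_irls(y, Xs$full, offset, phi[g])
    b <- full$beta
    lfc <- c(main_plus = unname(b["mut_wp"]) / log(2),
             main_minus = unname(b["mut_wm"]) / log(2),
             interaction = unname(b["mut_wp"] - b["mut_wm"]) / log(2))
    rows <- lapply(tests, function(te) {
      red <- nb_irls(y, Xs[[te]], offset, phi[g])
      ok <- full$converged && red$converged
      stat <- if (ok) max(0, 2 * (full$loglik - red$loglik)) else NA_real_
      pval <- if (ok) {
        max(pchisq(stat, df = 1, lower.tail = FALSE), .Machine$double.xmin)
      } else NA_real_
      data.frame(feature = feats[g], contrast = te, lfc = lfc[[te]],
                 statistic = stat, df = 1,
                 p = pval,
                 converged = ok, stringsAsFactors = FALSE)
    })
    res[[g]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-tissue count-based differential expression for genes and transposons
#'
#' Full count pipeline for one tissue: combined-feature size factors and
#' dispersion trend, independent-filtering-style removal of features whose
#' mean normalized count is below `min_mean_count`, the three
#' likelihood-ratio tests, and Benjamini-Hochberg adjustment per feature
#' class (genes and transposons form separate multiplicity families) and
#' contrast.
#'
#' @param counts Integer matrix for one tissue (genes + transposons).
#' @param design Design table.
#' @param feature_class Named character (`"gene"`/`"transposon"`); defaults
#'   to the matrix's `feature_class` attribute, else all `"gene"`.
#' @param tissue Tissue label recorded in the output.
#' @param min_mean_count Mean-normalized-count filter applied before testing.
#' @return data.frame: `feature`, `class`, `tissue`, `contrast`, `lfc`,
#'   `statistic`, `df`, `p`, `adjP`, `converged`.
#' @export
de_counts <- function(counts, design, feature_class = NULL,
                      tissue = NA_character_, min_mean_count = 1) {
  fc <- feature_class %||% attr(counts, "feature_class") %||%
    setNames(rep("gene", nrow(counts)), rownames(counts))
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersions(counts, design, size_factors = sf)
  keep <- rowMeans(sweep(counts, 2L, sf, "/")) >= min_mean_count
  res <- nb_lrt(counts[keep, , drop = FALSE], design, disp, size_factors = sf)
  res$class <- unname(fc[res$feature])
  res$tissue <- tissue
  res$adjP <- NA_real_
  for (cl in unique(res$class)) {
    for (te in unique(res$contrast)) {
      i <- res$class == cl & res$contrast == te & !is.na(res$p)
      if (any(i)) res$adjP[i] <- adjust_bh(res$p[i])
    }
  }
  res[, c("feature", "class", "tissue", "contrast", "lfc", "statistic",
          "df", "p", "adjP", "converged")]
}
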