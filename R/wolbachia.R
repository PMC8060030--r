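#' Data-driven equivalence threshold for interaction fold changes
#'
#' The equivalence bound `t` is the mean over tissues of the per-tissue
#' median absolute interaction log2 fold change. Signed medians would sit
#' near zero by symmetry, so absolute values are used; with per-tissue
#' medians of 0.10, 0.06, 0.08 and 0.10 this yields t = 0.085.
#'
#' @param interaction_de data.frame with columns `tissue` and `lfc`
#'   (interaction estimates, all tested features).
#' @return Single non-negative threshold `t`.
#' @export
equivalence_threshold <- function(interaction_de) {
  if (is.null(interaction_de) || nrow(interaction_de) == 0L) {
    stop("no interaction estimates supplied")
  }
  med <- tapply(abs(interaction_de$lfc), interaction_de$tissue, median,
                na.rm = TRUE)
  mean(med)
}

#' Two one-sided tests (TOST) of fold-change equivalence
#'
#' A feature's genotype effect is equivalent across Wolbachia states when
#' the `level` confidence interval of its interaction log2 fold change lies
#' inside `[-t, t]`. The TOST p-value is the larger of the two one-sided
#' t-test p-values against the bounds; at `level = 0.90` the CI criterion is
#' exactly `tost_p <= 0.05` (duality of the two formulations). Vectorized
#' over features.
#'
#' @param lfc Interaction log2 fold change(s).
#' @param se Standard error(s), > 0.
#' @param df Degrees of freedom.
#' @param t Equivalence bound (>= 0), e.g. from [equivalence_threshold()].
#' @param level Confidence level of the interval.
#' @return data.frame with `lfc`, `ci_lo`, `ci_hi`, `tost_p`, `equivalent`.
#' @export
tost_equivalence <- function(lfc, se, df, t, level = 0.90) {
  if (any(se <= 0)) stop("se must be > 0")
  if (any(df <= 0)) stop("df must be > 0")
  if (t < 0) stop("equivalence bound t must be >= 0")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  q <- qt((1 + level) / 2, df)
  ci_lo <- lfc - q * se
  ci_hi <- lfc + q * se
  p_lower <- pt((lfc + t) / se, df, lower.tail = FALSE)  # H0: lfc <= -t
  p_upper <- pt((lfc - t) / se, df, lower.tail = TRUE)   # H0: lfc >= t
  data.frame(lfc = lfc, ci_lo = ci_lo, ci_hi = ci_hi,
             tost_p = pmax(p_lower, p_upper),
             equivalent = ci_lo >= -t & ci_hi <= t)
}

#' Classify features as Wolbachia-dependent or -independent
#'
#' Applies the double-significance rule per feature and tissue:
#' *dependent* if both the genotype main effect (Wolbachia-plus) and the
#' interaction are significant at `alpha` (BH-adjusted); otherwise
#' *independent* if the main effect is significant and the interaction is
#' TOST-equivalent within `[-t, t]`; otherwise *unclassified* if only the
#' main effect is significant; else *not_insulin_responsive*. Equivalence is
#' evaluated only for insulin-responsive features (those passing the
#' main-effect gate).
#'
#' @param main_de data.frame of main-effect results (`feature`, `tissue`,
#'   `adjP`), typically the `main_plus` contrast.
#' @param interaction_de data.frame of interaction results (`feature`,
#'   `tissue`, `lfc`, `se`, `df`, `adjP`).
#' @param t Equivalence bound; `NULL` recomputes it from `interaction_de`
#'   via [equivalence_threshold()]. Use `t = 0.085` to fix the conventional
#'   constant.
#' @param alpha Significance threshold on adjusted p-values.
#' @param level TOST confidence level.
#' @return data.frame with `feature`, `tissue`, `call`, `interaction_lfc`,
#'   `ci_lo`, `ci_hi`, `tost_p`, `t`.
#' @export
classify_wolbachia <- function(main_de, interaction_de, t = NULL,
                               alpha = 0.1, level = 0.90) {
  key_m <- paste(main_de$feature, main_de$tissue)
  key_i <- paste(interaction_de$feature, interaction_de$tissue)
  if (!setequal(key_m, key_i)) {
    d1 <- setdiff(key_m, key_i)
    d2 <- setdiff(key_i, key_m)
    stop("main and interaction results are misaligned; only in main: ",
         paste(head(d1, 5), collapse = ", "), "; only in interaction: ",
         paste(head(d2, 5), collapse = ", "))
  }
  inter <- interaction_de[match(key_m, key_i), , drop = FALSE]
  if (is.null(t)) t <- equivalence_threshold(inter)
  tost <- tost_equivalence(inter$lfc, inter$se, inter$df, t, level)
  responsive <- !is.na(main_de$adjP) & main_de$adjP <= alpha
  inter_sig <- !is.na(inter$adjP) & inter$adjP <= alpha
  call <- ifelse(!responsive, "not_insulin_responsive",
          ifelse(inter_sig, "dependent",
          ifelse(tost$equivalent, "independent", "unclassified")))
  data.frame(feature = main_de$feature, tissue = main_de$tissue,
             call = call, interaction_lfc = inter$lfc,
             ci_lo = tost$ci_lo, ci_hi = tost$ci_hi, tost_p = tost$tost_p,
             t = t, row.names = NULL, stringsAsFactors = FALSE)
}
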