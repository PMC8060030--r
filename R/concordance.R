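#' Pair transcript and protein fold changes and classify direction quadrants
#'
#' Joins transcript and protein differential-expression results on the gene
#' identifier within one tissue, keeps pairs quantified in both assays whose
#' selected side is significant (`adjP <= alpha`), and labels each pair by
#' the signs of the two log2 fold changes: `both_up`, `both_down`, or
#' `opposite`. Pairs with an exactly zero fold change on either axis are
#' excluded from the quadrant tallies and counted separately.
#'
#' @param transcript_de data.frame with `feature`, `lfc`, `adjP` (one tissue,
#'   one contrast).
#' @param protein_de Same layout for proteins.
#' @param mapping Optional data.frame `gene`, `protein` mapping protein ids
#'   to gene ids; by default identifiers are shared. When several proteins
#'   map to one gene the protein with the smallest p-value (if a `p` column
#'   exists, else smallest `adjP`) represents the gene.
#' @param selection Which side's significance gates a pair into the analysis.
#' @param alpha Significance threshold on the adjusted p-values.
#' @return List with `pairs` (data.frame `gene`, `transcript_lfc`,
#'   `protein_lfc`, `quadrant`), `counts`, `percent` (rounded to 1 decimal),
#'   `n`, and `n_zero_lfc`.
#' @export
pair_and_classify <- function(transcript_de, protein_de, mapping = NULL,
                              selection = c("transcript", "protein"),
                              alpha = 0.1) {
  selection <- match.arg(selection)
  prot <- protein_de
  if (!is.null(mapping)) {
    m <- mapping[match(prot$feature, mapping$protein), "gene"]
    prot$feature <- ifelse(is.na(m), prot$feature, m)
  }
  if (anyDuplicated(prot$feature)) {
    crit <- if ("p" %in% names(prot)) prot$p else prot$adjP
    prot <- prot[order(prot$feature, crit), , drop = FALSE]
    prot <- prot[!duplicated(prot$feature), , drop = FALSE]
  }
  shared <- intersect(transcript_de$feature, prot$feature)
  if (length(shared) == 0L) stop("no gene quantified in both assays")
  tr <- transcript_de[match(shared, transcript_de$feature), , drop = FALSE]
  pr <- prot[match(shared, prot$feature), , drop = FALSE]
  gate <- if (selection == "transcript") tr$adjP else pr$adjP
  sel <- !is.na(gate) & gate <= alpha
  pairs <- data.frame(gene = shared[sel],
                      transcript_lfc = tr$lfc[sel],
                      protein_lfc = pr$lfc[sel],
                      stringsAsFactors = FALSE)
  zero <- pairs$transcript_lfc == 0 | pairs$protein_lfc == 0
  n_zero <- sum(zero)
  pairs <- pairs[!zero, , drop = FALSE]
  s <- sign(pairs$transcript_lfc) * sign(pairs$protein_lfc)
  pairs$quadrant <- ifelse(s < 0, "opposite",
                           ifelse(pairs$transcript_lfc > 0, "both_up",
                                  "both_down"))
  counts <- table(factor(pairs$quadrant,
                         levels = c("both_up", "both_down", "opposite")))
  n <- nrow(pairs)
  list(pairs = pairs, counts = as.vector(counts),
       percent = if (n > 0) round(100 * as.vector(counts) / n, 1) else
         rep(NA_real_, 3L),
       quadrants = names(counts), n = n, n_zero_lfc = n_zero)
}

#' Correlation of transcript and protein fold changes
#'
#' @param pairs A `pairs` data.frame from [pair_and_classify()] (or any
#'   data.frame with `transcript_lfc` and `protein_lfc`).
#' @param method Correlation type.
#' @return List with `r` and `n`.
#' @export
concordance_correlation <- function(pairs, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(pairs) < 3L) stop("need at least 3 pairs")
  x <- pairs$transcript_lfc
  y <- pairs$protein_lfc
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: zero variance on one axis")
  }
  list(r = stats::cor(x, y, method = method), n = nrow(pairs))
}
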