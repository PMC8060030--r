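#' Tissue-restricted background gene set for enrichment
#'
#' Proteomics backgrounds are the genes whose proteins were detected
#' (quantified) in the tissue; transcriptomics backgrounds are the genes
#' detected at a median raw count above five across the tissue's samples.
#'
#' @param x For `assay = "protein"`, a character vector of detected genes or
#'   an intensity matrix whose rownames are taken; for
#'   `assay = "transcript"`, a raw count matrix for the tissue's samples.
#' @param assay Which rule to apply.
#' @param min_median_count Count threshold (exclusive) for transcripts.
#' @return Character vector of background genes.
#' @export
define_background <- function(x, assay = c("protein", "transcript"),
                              min_median_count = 5) {
  assay <- match.arg(assay)
  bg <- if (assay == "protein") {
    if (is.matrix(x)) rownames(x)[rowSums(!is.na(x)) > 0] else as.character(x)
  } else {
    if (!is.matrix(x)) stop("transcript background needs a count matrix")
    rownames(x)[apply(x, 1L, median) > min_median_count]
  }
  if (length(bg) == 0L) stop("empty background")
  bg
}

#' Fisher enrichment tests of gene sets against a background
#'
#' One-sided (enrichment) Fisher exact test per term: the p-value is the
#' hypergeometric upper tail `P(X >= k)` for the overlap `k` between the
#' gene list (size `n`) and the background-restricted term (size `K`) in a
#' background of size `N`. Terms whose in-background size falls outside
#' `[min_size, max_size]` are skipped.
#'
#' @param gene_list Character vector, a subset of `background`.
#' @param background Character vector of background genes.
#' @param sets Named list of gene sets (term id -> member genes).
#' @param min_size,max_size In-background term-size bounds (default 5-1000).
#' @return data.frame per retained term: `term`, `k`, `n`, `K`, `N`,
#'   `odds_ratio`, `p`, and `total_annotations` (term size in the full,
#'   unrestricted collection, used later for primary-term selection).
#' @export
fisher_term_test <- function(gene_list, background, sets,
                             min_size = 5L, max_size = 1000L) {
  bad <- setdiff(gene_list, background)
  if (length(bad)) {
    stop("genes not in background: ", paste(head(bad, 5), collapse = ", "))
  }
  gene_list <- unique(gene_list)
  background <- unique(background)
  N <- length(background)
  n <- length(gene_list)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], background)
    K <- length(members)
    if (K < min_size || K > max_size) return(NULL)
    k <- length(intersect(members, gene_list))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - K - n + k)) / max((K - k) * (n - k), .Machine$double.eps)
    data.frame(term = id, k = k, n = n, K = K, N = N, odds_ratio = or,
               p = min(p, 1), total_annotations = length(sets[[id]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), odds_ratio = numeric(),
                      p = numeric(), total_annotations = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Redundancy reduction of enriched terms
#'
#' Terms whose gene-list overlaps differ by `max_diff` or fewer genes
#' (symmetric difference of the member genes present in `gene_list`) are
#' clustered together; clusters are the connected components of that
#' relation. Within each cluster the term with the smallest total annotation
#' count is flagged primary (ties broken by lexicographic term id), and
#' Benjamini-Hochberg adjustment is applied over the primary terms only.
#'
#' @param rows An [fisher_term_test()] table.
#' @param gene_list The gene list the rows were computed against.
#' @param sets The gene-set collection.
#' @param max_diff Maximal symmetric difference for clustering.
#' @return `rows` with added `cluster`, `primary`, and `adjP` (`NA` for
#'   non-primary terms).
#' @export
reduce_redundancy <- function(rows, gene_list, sets, max_diff = 5L) {
  if (nrow(rows) == 0L) {
    rows$cluster <- integer()
    rows$primary <- logical()
    rows$adjP <- numeric()
    return(rows)
  }
  ov <- lapply(rows$term, function(id) intersect(sets[[id]], gene_list))
  m <- nrow(rows)
  adj <- vector("list", m)
  for (i in seq_len(m)) adj[[i]] <- integer()
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        sdiff <- length(setdiff(ov[[i]], ov[[j]])) +
          length(setdiff(ov[[j]], ov[[i]]))
        if (sdiff <= max_diff) {
          adj[[i]] <- c(adj[[i]], j)
          adj[[j]] <- c(adj[[j]], i)
        }
      }
    }
  }
  rows$cluster <- components_bfs(adj)
  rows$primary <- FALSE
  for (cl in unique(rows$cluster)) {
    i <- which(rows$cluster == cl)
    o <- i[order(rows$total_annotations[i], rows$term[i])]
    rows$primary[o[1L]] <- TRUE
  }
  rows$adjP <- NA_real_
  rows$adjP[rows$primary] <- adjust_bh(rows$p[rows$primary])
  rows
}

#' Mean fold-change signature of annotated feature sets
#'
#' For each selected term, the mean log2 fold change of its annotated
#' features and a two-sided one-sample t-test against zero. Terms whose
#' members all share one value (zero SD) are reported with `p = 1`
#' (no evidence either way from a degenerate test).
#'
#' @param lfc Named numeric vector of per-feature log2 fold changes.
#' @param sets Named list of term gene sets (>= 2 quantified members each).
#' @return data.frame with `term`, `n_members`, `mean_lfc`, `statistic`,
#'   `df`, `p`, `stars`.
#' @export
signature_summary <- function(lfc, sets) {
  rows <- lapply(names(sets), function(id) {
    v <- lfc[intersect(sets[[id]], names(lfc))]
    if (length(v) < 2L) {
      stop("term '", id, "' has fewer than 2 quantified members")
    }
    m <- mean(v)
    s <- sd(v)
    df <- length(v) - 1L
    if (s == 0) {
      stat <- 0
      p <- 1
    } else {
      stat <- m / (s / sqrt(length(v)))
      p <- 2 * pt(abs(stat), df, lower.tail = FALSE)
    }
    stars <- if (p <= 0.001) "***" else if (p <= 0.01) "**" else
      if (p <= 0.05) "*" else ""
    data.frame(term = id, n_members = length(v), mean_lfc = m,
               statistic = stat, df = df, p = p, stars = stars,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
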