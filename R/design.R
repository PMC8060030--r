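#' Build the factorial sample design table
#'
#' Constructs the sample-to-condition map of the study design: every tissue
#' crossed with genotype (long-lived insulin mutant vs control) and Wolbachia
#' status, with separate replicate structure per assay. Defaults follow the
#' study layout of five biological replicates per proteomic condition and
#' three per RNA-seq condition.
#'
#' @param tissues Character vector of tissue names.
#' @param n_rep_protein Replicates per (tissue, genotype, wolbachia) cell in
#'   the proteomics assay.
#' @param n_rep_rna Replicates per cell in the RNA-seq assay.
#' @param assays Which assays to include.
#' @return A data.frame with columns `sample_id`, `tissue`, `genotype`
#'   (`mutant`/`control`), `wolbachia` (`plus`/`minus`), `replicate`, `assay`.
#' @examples
#' d <- sim_design()
#' table(d$tissue, d$assay)
#' @export
sim_design <- function(tissues = c("fat", "gut", "brain", "thorax"),
                       n_rep_protein = 5L, n_rep_rna = 3L,
                       assays = c("protein", "transcript")) {
  stopifnot(length(tissues) >= 1L, n_rep_protein >= 1L, n_rep_rna >= 1L)
  assays <- match.arg(assays, c("protein", "transcript"), several.ok = TRUE)
  one <- function(assay, nrep) {
    g <- expand.grid(
      replicate = seq_len(nrep),
      wolbachia = c("plus", "minus"),
      genotype  = c("mutant", "control"),
      tissue    = tissues,
      stringsAsFactors = FALSE
    )
    g$assay <- assay
    g
  }
  parts <- list()
  if ("protein" %in% assays) parts <- c(parts, list(one("protein", n_rep_protein)))
  if ("transcript" %in% assays) parts <- c(parts, list(one("transcript", n_rep_rna)))
  d <- do.call(rbind, parts)
  d$sample_id <- sprintf(
    "%s_%s_%s_W%s_r%d",
    substr(d$assay, 1, 1), d$tissue, d$genotype,
    ifelse(d$wolbachia == "plus", "p", "m"), d$replicate
  )
  rownames(d) <- NULL
  d[, c("sample_id", "tissue", "genotype", "wolbachia", "replicate", "assay")]
}

## Validate a design table and subset it to one tissue/assay.
design_subset <- function(design, tissue = NULL, assay = NULL) {
  need <- c("sample_id", "tissue", "genotype", "wolbachia", "replicate", "assay")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id)) stop("duplicated sample_id in design")
  d <- design
  if (!is.null(tissue)) d <- d[d$tissue == tissue, , drop = FALSE]
  if (!is.null(assay)) d <- d[d$assay == assay, , drop = FALSE]
  d
}
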