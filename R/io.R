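#' Write gene sets in GMT format
#'
#' One line per set: id, description (the id again), then member genes,
#' tab-separated.
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, id, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  sets
}

#' Write a feature x sample matrix as TSV (missing cells empty)
#'
#' @param m Numeric matrix with rownames.
#' @param path Output file.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a feature x sample TSV matrix (empty cells become NA)
#'
#' @param path TSV file with a `feature` first column.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   na.strings = "", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
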