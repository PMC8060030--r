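#' Benjamini-Hochberg adjustment for one multiplicity family
#'
#' Step-up false-discovery-rate adjustment. Call once per family; in this
#' workflow a family is one (tissue, assay, contrast) combination, matching
#' per-tissue correction.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

## Deterministic per-stage seed derived from one master seed, kept < 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) + 100003 * offs) %% 2147483647)
}

## Connected components of an undirected relation given as an adjacency list
## of integer indices; returns an integer membership vector.
components_bfs <- function(adj) {
  n <- length(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

`%||%` <- function(a, b) if (is.null(a)) b else a
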