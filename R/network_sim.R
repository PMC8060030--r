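#' Topology and annotation settings for the simulated interactome
#'
#' The generated protein-protein-interaction graph is a stochastic block
#' model over the truth modules laid on top of a sparse background: gene
#' pairs sharing a module are connected with probability `within_p`, other
#' pairs with `between_p`. Gene sets comprise one set per truth module plus
#' `n_decoy_sets` random decoys.
#'
#' @param n_nodes Number of genes placed in the network (demo default 200).
#' @param within_p,between_p Edge probabilities within/between modules.
#' @param n_decoy_sets Number of random decoy gene sets.
#' @param decoy_size_range Integer range of decoy set sizes.
#' @return A named list of class `network_params`.
#' @export
network_params <- function(n_nodes = 200L, within_p = 0.3, between_p = 0.01,
                           n_decoy_sets = 10L, decoy_size_range = c(10L, 50L)) {
  if (within_p < 0 || within_p > 1 || between_p < 0 || between_p > 1) {
    stop("edge probabilities must lie in [0, 1]")
  }
  if (n_nodes < 2L) stop("n_nodes must be >= 2")
  structure(as.list(environment()), class = "network_params")
}

#' Generate an interaction network and gene-set annotations from a truth
#'
#' Builds an undirected simple graph (no self-loops or duplicate edges) in
#' which genes sharing a truth module are preferentially connected, and a
#' gene-set collection with one set per truth module plus random decoy sets.
#'
#' @param truth A [generate_truth()] object.
#' @param params A [network_params()] list.
#' @param seed Integer seed.
#' @return List with `edges` (two-column character data.frame), `nodes`
#'   (character vector), and `genesets` (named list of gene vectors; module
#'   sets are named `module_<id>`, decoys `decoy_<i>`).
#' @export
generate_network_and_annotations <- function(truth, params = network_params(),
                                             seed = 1L) {
  if (!inherits(params, "network_params")) params <- do.call(network_params, params)
  set.seed(derive_seed(seed, "network"))
  n <- min(params$n_nodes, length(truth$genes))
  nodes <- sort(sample(truth$genes, n))
  mod <- truth$module[nodes]
  big <- max(tabulate(mod))
  exp_deg <- params$within_p * (big - 1) + params$between_p * (n - big)
  if (exp_deg >= n) stop("requested mean degree >= number of nodes")
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- ifelse(mod[ij[, 1]] == mod[ij[, 2]], params$within_p, params$between_p)
  keep <- runif(nrow(ij)) < p
  edges <- data.frame(from = nodes[ij[keep, 1]], to = nodes[ij[keep, 2]],
                      stringsAsFactors = FALSE)

  sets <- lapply(sort(unique(truth$module)), function(m) {
    names(truth$module)[truth$module == m]
  })
  names(sets) <- paste0("module_", sort(unique(truth$module)))
  if (params$n_decoy_sets > 0L) {
    rng <- params$decoy_size_range
    for (i in seq_len(params$n_decoy_sets)) {
      sz <- sample(seq(rng[1], min(rng[2], length(truth$genes))), 1L)
      sets[[paste0("decoy_", i)]] <- sort(sample(truth$genes, sz))
    }
  }
  list(edges = edges, nodes = nodes, genesets = sets)
}
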