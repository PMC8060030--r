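## Accept an edge-list data.frame or a list(edges, nodes); the node set
## defaults to the edge endpoints but may include isolated nodes.
resolve_network <- function(network) {
  if (is.data.frame(network)) network <- list(edges = network)
  edges <- network$edges
  nodes <- network$nodes %||% sort(unique(c(edges$from, edges$to)))
  if (!all(c(edges$from, edges$to) %in% nodes)) {
    stop("edge endpoints missing from node set")
  }
  list(edges = edges, nodes = nodes)
}

## Build a symmetrically degree-normalized adjacency from an edge list.
## Self-loops and duplicate/reversed duplicates are rejected.
normalized_adjacency <- function(edges, nodes = NULL) {
  if (any(edges$from == edges$to)) stop("network contains self-loops")
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (anyDuplicated(key)) stop("network contains duplicate edges")
  nodes <- nodes %||% sort(unique(c(edges$from, edges$to)))
  i <- match(edges$from, nodes)
  j <- match(edges$to, nodes)
  if (anyNA(i) || anyNA(j)) stop("edge endpoints missing from node set")
  n <- length(nodes)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(n, n), dimnames = list(nodes, nodes))
  deg <- Matrix::rowSums(A)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  W <- Matrix::Diagonal(n, dinv) %*% A %*% Matrix::Diagonal(n, dinv)
  dimnames(W) <- list(nodes, nodes)
  W
}

#' Network propagation of node scores (random walk with restart)
#'
#' Diffuses non-negative seed scores (here: absolute log2 fold changes) over
#' an undirected interaction network by iterating
#' `s <- alpha * W %*% s + (1 - alpha) * s0` with `W` the symmetrically
#' degree-normalized adjacency, until the maximum per-node change falls
#' below `tol`. For `alpha < 1` this converges to the closed form
#' `(1 - alpha) * solve(I - alpha * W) %*% s0`. Nodes absent from `seeds`
#' start at 0; isolated nodes return `(1 - alpha) * s0`.
#'
#' @param network Edge-list data.frame with columns `from`, `to`, or a list
#'   with elements `edges` and (optionally) `nodes` naming the full node set
#'   including isolated nodes, as from [generate_network_and_annotations()].
#' @param seeds Named non-negative numeric vector of seed scores.
#' @param alpha Spreading coefficient in `[0, 1)`: the weight on neighbour
#'   contributions per step (default 0.8).
#' @param tol Convergence tolerance on the max-norm.
#' @param max_iter Iteration cap.
#' @return Named numeric vector of steady-state scores over network nodes.
#' @export
propagate <- function(network, seeds, alpha = 0.8, tol = 1e-8,
                      max_iter = 10000L) {
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  if (any(seeds < 0)) stop("seeds must be non-negative")
  nw <- resolve_network(network)
  edges <- nw$edges
  nodes <- nw$nodes
  W <- normalized_adjacency(edges, nodes)
  s0 <- setNames(numeric(length(nodes)), nodes)
  hit <- intersect(names(seeds), nodes)
  s0[hit] <- seeds[hit]
  if (alpha == 0) return(s0)
  s <- s0
  for (it in seq_len(max_iter)) {
    s_new <- as.numeric(alpha * (W %*% s)) + (1 - alpha) * s0
    if (max(abs(s_new - s)) < tol) {
      return(setNames(s_new, nodes))
    }
    s <- s_new
  }
  warning("propagation did not reach tolerance within max_iter")
  setNames(s, nodes)
}

#' Hub-bias correction of propagation scores by seed permutation
#'
#' Network propagation favours hub nodes regardless of signal. The corrected
#' score subtracts, per node, the mean propagation score over `n_perm`
#' random permutations of the seed values across nodes. Constant seed
#' vectors are permutation-invariant, so their corrected scores are exactly
#' zero (computed without sampling).
#'
#' @inheritParams propagate
#' @param n_perm Number of seed permutations (>= 1).
#' @param seed Integer seed for the permutations.
#' @param shortcut Return exact zeros for permutation-invariant (constant)
#'   seed vectors without sampling.
#' @return Named numeric vector of corrected scores (may be negative).
#' @export
bias_correct <- function(network, seeds, alpha = 0.8, n_perm = 100L,
                         seed = 1L, tol = 1e-8, max_iter = 10000L,
                         shortcut = TRUE) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  nw <- resolve_network(network)
  nodes <- nw$nodes
  s0 <- setNames(numeric(length(nodes)), nodes)
  hit <- intersect(names(seeds), nodes)
  s0[hit] <- seeds[hit]
  raw <- propagate(nw, s0, alpha, tol, max_iter)
  if (shortcut && max(s0) - min(s0) == 0) {
    # exact permutation invariance: the null equals the raw score
    return(setNames(numeric(length(nodes)), nodes))
  }
  set.seed(derive_seed(seed, "biascorrect"))
  null_sum <- numeric(length(nodes))
  for (b in seq_len(n_perm)) {
    sp <- setNames(sample(s0), nodes)
    null_sum <- null_sum + propagate(nw, sp, alpha, tol, max_iter)
  }
  raw - null_sum / n_perm
}

#' Cross-model consensus score
#'
#' Per node the consensus is the minimum of the two models' corrected
#' propagation scores, high only where both reduced-insulin-signalling
#' models agree. Node sets are intersected; dropped nodes are reported via
#' the `dropped` attribute.
#'
#' @param scores_a,scores_b Named numeric vectors.
#' @return Named numeric vector over the shared nodes.
#' @export
consensus_min <- function(scores_a, scores_b) {
  shared <- intersect(names(scores_a), names(scores_b))
  if (length(shared) == 0L) stop("no shared nodes between the two models")
  out <- pmin(scores_a[shared], scores_b[shared])
  attr(out, "dropped") <- setdiff(union(names(scores_a), names(scores_b)),
                                  shared)
  out
}

#' Ward clustering of propagation-score profiles
#'
#' Agglomerative hierarchical clustering (Ward's method on Euclidean
#' distances) of the node x condition score matrix, cut at `k` clusters.
#'
#' @param scores Complete numeric matrix, nodes x conditions.
#' @param k Number of clusters (2 <= k <= number of nodes).
#' @return List with `labels` (named integer vector) and `tree` (`hclust`).
#' @export
cluster_scores <- function(scores, k) {
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("score matrix must be complete")
  if (k < 1L || k > nrow(scores)) stop("k must lie in [1, number of nodes]")
  tree <- hclust(dist(scores), method = "ward.D2")
  labels <- cutree(tree, k = k)
  names(labels) <- rownames(scores)
  list(labels = labels, tree = tree)
}

#' Bias-corrected propagation with cross-model consensus, per tissue
#'
#' Convenience wrapper running [bias_correct()] for two models' per-tissue
#' seed sets, taking the per-tissue [consensus_min()], and clustering the
#' consensus profiles across tissues with [cluster_scores()].
#'
#' @param network Edge list (or list with `edges`).
#' @param seeds_a,seeds_b Named lists (one element per tissue) of named
#'   non-negative seed vectors, e.g. absolute log2 fold changes per model.
#' @param alpha Spreading coefficient.
#' @param n_perm Permutations for bias correction.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @return List with `corrected_a`, `corrected_b`, `consensus` (matrices
#'   nodes x tissues) and `clusters` (from [cluster_scores()]).
#' @export
run_netprop <- function(network, seeds_a, seeds_b, alpha = 0.8,
                        n_perm = 100L, k = 10L, seed = 1L) {
  tissues <- intersect(names(seeds_a), names(seeds_b))
  if (length(tissues) == 0L) stop("no shared tissues between seed lists")
  nw <- resolve_network(network)
  nodes <- nw$nodes
  mk <- function(seed_list, tag) {
    vapply(tissues, function(tau) {
      bias_correct(nw, seed_list[[tau]], alpha = alpha, n_perm = n_perm,
                   seed = derive_seed(seed, paste0(tag, tau)))
    }, numeric(length(nodes)))
  }
  ca <- mk(seeds_a, "A")
  cb <- mk(seeds_b, "B")
  rownames(ca) <- rownames(cb) <- nodes
  cons <- pmin(ca, cb)
  k_eff <- min(k, nrow(cons))
  list(corrected_a = ca, corrected_b = cb, consensus = cons,
       clusters = cluster_scores(cons, k_eff))
}
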