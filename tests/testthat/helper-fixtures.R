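# Shared fixture builders. Everything is generated in code at test time.

# One-tissue protein design with n replicates per 2x2 cell.
one_tissue_design <- function(n = 5L, tissue = "fat", assay = "protein") {
  sim_design(tissues = tissue,
             n_rep_protein = if (assay == "protein") n else 1L,
             n_rep_rna = if (assay == "transcript") n else 1L,
             assays = assay)
}

# Intensity matrix with exact per-cell means and optional Gaussian noise.
cell_mean_matrix <- function(design, means, n_features = 1L, noise_sd = 0,
                             seed = 1L) {
  set.seed(seed)
  cell <- paste(design$genotype, design$wolbachia, sep = ".")
  base <- matrix(rep(means[cell], each = n_features), nrow = n_features)
  if (noise_sd > 0) base <- base + rnorm(length(base), sd = noise_sd)
  dimnames(base) <- list(sprintf("f%03d", seq_len(n_features)),
                         design$sample_id)
  base
}

# Brute-force BH step-up: adj_(i) = min(1, min_{j >= i} m p_(j) / j).
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Exhaustive hypergeometric upper tail P(X >= k) for overlap k of a list of
# size n with a set of size K in a background of size N.
hyper_tail_bruteforce <- function(k, K, n, N) {
  xs <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Random simple graph edge list on n nodes (guaranteed connected enough for
# propagation tests via a spanning chain).
random_graph <- function(n, p = 0.15, seed = 1L) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- runif(nrow(ij)) < p
  chain <- cbind(seq_len(n - 1), 2:n)
  pairs <- unique(rbind(ij[keep, , drop = FALSE], chain))
  data.frame(from = nodes[pairs[, 1]], to = nodes[pairs[, 2]],
             stringsAsFactors = FALSE)
}

# Dense closed-form propagation: (1 - alpha) (I - alpha W)^{-1} s0 with W the
# symmetrically normalized adjacency, built independently of the package's
# sparse implementation.
propagate_dense_oracle <- function(edges, seeds, alpha) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    A[edges$from[r], edges$to[r]] <- 1
    A[edges$to[r], edges$from[r]] <- 1
  }
  d <- rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  W <- diag(dinv) %*% A %*% diag(dinv)
  s0 <- setNames(numeric(n), nodes)
  s0[intersect(names(seeds), nodes)] <- seeds[intersect(names(seeds), nodes)]
  setNames(drop((1 - alpha) * solve(diag(n) - alpha * W, s0)), nodes)
}
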