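test_that("design table forms a complete 2x2 per tissue with unique ids", {
  d <- sim_design()
  expect_false(anyDuplicated(d$sample_id) > 0)
  for (tau in unique(d$tissue)) {
    for (as_ in unique(d$assay)) {
      cells <- table(d[d$tissue == tau & d$assay == as_,
                       c("genotype", "wolbachia")])
      expect_true(all(cells > 0))
    }
  }
  expect_equal(sum(d$assay == "protein"), 4 * 4 * 5)
  expect_equal(sum(d$assay == "transcript"), 4 * 4 * 3)
})

test_that("ground truth honours class fractions and flag invariants", {
  # zero decoupling: no gene decoupled anywhere
  tr0 <- generate_truth(50, 5, truth_params(decoupled_fraction = 0), seed = 7)
  expect_false(any(tr0$decoupled))

  # saturation: every gene Wolbachia-dependent in the designated tissue
  tr1 <- generate_truth(100, 0,
                        truth_params(wolbachia_dependent_fraction = 1,
                                     responsive_fraction = 0), seed = 7)
  expect_true(all(tr1$wolbachia_dependent[, "fat"]))
  expect_true(all(abs(tr1$gamma[tr1$wolbachia_dependent[, "fat"], "fat"]) >= 1.5))

  # binomial bound on the decoupled count among (fully) responsive genes
  tr2 <- generate_truth(2000, 0,
                        truth_params(responsive_fraction = 1,
                                     wolbachia_dependent_fraction = 0,
                                     decoupled_fraction = 0.5), seed = 11)
  n_dec <- sum(tr2$decoupled[, "fat"])
  expect_lt(abs(n_dec - 1000), 3 * sqrt(2000 * 0.25))

  # flag invariants
  tr <- generate_truth(500, 20, seed = 3)
  dec <- which(tr$decoupled, arr.ind = TRUE)
  expect_true(all(sign(tr$beta_p[tr$decoupled]) ==
                    -sign(tr$beta_t[seq_along(tr$genes), ][tr$decoupled])))
  expect_true(all(abs(tr$beta_p[tr$decoupled]) >= 1))
  wd <- tr$wolbachia_dependent
  expect_true(all(abs(tr$gamma[wd]) >= 1.5))
  expect_true(all(abs(tr$beta_t[wd]) >= 1))
  expect_true(all(tr$phi > 0) && all(tr$baseline_count > 0))
})

test_that("inconsistent class fractions raise a configuration error", {
  expect_error(truth_params(wolbachia_dependent_fraction = 0.8,
                            responsive_fraction = 0.5),
               "wolbachia_dependent_fraction")
  expect_error(truth_params(decoupled_fraction = 1.2), "decoupled_fraction")
})

test_that("truth and simulators are deterministic under a fixed seed", {
  tr_a <- generate_truth(60, 6, seed = 42)
  tr_b <- generate_truth(60, 6, seed = 42)
  expect_identical(tr_a, tr_b)
  d <- sim_design(tissues = "fat")
  expect_identical(simulate_counts(tr_a, d, seed = 9),
                   simulate_counts(tr_b, d, seed = 9))
  expect_identical(simulate_intensities(tr_a, d, seed = 9),
                   simulate_intensities(tr_b, d, seed = 9))
})

test_that("simulated counts recover baselines and planted fold changes", {
  # near-Poisson, zero effects: per-gene means close to baseline
  pz <- truth_params(responsive_fraction = 0, wolbachia_dependent_fraction = 0,
                     dispersion_meanlog = log(1e-12), dispersion_sdlog = 0,
                     baseline_count_meanlog = log(500),
                     baseline_count_sdlog = 0.2)
  tr <- generate_truth(1000, 0, pz, seed = 5, tissues = "fat")
  d <- sim_design(tissues = "fat", n_rep_rna = 3L, assays = "transcript")
  cm <- simulate_counts(tr, d, seed = 5)
  rel <- abs(rowMeans(cm) / tr$baseline_count - 1)
  expect_gt(mean(rel < 0.05), 0.9)
  expect_lt(abs(mean(rowMeans(cm) / tr$baseline_count) - 1), 0.01)

  # a planted transcript effect of +1 doubles the mutant mean (W+ samples)
  tr1 <- generate_truth(10, 0, truth_params(responsive_fraction = 0,
                                            wolbachia_dependent_fraction = 0),
                        seed = 5, tissues = "fat")
  tr1$beta_t["g0001", "fat"] <- 1
  dbig <- sim_design(tissues = "fat", n_rep_rna = 200L, assays = "transcript")
  cm1 <- simulate_counts(tr1, dbig, seed = 6)
  dd <- dbig[match(colnames(cm1), dbig$sample_id), ]
  mut <- mean(cm1["g0001", dd$genotype == "mutant" & dd$wolbachia == "plus"])
  ctl <- mean(cm1["g0001", dd$genotype == "control" & dd$wolbachia == "plus"])
  expect_lt(abs(mut / ctl - 2), 0.25)

  # a size factor of 2 doubles that sample's column sum
  sf <- setNames(rep(1, nrow(d)), d$sample_id)
  sf[1] <- 2
  cm2 <- simulate_counts(tr, d, seed = 7, size_factors = sf)
  expect_lt(abs(sum(cm2[, 1]) / sum(cm2[, 2]) - 2), 0.1)
})

test_that("intensity dropout behaves as configured", {
  tr <- generate_truth(200, 0, seed = 2, tissues = "fat")
  d <- sim_design(tissues = "fat", assays = "protein")
  none <- simulate_intensities(tr, d, missing_params =
                                 dropout_params(max_rate = 0), seed = 1)
  expect_false(anyNA(none))

  # hard threshold below every intensity: nothing can drop out
  low <- simulate_intensities(tr, d, missing_params =
                                dropout_params(midpoint = -100, scale = 0,
                                               max_rate = 1), seed = 1)
  expect_false(anyNA(low))

  # steep dropout at low intensity censors the left tail
  steep <- simulate_intensities(tr, d, missing_params =
                                  dropout_params(midpoint = 25, scale = 0.5,
                                                 max_rate = 1), seed = 1)
  truthm <- attr(steep, "true_values")
  expect_true(anyNA(steep))
  expect_lt(mean(truthm[is.na(steep)]), mean(truthm[!is.na(steep)]))

  expect_error(dropout_params(max_rate = 1.3), "max_rate")
})

test_that("generated networks are simple, modular, and annotated", {
  # complete graph on 5 genes under within-module probability 1
  tr <- generate_truth(10, 0, truth_params(n_modules = 1), seed = 1)
  net <- generate_network_and_annotations(
    tr, network_params(n_nodes = 5, within_p = 1, between_p = 0,
                       n_decoy_sets = 0), seed = 1)
  expect_equal(nrow(net$edges), 10)
  expect_equal(length(net$genesets), 1)

  # modular structure: within-module degree exceeds between-module degree
  tr2 <- generate_truth(500, 0, truth_params(n_modules = 10), seed = 4)
  net2 <- generate_network_and_annotations(
    tr2, network_params(n_nodes = 500, within_p = 0.3, between_p = 0.01,
                        n_decoy_sets = 3), seed = 4)
  e <- net2$edges
  expect_false(any(e$from == e$to))
  expect_false(anyDuplicated(paste(pmin(e$from, e$to), pmax(e$from, e$to))) > 0)
  mod <- tr2$module
  within <- sum(mod[e$from] == mod[e$to])
  between <- nrow(e) - within
  n_per_mod <- table(mod[net2$nodes])
  # normalize by the number of possible pairs of each kind
  poss_within <- sum(n_per_mod * (n_per_mod - 1) / 2)
  poss_between <- choose(length(net2$nodes), 2) - poss_within
  expect_gt(within / poss_within, between / poss_between)
  expect_equal(length(net2$genesets), 13)
})
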