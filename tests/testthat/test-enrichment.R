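test_that("transcript backgrounds apply the strict median rule", {
  cm <- rbind(in_bg = c(6, 6, 6, 6, 6, 6),
              boundary = c(5, 5, 5, 5, 5, 5),
              low = c(0, 1, 0, 2, 0, 1))
  colnames(cm) <- paste0("s", 1:6)
  bg <- define_background(cm, assay = "transcript")
  expect_identical(bg, "in_bg")

  # brute-force per-gene median filter on a random fixture
  set.seed(61)
  cm2 <- matrix(rpois(200 * 6, 6), 200,
                dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:6)))
  bg2 <- define_background(cm2, assay = "transcript")
  oracle <- rownames(cm2)[vapply(seq_len(nrow(cm2)), function(i) {
    median(cm2[i, ]) > 5
  }, logical(1))]
  expect_identical(bg2, oracle)

  # protein background: detected features
  m <- matrix(c(1, NA, NA, NA, 2, 3), 2, dimnames = list(c("a", "b"), NULL))
  expect_setequal(define_background(m, assay = "protein"), c("a", "b"))
  m2 <- matrix(NA_real_, 1, 3, dimnames = list("a", NULL))
  expect_error(define_background(m2, assay = "protein"), "empty")
})

test_that("Fisher p equals the hypergeometric tail on worked examples", {
  bg <- sprintf("g%02d", 1:20)
  sets <- list(term1 = bg[1:8])
  # N = 20, K = 8, n = 5, k = 4
  gl <- c(bg[1:4], bg[20])
  r <- fisher_term_test(gl, bg, sets, min_size = 1, max_size = 1000)
  expect_equal(r$p, hyper_tail_bruteforce(4, 8, 5, 20), tolerance = 1e-12)
  expect_equal(r$p, 0.0578, tolerance = 1e-3)

  # zero overlap: upper tail from 0 is 1
  r0 <- fisher_term_test(bg[15:19], bg, sets, min_size = 1)
  expect_equal(r0$p, 1)

  # the saturated list hits k = K with p = 1
  rall <- fisher_term_test(bg, bg, sets, min_size = 1)
  expect_equal(rall$k, rall$K)
  expect_equal(rall$p, 1)

  # size filter (in-background size 8 < min 9) and membership validation
  expect_equal(nrow(fisher_term_test(gl, bg, sets, min_size = 9)), 0L)
  expect_error(fisher_term_test(c("zz"), bg, sets), "not in background")
})

test_that("enrichment p is monotone non-increasing in the overlap", {
  bg <- sprintf("g%02d", 1:30)
  sets <- list(t = bg[1:10])
  ps <- vapply(0:10, function(k) {
    gl <- c(bg[seq_len(k)], bg[11:(21 - k)])[1:10]  # list size 10, overlap k
    fisher_term_test(gl, bg, sets, min_size = 1)$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("redundancy clustering matches a transitive-closure oracle", {
  gl <- sprintf("g%02d", 1:40)
  bg <- sprintf("g%02d", 1:100)
  set.seed(67)
  sets <- lapply(1:50, function(i) {
    sample(bg, sample(8:30, 1))
  })
  names(sets) <- sprintf("t%02d", 1:50)
  rows <- fisher_term_test(gl, bg, sets, min_size = 1, max_size = 1000)
  red <- reduce_redundancy(rows, gl, sets, max_diff = 5)

  # oracle: pairwise relation + boolean transitive closure
  ov <- lapply(red$term, function(id) intersect(sets[[id]], gl))
  m <- length(ov)
  R <- diag(m) > 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    R[i, j] <- length(union(setdiff(ov[[i]], ov[[j]]),
                            setdiff(ov[[j]], ov[[i]]))) <= 5
  }
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  oracle_comp <- match(apply(R, 1, paste, collapse = ""),
                       unique(apply(R, 1, paste, collapse = "")))
  canon <- function(v) match(v, unique(v))
  expect_equal(canon(red$cluster), canon(oracle_comp))

  # exactly one primary per cluster, with the smallest total annotations
  for (cl in unique(red$cluster)) {
    sub <- red[red$cluster == cl, ]
    expect_equal(sum(sub$primary), 1L)
    expect_true(all(sub$total_annotations[sub$primary] <=
                      sub$total_annotations))
  }
  # BH over primary terms only
  expect_true(all(is.na(red$adjP[!red$primary])))
  expect_equal(red$adjP[red$primary],
               unname(adjust_bh(red$p[red$primary])), tolerance = 1e-12)
})

test_that("redundancy boundary: identical overlaps merge, 6-gene gaps split", {
  gl <- sprintf("g%02d", 1:20)
  bg <- sprintf("g%02d", 1:40)
  sets <- list(a = gl[1:10], b = c(gl[1:10], bg[30:34]),  # same overlap
               c = gl[c(1:2, 11:18)])                     # differs by 6+ from a
  rows <- fisher_term_test(gl, bg, sets, min_size = 1)
  red <- reduce_redundancy(rows, gl, sets, max_diff = 5)
  cl <- setNames(red$cluster, red$term)
  expect_equal(cl[["a"]], cl[["b"]])
  expect_false(cl[["a"]] == cl[["c"]])
})

test_that("signature summaries match the closed-form one-sample t-test", {
  lfc <- c(a = -0.5, b = -0.3, c = -0.4, d = 2, e = 0, f = 0)
  r <- signature_summary(lfc, list(s1 = c("a", "b", "c")))
  expect_equal(r$mean_lfc, -0.4, tolerance = 1e-12)
  expect_equal(r$statistic, -0.4 / (0.1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$statistic, -6.93, tolerance = 1e-3)
  expect_equal(r$p, 0.0202, tolerance = 1e-2)
  expect_equal(r$stars, "*")

  # degenerate zero-variance set reports no evidence
  r0 <- signature_summary(lfc, list(z = c("e", "f")))
  expect_equal(r0$mean_lfc, 0)
  expect_equal(r0$p, 1)

  expect_error(signature_summary(lfc, list(tiny = "a")), "fewer than 2")

  # null members give uniform p-values
  set.seed(71)
  lfc_null <- setNames(rnorm(5000), sprintf("g%04d", 1:5000))
  sets <- lapply(1:1000, function(i) sample(names(lfc_null), 10))
  names(sets) <- sprintf("t%04d", 1:1000)
  ps <- signature_summary(lfc_null, sets)$p
  ks <- max(abs(sort(ps) - (seq_along(ps) - 0.5) / length(ps)))
  expect_lt(ks, 0.05)
})
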