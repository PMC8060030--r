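test_that("factorial OLS reproduces exact cell-mean constructions", {
  d <- one_tissue_design(n = 5L)
  m <- cell_mean_matrix(d, c("control.plus" = 10, "mutant.plus" = 11,
                             "control.minus" = 10, "mutant.minus" = 10))
  fit <- fit_intensity_model(m, d)
  mp <- test_contrast(fit, list(var_post = fit$s2, df_prior = 0,
                                var_prior = 0), "main_plus")
  mm <- test_contrast(fit, list(var_post = fit$s2, df_prior = 0,
                                var_prior = 0), "main_minus")
  ia <- test_contrast(fit, list(var_post = fit$s2, df_prior = 0,
                                var_prior = 0), "interaction")
  expect_equal(mp$lfc, 1, tolerance = 1e-12)
  expect_equal(mm$lfc, 0, tolerance = 1e-12)
  expect_equal(ia$lfc, 1, tolerance = 1e-12)
  expect_equal(unname(fit$s2), 0, tolerance = 1e-20)

  # constant data: all non-intercept coefficients zero
  m2 <- matrix(7, 1, nrow(d), dimnames = list("f001", d$sample_id))
  fit2 <- fit_intensity_model(m2, d)
  expect_equal(unname(fit2$coefficients[1, -1]), c(0, 0, 0), tolerance = 1e-12)
})

test_that("OLS coefficients equal the independent cell-mean algebra", {
  set.seed(21)
  d <- one_tissue_design(n = 5L)
  m <- matrix(rnorm(50 * nrow(d), 20, 2), 50,
              dimnames = list(sprintf("f%03d", 1:50), d$sample_id))
  fit <- fit_intensity_model(m, d)
  cell <- paste(d$genotype, d$wolbachia, sep = ".")
  cm <- t(apply(m, 1, function(x) tapply(x, cell, mean)))
  # treatment coding: reference = control / Wolbachia-minus
  expect_equal(unname(fit$coefficients[, "intercept"]),
               unname(cm[, "control.minus"]), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[, "genotype"]),
               unname(cm[, "mutant.minus"] - cm[, "control.minus"]),
               tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[, "wolbachia"]),
               unname(cm[, "control.plus"] - cm[, "control.minus"]),
               tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[, "interaction"]),
               unname((cm[, "mutant.plus"] - cm[, "control.plus"]) -
                        (cm[, "mutant.minus"] - cm[, "control.minus"])),
               tolerance = 1e-10)

  # an empty design cell is reported
  d2 <- d[!(d$genotype == "mutant" & d$wolbachia == "plus"), ]
  expect_error(fit_intensity_model(m[, d2$sample_id], d2), "empty cell")
})

test_that("variance moderation recovers the scaled-F prior", {
  # degenerate: identical variances -> infinite prior df, pooled value
  mod <- moderate_variances(rep(4, 50), df = 16)
  expect_equal(mod$df_prior, Inf)
  expect_equal(mod$var_prior, 4)
  expect_true(all(mod$var_post == 4))

  # no-shrinkage limit: enormous spread of log s2 -> d0 ~ 0, s2 unchanged
  # (checked away from the extreme tails, where any finite prior dominates)
  set.seed(5)
  s2_wide <- exp(rnorm(2000, 0, 60))
  mod0 <- moderate_variances(s2_wide, df = 16)
  expect_lt(mod0$df_prior, 0.05)
  mid <- s2_wide > 0.1 & s2_wide < 10
  expect_lt(max(abs(mod0$var_post[mid] / s2_wide[mid] - 1)), 0.05)

  # Monte-Carlo recovery: s2 ~ s0^2 chi^2_d / d with s0^2 = 1, d = 16
  set.seed(6)
  s2 <- rchisq(5000, df = 16) / 16
  mod1 <- moderate_variances(s2, df = 16)
  expect_lt(abs(mod1$var_prior - 1), 0.05)
  # shrinkage reduces MSE against the true unit variance
  expect_lt(mean((mod1$var_post - 1)^2), mean((s2 - 1)^2))

  expect_error(moderate_variances(rep(1, 5), 16), "at least 10")
})

test_that("moderation agrees with the limma cross-check", {
  set.seed(7)
  s2 <- 0.09 * rf(3000, 16, 8)  # scaled-F draws: s0^2 = 0.09, d0 = 8
  mod <- moderate_variances(s2, df = 16)
  sq <- limma::squeezeVar(s2, df = 16)
  expect_equal(mod$df_prior, sq$df.prior, tolerance = 0.05)
  expect_equal(mod$var_prior, sq$var.prior, tolerance = 0.02)
  expect_equal(unname(mod$var_post), unname(sq$var.post), tolerance = 0.02)
})

test_that("moderated t statistics follow the stated t reference", {
  # white-box fixture: lfc 0.5, se 0.1, total df 16 -> t = 5, p ~ 1.24e-4
  fit <- list(coefficients = matrix(c(0, 0.5, 0, 0), 1,
                                    dimnames = list("f1", NULL)),
              s2 = 0.01, df = 12, xtx_inv = diag(4))
  mod <- list(var_post = 0.01, df_prior = 4, var_prior = 0.01)
  r <- test_contrast(fit, mod, "main_minus")
  expect_equal(r$statistic, 5, tolerance = 1e-12)
  expect_equal(r$df, 16)
  expect_equal(r$p, 2 * pt(5, 16, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r$p, 1.24e-4, tolerance = 0.01)

  # zero effect gives statistic 0 and p 1
  fit0 <- list(coefficients = matrix(0, 1, 4, dimnames = list("f1", NULL)),
               s2 = 0.01, df = 12, xtx_inv = diag(4))
  r0 <- test_contrast(fit0, mod, "interaction")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  expect_error(test_contrast(fit, mod, c(0, 0, 0, 0)), "zero contrast")
})

test_that("interaction equals main_plus minus main_minus identically", {
  set.seed(9)
  d <- one_tissue_design(n = 5L)
  m <- matrix(rnorm(200 * nrow(d), 22, 1.5), 200,
              dimnames = list(sprintf("f%03d", 1:200), d$sample_id))
  de <- de_intensity(m, d, tissue = "fat")
  w <- reshape(de[, c("feature", "contrast", "lfc")], timevar = "contrast",
               idvar = "feature", direction = "wide")
  expect_lt(max(abs(w$lfc.interaction -
                      (w$lfc.main_plus - w$lfc.main_minus))), 1e-12)
  expect_true(all(de$adjP >= de$p))
})

test_that("null intensity p-values are uniform", {
  set.seed(10)
  d <- one_tissue_design(n = 5L)
  m <- matrix(rnorm(2000 * nrow(d), 25, 0.3), 2000,
              dimnames = list(sprintf("f%04d", 1:2000), d$sample_id))
  de <- de_intensity(m, d, tissue = "fat")
  p <- de$p[de$contrast == "main_plus"]
  ks <- max(abs(sort(p) - (seq_along(p) - 0.5) / length(p)))
  expect_lt(ks, 0.05)
})

test_that("BH adjustment matches the step-up definition on worked cases", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(adjust_bh(rep(0.2, 7)), rep(0.2, 7))
  expect_error(adjust_bh(c(0.5, 0)), "p-values")
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_bh(p), bh_bruteforce(p), tolerance = 1e-12)
  }
})
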