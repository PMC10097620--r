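test_that("design matrix rows follow the condition factor encoding", {
  d <- generate_design(3, 2)
  X <- build_design(d)
  expect_equal(colnames(X), c("(Intercept)", "brafwt", "v600e", "dimerizer",
                              "sorafenib", "vemurafenib"))
  # tag-only control: dimerizer-treated, no bait construct, no RAF inhibitor
  ctrl <- X[d$condition == "FRB+FKBP", , drop = FALSE][1, ]
  expect_equal(unname(ctrl), c(1, 0, 0, 1, 0, 0))
  braf_s_ac <- X[d$condition == "BRAF + S + A/C", , drop = FALSE][1, ]
  expect_equal(unname(braf_s_ac), c(1, 1, 0, 1, 1, 0))
  # full rank, checked against an independent decomposition
  expect_equal(qr(X)$rank, 6)
  expect_equal(sum(svd(X)$d > 1e-8), 6)
  # a constant factor is named in the error
  d2 <- d[d$sorafenib == 0, ]
  expect_error(build_design(d2), "sorafenib")
})

sim_complete <- function(n_prot = 30, seed = 1, sigma = 0) {
  d <- generate_design(2, 1)
  set.seed(seed)
  beta <- matrix(rnorm(n_prot * 5, 0, 1), n_prot, 5,
                 dimnames = list(NULL, c("brafwt", "v600e", "dimerizer",
                                         "sorafenib", "vemurafenib")))
  tr <- ground_truth(sprintf("P%03d", seq_len(n_prot)),
                     rnorm(n_prot, 25, 2), beta,
                     sigma_bio = 0, sigma_tech = sigma,
                     censor_midpoint = -100, censor_slope = 0)
  s <- simulate_lfq(d, tr, seed = seed)
  V <- s$intensity
  rownames(V) <- s$protein_ids
  im <- log2_transform(V)
  im$design <- d
  list(im = im, truth = tr, design = d)
}

test_that("noise-free data recovers the true coefficients exactly", {
  s <- sim_complete(sigma = 0)
  fit <- fit_ols(s$im)
  expect_equal(unname(fit$coefficients[, -1]), unname(s$truth$beta),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[, 1]), s$truth$baseline,
               tolerance = 1e-8)
  # predictions equal measurements exactly
  pr <- predict_logLFQ(fit)
  expect_equal(unname(pr$predicted), unname(s$im$values), tolerance = 1e-8)
})

test_that("OLS fit, coefficient tests and contrasts match lm/vcov oracles", {
  s <- sim_complete(n_prot = 25, seed = 7, sigma = 0.5)
  fit <- fit_ols(s$im)
  ct <- coefficient_tests(fit)
  cvec <- c(0, -1, 1, 0, 0, 0)
  cres <- contrast(fit, cvec, name = "v600e-brafwt")
  X <- fit$X
  for (i in seq_len(nrow(fit$coefficients))) {
    y <- s$im$values[i, ]
    lmfit <- lm(y ~ X - 1)
    sm <- summary(lmfit)
    expect_equal(unname(fit$coefficients[i, ]), unname(coef(lmfit)),
                 tolerance = 1e-8)
    expect_equal(unname(fit$se[i, ]), unname(sm$coefficients[, 2]),
                 tolerance = 1e-8)
    # centred R^2 (lm's no-intercept summary reports the uncentred one)
    r2_oracle <- 1 - sum(residuals(lmfit)^2) / sum((y - mean(y))^2)
    expect_equal(unname(fit$r2[i]), r2_oracle, tolerance = 1e-8)
    # two-sided coefficient p-values
    pi <- ct$p_value[ct$protein == rownames(fit$coefficients)[i]]
    expect_equal(pi, unname(sm$coefficients[, 4]), tolerance = 1e-10)
    # contrast estimate and se via the direct quadratic form
    expect_equal(cres$estimate[i], unname(sum(cvec * coef(lmfit))),
                 tolerance = 1e-10)
    expect_equal(cres$se[i], drop(sqrt(t(cvec) %*% vcov(lmfit) %*% cvec)),
                 tolerance = 1e-8)
  }
  expect_equal(fit$df_resid, nrow(X) - ncol(X))
})

test_that("fit agrees with limma's least-squares fit", {
  skip_if_not_installed("limma")
  s <- sim_complete(n_prot = 20, seed = 3, sigma = 0.4)
  fit <- fit_ols(s$im)
  lf <- limma::lmFit(s$im$values, fit$X)
  expect_equal(unname(fit$coefficients), unname(lf$coefficients),
               tolerance = 1e-8)
  expect_equal(unname(fit$se),
               unname(lf$stdev.unscaled * lf$sigma), tolerance = 1e-8)
})

test_that("contrast conventions: presets, reductions and degenerate cases", {
  s <- sim_complete(n_prot = 12, seed = 5, sigma = 0.3)
  fit <- fit_ols(s$im)
  # elementary contrast reproduces the coefficient test exactly
  e_dim <- contrast(fit, c(0, 0, 0, 1, 0, 0), name = "dimerizer")
  ct <- coefficient_tests(fit)
  dim_rows <- ct[ct$term == "dimerizer", ]
  expect_equal(e_dim$estimate, dim_rows$estimate, tolerance = 1e-12)
  expect_equal(e_dim$p_value, dim_rows$p_value, tolerance = 1e-12)
  # preset equals its explicit vector
  p1 <- contrast(fit, "v600e-brafwt")
  p2 <- contrast(fit, c(0, -1, 1, 0, 0, 0))
  expect_equal(p1$estimate, p2$estimate)
  expect_equal(unname(p1$estimate),
               unname(fit$coefficients[, "v600e"] - fit$coefficients[, "brafwt"]))
  # positive sign means the first-named variable increases log-LFQ more
  expect_identical(p1$sign, as.integer(sign(p1$estimate)))
  # contrast of a coefficient with itself: exactly 0 and flagged degenerate
  z <- contrast(fit, c(0, 1, 0, 0, 0, 0) - c(0, 1, 0, 0, 0, 0))
  expect_true(all(z$estimate == 0))
  expect_true(all(z$degenerate))
  expect_true(all(z$p_value == 1))
  expect_error(contrast(fit, c(1, 0)), "dimension mismatch")
})

test_that("R-squared stays in [0,1] and never drops when columns are added", {
  set.seed(11)
  n <- 24
  X1 <- cbind(`(Intercept)` = 1, a = rnorm(n), b = rnorm(n))
  V <- matrix(rnorm(15 * n), 15, n)
  colnames(V) <- rownames(X1) <- paste0("r", 1:n)
  f1 <- fit_ols(V, X = X1)
  expect_true(all(f1$r2 >= 0 & f1$r2 <= 1))
  X2 <- cbind(X1, noise = rnorm(n))
  rownames(X2) <- rownames(X1)
  f2 <- fit_ols(V, X = X2)
  expect_true(all(f2$r2 >= f1$r2 - 1e-12))
})

test_that("residuals sum to zero and predictions track run permutations", {
  s <- sim_complete(n_prot = 10, seed = 9, sigma = 0.6)
  fit <- fit_ols(s$im)
  pr <- predict_logLFQ(fit)
  resid <- s$im$values - pr$predicted
  expect_equal(unname(rowSums(resid)), rep(0, 10), tolerance = 1e-8)
  # permuting runs together with X rows permutes predictions identically
  perm <- sample(nrow(fit$X))
  pr2 <- predict_logLFQ(fit, fit$X[perm, ])
  expect_equal(unname(pr2$predicted), unname(pr$predicted[, perm]))
  # the paired table carries the measured values in matching order
  expect_equal(pr$table$measured, as.vector(s$im$values))
})

test_that("coefficient estimates are unbiased as replication grows", {
  d_sizes <- c(3, 10)
  bias <- vapply(d_sizes, function(nb) {
    d <- generate_design(nb, 1)
    beta <- matrix(0, 40, 5, dimnames = list(NULL, c("brafwt", "v600e",
      "dimerizer", "sorafenib", "vemurafenib")))
    beta[, "dimerizer"] <- 1.5
    tr <- ground_truth(sprintf("P%03d", 1:40), rep(25, 40), beta,
                       sigma_bio = 0, sigma_tech = 0.6,
                       censor_midpoint = -100, censor_slope = 0)
    s <- simulate_lfq(d, tr, seed = 100 + nb)
    im <- log2_transform(s$intensity)
    fit <- fit_ols(im, X = build_design(d))
    mean(fit$coefficients[, "dimerizer"] - 1.5)
  }, 0)
  expect_lt(abs(bias[2]), abs(bias[1]) + 0.05)
  expect_lt(abs(bias[2]), 0.05)
})
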