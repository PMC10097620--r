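test_that("PCA matches an independent eigendecomposition up to sign", {
  set.seed(14)
  V <- matrix(rnorm(50 * 10, 25, 2), 50, 10,
              dimnames = list(paste0("p", 1:50), paste0("r", 1:10)))
  pca <- run_pca(V)
  ev <- pca$explained_variance
  expect_equal(sum(ev), 1, tolerance = 1e-12)
  expect_true(all(diff(ev) <= 1e-12))
  # covariance eigensolver oracle on the centred sample matrix
  Xc <- scale(t(V), scale = FALSE)
  eig <- eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE)
  scores_oracle <- Xc %*% eig$vectors
  for (k in 1:5) {
    a <- pca$scores[, k]; b <- scores_oracle[, k]
    expect_equal(abs(sum(a * b)) / (sqrt(sum(a^2)) * sqrt(sum(b^2))), 1,
                 tolerance = 1e-8)
    expect_equal(ev[k], eig$values[k] / sum(eig$values), tolerance = 1e-8)
  }
  # sample reordering permutes scores (up to component sign)
  perm <- sample(10)
  pca2 <- run_pca(V[, perm])
  for (k in 1:3) {
    expect_true(isTRUE(all.equal(pca2$scores[, k], pca$scores[perm, k],
                                 tolerance = 1e-8)) ||
                isTRUE(all.equal(pca2$scores[, k], -pca$scores[perm, k],
                                 tolerance = 1e-8)))
  }
  # identical samples project identically
  V2 <- V; V2[, 2] <- V2[, 1]
  s2 <- run_pca(V2)$scores
  expect_equal(s2[1, ], s2[2, ], tolerance = 1e-8)
  expect_error(run_pca(V[, 1, drop = FALSE]), "fewer than 2")
})

test_that("outlier flagging isolates displaced samples and is conservative", {
  des <- mini_design(4, 3)
  scores <- matrix(0, 12, 2, dimnames = list(des$run_id, c("PC1", "PC2")))
  set.seed(2)
  scores[] <- rnorm(24, sd = 1)
  base <- flag_outliers(scores, des, k_sd = 4)
  expect_false(any(base$flagged))
  # displace one sample far from its condition centroid
  scores2 <- scores
  scores2[5, ] <- scores2[5, ] + 60
  out <- flag_outliers(scores2, des, k_sd = 4)
  expect_identical(out$run_id[out$flagged], des$run_id[5])
  # k_sd = Inf flags nothing
  expect_false(any(flag_outliers(scores2, des, k_sd = Inf)$flagged))
  # all-identical scores: no flags
  expect_false(any(flag_outliers(matrix(1, 12, 2,
    dimnames = list(des$run_id, NULL)), des)$flagged))
})

test_that("a corrupted biological replicate is flagged on both its runs", {
  d <- generate_design(3, 2)
  tr <- default_ground_truth(n_proteins = 150, prop_active = 0.1,
                             n_contaminant = 0, n_reverse = 0, n_onlysite = 0,
                             censor_midpoint = -100, seed = 5)
  s <- simulate_lfq(d, tr, seed = 5)
  V <- s$intensity
  rownames(V) <- s$protein_ids
  L <- log2(V)
  # shift both technical replicates of one biological replicate
  bad <- d$run_id[d$condition == "V600E + S + A/C" & d$bio_rep == 2]
  expect_length(bad, 2)
  L[, bad] <- L[, bad] + 8
  pca <- run_pca(L)
  out <- flag_outliers(pca, d, k_sd = 4)
  expect_setequal(out$run_id[out$flagged], bad)
})

test_that("overlap matrix has Table-1 numerator/denominator semantics", {
  ov <- overlap_matrix(list(A = c("p1", "p2", "p3"), B = c("p2", "p3")))
  expect_equal(unname(ov$numerator["A", "B"]), 2)
  expect_equal(unname(ov$denominator["A"]), 3)
  expect_equal(format(ov)["A", "B"], "2/3")
  expect_equal(format(ov)["B", "A"], "2/2")
  expect_equal(format(ov)["A", "A"], "3/3")
  long <- as.data.frame(ov)
  expect_equal(long$numerator[long$row == "A" & long$column == "B"], 2)
  expect_equal(long$denominator[long$row == "A" & long$column == "B"], 3)
  expect_warning(overlap_matrix(list(A = c("p1", "p1"), B = "p1")),
                 "deduplicated")
})

test_that("overlap invariants hold and match a brute-force oracle on random families", {
  set.seed(23)
  for (rep in 1:100) {
    k <- sample(2:6, 1)
    universe <- paste0("g", 1:30)
    sets <- lapply(seq_len(k), function(i)
      sample(universe, sample(0:15, 1)))
    names(sets) <- paste0("S", seq_len(k))
    ov <- overlap_matrix(sets)
    # brute-force double loop
    for (i in seq_len(k)) for (j in seq_len(k)) {
      expect_equal(unname(ov$numerator[i, j]),
                   length(intersect(sets[[i]], sets[[j]])))
    }
    expect_equal(unname(diag(ov$numerator)), unname(lengths(sets)))
    expect_identical(ov$numerator, t(ov$numerator))
    for (i in seq_len(k)) for (j in seq_len(k))
      expect_lte(ov$numerator[i, j], min(length(sets[[i]]), length(sets[[j]])))
  }
})

test_that("reference comparison intersects against a local identifier list", {
  set.seed(4)
  prey <- paste0("GENE", 1:20)
  ref <- c(prey[1:5], paste0("OTHER", 1:3))
  r <- compare_reference(prey, ref)
  expect_equal(r$n_shared, 5)
  expect_setequal(r$shared, prey[1:5])
  expect_equal(compare_reference(prey, prey)$n_shared, 20)
  expect_equal(compare_reference(prey, "ZZZ")$n_shared, 0)
  expect_warning(r0 <- compare_reference(prey, character(0)), "empty")
  expect_equal(r0$n_shared, 0)
  # file-based reference with comments and blank lines
  f <- withr::local_tempfile()
  writeLines(c("# reference interactors", "", prey[3:7]), f)
  rf <- compare_reference(prey, f)
  expect_equal(rf$n_shared, 5)
})
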