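make_two_group <- function(x, y) {
  V <- matrix(c(x, y), nrow = 1)
  colnames(V) <- c(paste0("a", seq_along(x)), paste0("b", seq_along(y)))
  rownames(V) <- "p1"
  des <- data.frame(run_id = colnames(V),
                    condition = rep(c("T", "C"), c(length(x), length(y))),
                    stringsAsFactors = FALSE)
  list(V = V, des = des)
}

test_that("right-tailed t-test matches the textbook cases", {
  g <- make_two_group(c(1, 2, 3), c(1, 2, 3))
  r <- right_tailed_ttest(g$V, "T", "C", design = g$des)
  expect_equal(r$diff, 0)
  expect_equal(r$p_value, 0.5)

  g2 <- make_two_group(c(10, 10, 10) + c(-0.1, 0, 0.1),
                       c(8, 8, 8) + c(-0.1, 0, 0.1))
  r2 <- right_tailed_ttest(g2$V, "T", "C", design = g2$des)
  expect_equal(r2$diff, 2, tolerance = 1e-12)
  expect_lt(r2$p_value, 0.05)

  # fewer than 2 values in a group -> skipped with reason
  g3 <- make_two_group(5, c(1, 2, 3))
  r3 <- right_tailed_ttest(g3$V, "T", "C", design = g3$des)
  expect_true(is.na(r3$p_value))
  expect_match(attr(r3, "skipped")$reason, "fewer than 2")
})

test_that("Welch statistic and tail probability match stats::t.test to 1e-10", {
  set.seed(31)
  for (i in 1:60) {
    x <- rnorm(3 + i %% 4, sd = runif(1, 0.5, 2))
    y <- rnorm(3 + (i + 1) %% 3, mean = rnorm(1), sd = runif(1, 0.5, 2))
    g <- make_two_group(x, y)
    r <- right_tailed_ttest(g$V, "T", "C", design = g$des)
    o <- t.test(x, y, alternative = "greater")
    expect_equal(r$p_value, unname(o$p.value), tolerance = 1e-10)
    expect_equal(r$t_stat, unname(o$statistic), tolerance = 1e-10)
    rp <- right_tailed_ttest(g$V, "T", "C", design = g$des, var_equal = TRUE)
    op <- t.test(x, y, alternative = "greater", var.equal = TRUE)
    expect_equal(rp$p_value, unname(op$p.value), tolerance = 1e-10)
  }
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
  set.seed(17)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("differential calls require both the fold-change and the q gate", {
  res <- data.frame(protein = c("a", "b", "c"),
                    comparison = "T vs C",
                    diff = c(1.0, 0.3, 3.0),
                    p_value = c(0.0001, 0.00001, 0.2))
  out <- call_differential(res, fold_change = 1.5, alpha = 0.05)
  expect_true(out$significant_bh[out$protein == "a"])
  expect_false(out$significant_bh[out$protein == "b"])  # FC gate
  expect_false(out$significant_bh[out$protein == "c"])  # q gate
  expect_true(all(out$q_value >= out$p_value))
  expect_identical(attr(out, "interactors")[["T vs C"]], "a")
})

test_that("s0 statistic follows its arithmetic definition and reductions", {
  expect_equal(s0_statistic(1.0, 0, 0.1), 10)
  expect_equal(s0_statistic(2, 0.4, 0), 5)        # s0 = 0: plain t form
  expect_true(is.na(s0_statistic(1, 0, 0)))        # undefined denominator
  expect_equal(s0_statistic(c(1, -1), c(0.1, 0.3), 0.1), c(5, -2.5))
})

test_that("exhaustive permutation FDR reproduces the enumeration oracle", {
  set.seed(5)
  V <- matrix(rnorm(40 * 6, 25, 1), 40, 6)
  V[1:8, 1:3] <- V[1:8, 1:3] + 2.5
  rownames(V) <- sprintf("p%02d", 1:40)
  colnames(V) <- paste0("r", 1:6)
  des <- data.frame(run_id = colnames(V),
                    condition = rep(c("T", "C"), each = 3))
  pf <- permutation_fdr(V, "T", "C", design = des, s0 = 0.1,
                        target_fdr = 0.1, exhaustive = TRUE)
  expect_equal(pf$n_randomisations, choose(6, 3))

  d_obs <- apply(V, 1, function(r) dstat_oracle(r[1:3], r[4:6], 0.1))
  splits <- combn(6, 3, simplify = FALSE)
  perm <- unlist(lapply(splits, function(s)
    apply(V, 1, function(r) dstat_oracle(r[s], r[-s], 0.1))))
  cand <- sort(unique(d_obs[d_obs > 0]))
  fdr <- vapply(cand, function(cc) (sum(perm >= cc) / length(splits)) /
                  sum(d_obs >= cc), 0)
  thr <- if (any(fdr <= 0.1)) cand[which(fdr <= 0.1)[1]] else Inf
  expect_equal(pf$fdr_table$fdr_est, unname(fdr), tolerance = 1e-12)
  expect_equal(pf$threshold, thr, tolerance = 1e-12)
  dd <- rowMeans(V[, 1:3]) - rowMeans(V[, 4:6])
  expect_setequal(pf$significant, rownames(V)[d_obs >= thr & dd > 0])
})

test_that("sampled permutation FDR is stable across seeds and the curve sits at the threshold", {
  set.seed(9)
  V <- matrix(rnorm(60 * 8, 25, 1), 60, 8)
  V[1:10, 1:4] <- V[1:10, 1:4] + 2
  rownames(V) <- sprintf("p%02d", 1:60)
  colnames(V) <- paste0("r", 1:8)
  des <- data.frame(run_id = colnames(V),
                    condition = rep(c("T", "C"), each = 4))
  ns <- vapply(1:8, function(s)
    length(permutation_fdr(V, "T", "C", design = des, n_randomisations = 150,
                           seed = s)$significant), 0L)
  expect_lt(diff(range(ns)), 8)  # binomial-scale wobble only
  pf <- permutation_fdr(V, "T", "C", design = des, n_randomisations = 150,
                        seed = 1)
  # the cutoff curve is the locus d = threshold in (diff, -log10 p) space
  cv <- pf$curve
  spread <- cv$diff / pf$threshold - 0.1
  expect_equal(cv$diff / (spread + 0.1), rep(pf$threshold, nrow(cv)),
               tolerance = 1e-9)
  expect_equal(cv$neg_log10_p,
               -log10(pt(cv$diff / spread, 6, lower.tail = FALSE)),
               tolerance = 1e-9)
})

test_that("shifting a condition up never decreases diff nor increases p", {
  set.seed(12)
  x <- rnorm(4, 25); y <- rnorm(4, 25)
  g <- make_two_group(x, y)
  r0 <- right_tailed_ttest(g$V, "T", "C", design = g$des)
  for (delta in c(0.5, 1, 2)) {
    g2 <- make_two_group(x + delta, y)
    r <- right_tailed_ttest(g2$V, "T", "C", design = g2$des)
    expect_gt(r$diff, r0$diff)
    expect_lte(r$p_value, r0$p_value)
  }
})
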