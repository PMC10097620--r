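# Group summary statistics shared by the t-test and the permutation branch.
# idx1/idx2 index columns of V. Welch by default; pooled-variance optional.
.group_stats <- function(V, idx1, idx2, var_equal = FALSE) {
  x <- V[, idx1, drop = FALSE]
  y <- V[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(x))
  n2 <- rowSums(!is.na(y))
  m1 <- rowMeans(x, na.rm = TRUE)
  m2 <- rowMeans(y, na.rm = TRUE)
  v1 <- .row_vars(x)
  v2 <- .row_vars(y)
  diff <- m1 - m2
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    a <- v1 / n1
    b <- v2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  list(n1 = n1, n2 = n2, diff = diff, se = se, df = df)
}

# Right-tail p from (diff, se, df); exact limits when the spread is zero.
.right_tail_p <- function(diff, se, df) {
  p <- ifelse(se > 0, stats::pt(diff / se, df, lower.tail = FALSE),
              ifelse(diff > 0, 0, ifelse(diff < 0, 1, 0.5)))
  p
}

#' Right-tailed two-sample t-test of a condition against its control
#'
#' Tests, per protein, whether abundance is higher in the treatment group
#' than in the control group: `diff = mean(condition) - mean(control)` and
#' the p-value is the right-tail probability of the two-sample statistic
#' (Welch by default; set `var_equal = TRUE` for the pooled-variance test).
#' Proteins with fewer than 2 values in either group are skipped (all test
#' columns `NA`, reason recorded in the `skipped` attribute).
#'
#' @param im An `intensity_matrix` (normally fully imputed) or a numeric
#'   matrix.
#' @param condition,control Condition labels to compare.
#' @param design Run design mapping columns to conditions.
#' @param var_equal Use the pooled-variance statistic instead of Welch.
#' @return data.frame with one row per protein: `protein`, `comparison`,
#'   `n_condition`, `n_control`, `diff`, `pooled_spread` (the denominator of
#'   the plain t statistic), `t_stat`, `df`, `p_value`, `neg_log10_p`.
#' @export
right_tailed_ttest <- function(im, condition, control, design = NULL,
                               var_equal = FALSE) {
  if (inherits(im, "intensity_matrix")) {
    V <- im$values
    cond <- .im_conditions(im, design)
  } else {
    V <- as.matrix(im)
    if (is.null(design)) stop("a design is required for a plain matrix")
    cond <- design$condition[match(colnames(V), design$run_id)]
  }
  idx1 <- which(cond == condition)
  idx2 <- which(cond == control)
  if (!length(idx1)) stop("unknown condition: ", condition)
  if (!length(idx2)) stop("unknown control: ", control)
  st <- .group_stats(V, idx1, idx2, var_equal)
  ok <- st$n1 >= 2 & st$n2 >= 2
  t_stat <- ifelse(st$se > 0, st$diff / st$se,
                   ifelse(st$diff == 0, 0, sign(st$diff) * Inf))
  p <- .right_tail_p(st$diff, st$se, st$df)
  t_stat[!ok] <- NA_real_
  p[!ok] <- NA_real_
  out <- data.frame(protein = rownames(V) %||% as.character(seq_len(nrow(V))),
                    comparison = paste(condition, "vs", control),
                    n_condition = st$n1, n_control = st$n2,
                    diff = ifelse(ok, st$diff, NA_real_),
                    pooled_spread = ifelse(ok, st$se, NA_real_),
                    t_stat = t_stat, df = ifelse(ok, st$df, NA_real_),
                    p_value = p, neg_log10_p = -log10(p),
                    stringsAsFactors = FALSE)
  if (any(!ok))
    attr(out, "skipped") <- data.frame(protein = out$protein[!ok],
                                       reason = "fewer than 2 values in a group")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (with the usual monotonicity
#' enforcement) of a vector of p-values.
#'
#' @param p Numeric p-values in \[0, 1\] (`NA` allowed and propagated).
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("data error: p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differential interactors with the fold-change / adjusted-p rule
#'
#' Adds BH q-values (adjusted within each comparison) and the significance
#' call `significant_bh = diff > log2(fold_change) & q_value < alpha` to a
#' [right_tailed_ttest()] result table.
#'
#' @param results Result table from [right_tailed_ttest()] (rows from
#'   several comparisons may be stacked; adjustment is per comparison).
#' @param fold_change Linear fold-change threshold (default 1.5, i.e. a log2
#'   difference above `log2(1.5)`).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return The table with `q_value` and `significant_bh` columns; the
#'   significant protein ids per comparison are attached as the
#'   `interactors` attribute (a named list).
#' @export
call_differential <- function(results, fold_change = 1.5, alpha = 0.05) {
  stopifnot(fold_change > 1, alpha > 0, alpha < 1,
            all(c("protein", "comparison", "diff", "p_value") %in% names(results)))
  results$q_value <- stats::ave(results$p_value, results$comparison,
                                FUN = bh_adjust)
  results$significant_bh <- !is.na(results$q_value) &
    results$diff > log2(fold_change) & results$q_value < alpha
  attr(results, "interactors") <-
    lapply(split(results, results$comparison),
           function(d) d$protein[d$significant_bh])
  results
}

#' s0-modified test statistic
#'
#' `d = diff / (pooled_spread + s0)`: the artificial within-group variance
#' `s0` stabilises the denominator so near-zero-variance proteins do not
#' dominate the significance ranking. With `s0 = 0` the statistic reduces to
#' the plain t statistic.
#'
#' @param diff Mean log2 difference(s).
#' @param pooled_spread Denominator of the plain t statistic (>= 0).
#' @param s0 Artificial within-group variance term (>= 0).
#' @return The modified statistic; `NA` where `pooled_spread + s0 == 0`.
#' @export
s0_statistic <- function(diff, pooled_spread, s0) {
  stopifnot(s0 >= 0, all(pooled_spread >= 0, na.rm = TRUE))
  den <- pooled_spread + s0
  out <- diff / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' Permutation-based FDR with a volcano cutoff curve
#'
#' Computes the observed s0-modified statistics for the condition-vs-control
#' comparison, re-computes them under random relabelings of the pooled
#' columns into groups of the original sizes, and estimates, for each
#' candidate threshold `c` (the positive observed statistics), the FDR as
#' the mean permuted exceedance count divided by the observed exceedance
#' count. The selected threshold is the smallest candidate whose estimated
#' FDR is at or below `target_fdr`; proteins at or above it with a positive
#' difference are significant ("all points to the right"). The cutoff curve
#' is reported as the locus in (diff, -log10 p) space corresponding to
#' `d = threshold`, using the pooled degrees of freedom `n1 + n2 - 2`.
#'
#' @inheritParams right_tailed_ttest
#' @param s0 Artificial within-group variance (default 0.1).
#' @param target_fdr Target FDR for truncation (default 0.1).
#' @param n_randomisations Number of random relabelings (default 250);
#'   ignored when `exhaustive = TRUE`.
#' @param seed Seed for the relabelings.
#' @param exhaustive Enumerate all distinct relabelings instead of sampling
#'   (feasible for small groups, e.g. all 20 splits of 3 vs 3).
#' @param n_curve Number of points on the reported cutoff curve.
#' @return A list of class `perm_fdr`: `threshold`, `fdr_table` (candidate
#'   thresholds with observed / mean permuted exceedance counts and the FDR
#'   estimate), `significant` (protein ids), `table` (per-protein `diff`,
#'   `pooled_spread`, `d_stat`, `p_value`, `neg_log10_p`,
#'   `significant_perm`), `curve`, `n_randomisations`.
#' @export
permutation_fdr <- function(im, condition, control, design = NULL,
                            s0 = 0.1, target_fdr = 0.1,
                            n_randomisations = 250, seed = 1,
                            exhaustive = FALSE, var_equal = FALSE,
                            n_curve = 200) {
  if (inherits(im, "intensity_matrix")) {
    V <- im$values
    cond <- .im_conditions(im, design)
  } else {
    V <- as.matrix(im)
    if (is.null(design)) stop("a design is required for a plain matrix")
    cond <- design$condition[match(colnames(V), design$run_id)]
  }
  idx1 <- which(cond == condition)
  idx2 <- which(cond == control)
  if (!length(idx1)) stop("unknown condition: ", condition)
  if (!length(idx2)) stop("unknown control: ", control)
  n1 <- length(idx1)
  pool <- c(idx1, idx2)
  n <- length(pool)
  Vp <- V[, pool, drop = FALSE]

  dfun <- function(i1) {
    st <- .group_stats(Vp, i1, setdiff(seq_len(n), i1), var_equal)
    s0_statistic(st$diff, st$se, s0)
  }
  obs <- .group_stats(Vp, seq_len(n1), seq.int(n1 + 1, n), var_equal)
  d_obs <- s0_statistic(obs$diff, obs$se, s0)
  p_obs <- .right_tail_p(obs$diff, obs$se, obs$df)

  if (exhaustive) {
    splits <- utils::combn(n, n1, simplify = FALSE)
  } else {
    set.seed(.derive_seed(seed, paste0("perm_", condition)))
    splits <- lapply(seq_len(n_randomisations), function(b) sample.int(n, n1))
  }
  perm_d <- unlist(lapply(splits, dfun), use.names = FALSE)
  perm_d <- perm_d[is.finite(perm_d)]

  cand <- sort(unique(d_obs[is.finite(d_obs) & d_obs > 0]))
  if (length(cand)) {
    ds <- sort(d_obs[is.finite(d_obs)])
    ps <- sort(perm_d)
    n_ge_obs <- length(ds) - findInterval(cand, ds, left.open = TRUE)
    mean_ge_perm <- (length(ps) - findInterval(cand, ps, left.open = TRUE)) /
      length(splits)
    fdr_est <- mean_ge_perm / n_ge_obs
    hit <- which(fdr_est <= target_fdr)
    threshold <- if (length(hit)) cand[hit[1]] else Inf
    fdr_table <- data.frame(candidate = cand, n_observed = n_ge_obs,
                            mean_permuted = mean_ge_perm, fdr_est = fdr_est)
  } else {
    threshold <- Inf
    fdr_table <- data.frame(candidate = numeric(0), n_observed = numeric(0),
                            mean_permuted = numeric(0), fdr_est = numeric(0))
  }

  sig <- !is.na(d_obs) & is.finite(d_obs) & d_obs >= threshold & obs$diff > 0
  ids <- rownames(V) %||% as.character(seq_len(nrow(V)))

  curve <- NULL
  if (is.finite(threshold)) {
    df_c <- n - 2
    lo <- threshold * s0
    hi <- max(c(obs$diff, lo * 2), na.rm = TRUE) * 1.2
    dgrid <- seq(lo + (hi - lo) / n_curve, hi, length.out = n_curve)
    spread <- dgrid / threshold - s0
    pcurve <- stats::pt(dgrid / spread, df_c, lower.tail = FALSE)
    curve <- data.frame(diff = dgrid, neg_log10_p = -log10(pcurve))
  }

  structure(list(threshold = threshold,
                 fdr_table = fdr_table,
                 significant = ids[sig],
                 table = data.frame(protein = ids,
                                    comparison = paste(condition, "vs", control),
                                    diff = obs$diff, pooled_spread = obs$se,
                                    d_stat = d_obs, p_value = p_obs,
                                    neg_log10_p = -log10(p_obs),
                                    significant_perm = sig,
                                    stringsAsFactors = FALSE),
                 curve = curve,
                 n_randomisations = length(splits)),
            class = "perm_fdr")
}

#' @export
print.perm_fdr <- function(x, ...) {
  cat(sprintf("permutation FDR: threshold d >= %s, %d significant (of %d), %d relabelings\n",
              format(x$threshold, digits = 4), length(x$significant),
              nrow(x$table), x$n_randomisations))
  invisible(x)
}
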