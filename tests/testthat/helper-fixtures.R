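# Small builders shared across test files. All fixtures are generated in
# code; nothing is read from disk unless a test writes it first.

quietly <- function(expr) suppressMessages(expr)

# A generic design with n_cond conditions x n_rep runs (single technical
# replicate), enough for the filter / imputation / differential stages.
mini_design <- function(n_cond = 4, n_rep = 3) {
  cond <- paste0("C", seq_len(n_cond))
  d <- data.frame(run_id = paste0(rep(cond, each = n_rep), "_r",
                                  rep(seq_len(n_rep), n_cond)),
                  condition = rep(cond, each = n_rep),
                  bio_rep = rep(seq_len(n_rep), n_cond),
                  tech_rep = 1L,
                  stringsAsFactors = FALSE)
  class(d) <- c("sample_design", "data.frame")
  d
}

# Intensity matrix (log2 scale, NA = missing) wired to a design.
mini_im <- function(values, design) {
  if (is.null(colnames(values))) colnames(values) <- design$run_id
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("p%03d", seq_len(nrow(values)))
  new_intensity_matrix(values, design = design)
}

# Brute-force Benjamini-Hochberg step-up: p * m / rank, cumulative minimum
# from the largest rank, capped at 1. Independent of stats::p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Plain-loop s0 statistic for two groups of columns (oracle for the
# permutation branch).
dstat_oracle <- function(x, y, s0) {
  a <- stats::var(x) / length(x)
  b <- stats::var(y) / length(y)
  (mean(x) - mean(y)) / (sqrt(a + b) + s0)
}
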