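#' Downshifted-Gaussian imputation, separately for each column
#'
#' Missing cells in a column are drawn independently from a Gaussian with
#' mean `mean(observed) - downshift * sd(observed)` and standard deviation
#' `width * sd(observed)`, the standard model of left-censored (detection
#' limit) missingness in label-free proteomics. Observed cells are never
#' touched. Columns with fewer than 2 observed values fall back to the
#' pooled whole-matrix mean/sd with a warning; a floor of `sd_floor` guards
#' degenerate zero-variance columns.
#'
#' @param im An `intensity_matrix` (log2 scale).
#' @param width Imputation sd as a multiple of the observed column sd.
#' @param downshift Left shift in multiples of the observed column sd.
#' @param seed Integer seed; identical seeds give identical draws.
#' @param sd_floor Lower bound on the observed sd (log2 units).
#' @return The imputed `intensity_matrix`: no missing cells remain and
#'   `imputed_mask` marks exactly the formerly missing cells.
#' @export
impute_downshift <- function(im, width = 0.3, downshift = 1.8, seed = 1,
                             sd_floor = 0.01) {
  stopifnot(inherits(im, "intensity_matrix"), width > 0, downshift >= 0)
  V <- im$values
  miss <- is.na(V)
  if (!any(miss)) return(im)
  set.seed(.derive_seed(seed, "impute_downshift"))
  obs_all <- V[!miss]
  gm <- mean(obs_all)
  gs <- stats::sd(obs_all)
  imp <- im$imputed_mask
  for (j in seq_len(ncol(V))) {
    mj <- miss[, j]
    if (!any(mj)) next
    o <- V[!mj, j]
    if (length(o) < 2) {
      warning("column '", colnames(V)[j],
              "' has fewer than 2 observed values; using pooled matrix mean/sd")
      m <- gm; s <- gs
    } else {
      m <- mean(o); s <- stats::sd(o)
    }
    s <- max(s, sd_floor, na.rm = TRUE)
    V[mj, j] <- stats::rnorm(sum(mj), m - downshift * s, width * s)
    imp[mj, j] <- TRUE
  }
  new_intensity_matrix(V, imp, im$design)
}

#' Condition-wise log-normal imputation
#'
#' Each missing cell is drawn from a log-normal distribution whose log-scale
#' location is the mean of the protein's observed log2 values within the
#' same condition (draws are made, and stored, on the log2 scale). The
#' log-scale spread follows a fallback hierarchy, because a variance cannot
#' be estimated reliably from one or two replicates: (1) the protein's
#' within-condition sd when at least 3 values are observed; (2) the pooled
#' within-protein sd of the condition; (3) the pooled within-protein sd of
#' the whole matrix; all floored at `sd_floor`. When a protein has no
#' observed value in a condition, the location falls back to the protein's
#' observed mean across all runs (a protein observed nowhere is an error;
#' the valid-value filter makes that impossible upstream).
#'
#' @param im An `intensity_matrix` (log2 scale).
#' @param design Run design (defaults to the one attached to `im`).
#' @param seed Integer seed.
#' @param per_protein If `TRUE` (default) the location is the per-protein
#'   within-condition mean; if `FALSE`, parameters are estimated per
#'   condition globally (location and spread over all observed values of
#'   the condition).
#' @param sd_floor Lower bound on the spread (log2 units).
#' @return The imputed `intensity_matrix`.
#' @export
impute_lognormal <- function(im, design = NULL, seed = 1, per_protein = TRUE,
                             sd_floor = 0.01) {
  stopifnot(inherits(im, "intensity_matrix"))
  cond <- .im_conditions(im, design)
  V <- im$values
  miss <- is.na(V)
  if (!any(miss)) return(im)
  if (any(rowSums(!miss) == 0))
    stop("imputation error: protein(s) with no observed value in any run")
  set.seed(.derive_seed(seed, "impute_lognormal"))
  imp <- im$imputed_mask
  prot_mean_all <- rowMeans(V, na.rm = TRUE)

  conds <- unique(cond)
  # pooled within-(protein, condition) sd over the whole matrix
  ss_tot <- df_tot <- 0
  for (g in conds) {
    sub <- V[, cond == g, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    pv <- .row_vars(sub)
    ok <- n_obs >= 2 & !is.na(pv)
    ss_tot <- ss_tot + sum((n_obs[ok] - 1) * pv[ok])
    df_tot <- df_tot + sum(n_obs[ok] - 1)
  }
  global_sd <- if (df_tot > 0) sqrt(ss_tot / df_tot) else stats::sd(V[!miss])
  if (!is.finite(global_sd)) global_sd <- sd_floor

  for (g in conds) {
    cols <- which(cond == g)
    sub <- V[, cols, drop = FALSE]
    sub_miss <- miss[, cols, drop = FALSE]
    if (!any(sub_miss)) next
    n_obs <- rowSums(!is.na(sub))
    pm <- rowMeans(sub, na.rm = TRUE)
    pv <- .row_vars(sub)
    ok <- n_obs >= 2 & !is.na(pv)
    cond_sd <- if (any(ok))
      sqrt(sum((n_obs[ok] - 1) * pv[ok]) / sum(n_obs[ok] - 1)) else global_sd
    if (!is.finite(cond_sd)) cond_sd <- global_sd
    if (per_protein) {
      loc <- ifelse(n_obs >= 1, pm, prot_mean_all)
      spr <- ifelse(n_obs >= 3 & is.finite(sqrt(pv)) & !is.na(pv),
                    sqrt(pv), cond_sd)
    } else {
      loc <- rep(mean(sub[!sub_miss]), nrow(sub))
      s_all <- stats::sd(sub[!sub_miss])
      spr <- rep(if (is.finite(s_all)) s_all else cond_sd, nrow(sub))
    }
    spr <- pmax(spr, sd_floor)
    cells <- which(sub_miss, arr.ind = TRUE)
    draws <- stats::rnorm(nrow(cells), loc[cells[, 1]], spr[cells[, 1]])
    V[cbind(cells[, 1], cols[cells[, 2]])] <- draws
    imp[cbind(cells[, 1], cols[cells[, 2]])] <- TRUE
  }
  new_intensity_matrix(V, imp, im$design)
}
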