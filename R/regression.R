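#' Build the one-hot design matrix
#'
#' Intercept column of ones plus the five 0/1 experimental factors: BRAF
#' wild-type transfection, BRAF V600E transfection, A/C dimerizer treatment,
#' Sorafenib and Vemurafenib. The matrix is checked for full column rank;
#' a factor constant across all runs is reported by name.
#'
#' @param design A `sample_design` data.frame.
#' @return Runs x 6 numeric matrix with row names = run ids and columns
#'   `(Intercept)`, `brafwt`, `v600e`, `dimerizer`, `sorafenib`,
#'   `vemurafenib`.
#' @export
build_design <- function(design) {
  miss <- setdiff(.DESIGN_VARS, names(design))
  if (length(miss))
    stop("design error: missing factor column(s): ", paste(miss, collapse = ", "))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(design)[, .DESIGN_VARS]))
  storage.mode(X) <- "double"
  rownames(X) <- design$run_id
  const <- colnames(X)[-1][apply(X[, -1, drop = FALSE], 2,
                                 function(v) length(unique(v)) == 1)]
  if (length(const))
    stop("configuration error: design column(s) constant across all runs: ",
         paste(const, collapse = ", "))
  if (qr(X)$rank < ncol(X))
    stop("configuration error: design matrix is rank-deficient")
  X
}

#' Per-protein ordinary least squares on the one-hot design
#'
#' Fits, for every protein, the linear model of log2 LFQ intensity on the
#' design matrix by QR-based least squares. The residual variance is
#' `RSS / df_resid` with `df_resid = n_runs - n_columns`, and the
#' coefficient covariance is `residual variance x (X'X)^-1`.
#'
#' @param im A fully imputed `intensity_matrix` (no missing cells) or a
#'   complete numeric matrix with run-id column names.
#' @param X Design matrix from [build_design()]; defaults to building it
#'   from the design attached to `im`. Rows are aligned to the matrix
#'   columns by run id.
#' @return A list of class `regression_fit`: `coefficients` (proteins x 6),
#'   `se`, `sigma2`, `df_resid`, `XtXinv`, `r2`, `X`, `values`.
#' @export
fit_ols <- function(im, X = NULL) {
  V <- if (inherits(im, "intensity_matrix")) im$values else as.matrix(im)
  if (anyNA(V))
    stop("fit_ols requires a fully imputed matrix (no missing cells)")
  if (is.null(X)) {
    if (inherits(im, "intensity_matrix") && !is.null(im$design))
      X <- build_design(im$design)
    else stop("a design matrix is required")
  }
  if (!is.null(rownames(X)) && !is.null(colnames(V))) {
    idx <- match(colnames(V), rownames(X))
    if (anyNA(idx)) stop("design error: runs missing from the design matrix")
    X <- X[idx, , drop = FALSE]
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n != ncol(V)) stop("design rows do not match matrix columns")
  df_resid <- n - p
  if (df_resid <= 0)
    stop("error: non-positive residual degrees of freedom (n = ", n,
         ", p = ", p, ")")
  qrx <- qr(X)
  coefs <- qr.coef(qrx, t(V))                       # p x proteins
  fitted <- X %*% coefs
  res <- t(V) - fitted
  rss <- colSums(res^2)
  sigma2 <- rss / df_resid
  XtXinv <- chol2inv(chol(crossprod(X)))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  se <- sqrt(outer(sigma2, diag(XtXinv)))
  tss <- colSums(scale(t(V), scale = FALSE)^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, NA_real_)
  B <- t(coefs)
  dimnames(B) <- list(rownames(V), colnames(X))
  dimnames(se) <- dimnames(B)
  structure(list(coefficients = B, se = se, sigma2 = sigma2,
                 df_resid = df_resid, XtXinv = XtXinv, r2 = r2,
                 X = X, values = V),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("regression_fit: %d proteins, %d coefficients, %d residual df\n",
              nrow(x$coefficients), ncol(x$coefficients), x$df_resid))
  invisible(x)
}

#' t-tests of the regression coefficients
#'
#' Two-sided t-test of each coefficient against zero (`t = estimate / se`
#' on `df_resid` degrees of freedom), with BH adjustment across proteins
#' within each coefficient. A zero standard error with a nonzero estimate
#' yields `t = +/-Inf`, `p = 0` and is flagged in the `degenerate` column.
#'
#' @param fit A `regression_fit`.
#' @return Long data.frame: `protein`, `term`, `estimate`, `se`, `t_stat`,
#'   `df`, `p_value`, `q_value`, `degenerate`.
#' @export
coefficient_tests <- function(fit) {
  stopifnot(inherits(fit, "regression_fit"))
  B <- fit$coefficients
  SE <- fit$se
  t_stat <- ifelse(SE > 0, B / SE, ifelse(B == 0, 0, sign(B) * Inf))
  p <- ifelse(SE > 0, 2 * stats::pt(-abs(t_stat), fit$df_resid),
              ifelse(B == 0, 1, 0))
  out <- data.frame(protein = rep(rownames(B), times = ncol(B)),
                    term = rep(colnames(B), each = nrow(B)),
                    estimate = as.vector(B), se = as.vector(SE),
                    t_stat = as.vector(t_stat), df = fit$df_resid,
                    p_value = as.vector(p),
                    degenerate = as.vector(SE == 0),
                    stringsAsFactors = FALSE)
  out$q_value <- stats::ave(out$p_value, out$term, FUN = bh_adjust)
  out[, c("protein", "term", "estimate", "se", "t_stat", "df",
          "p_value", "q_value", "degenerate")]
}

#' Named contrast presets over the design coefficients
#'
#' The three comparison families of the study: mutant versus wild-type
#' transfection (`v600e - brafwt`), the two RAF inhibitors against each
#' other (`sorafenib - vemurafenib`), and the dimerizer effect (monomer vs
#' dimer state).
#'
#' @return Named list of length-6 contrast vectors in design-column order.
#' @export
contrast_presets <- function() {
  list("v600e-brafwt"          = c(0, -1, 1, 0, 0, 0),
       "sorafenib-vemurafenib" = c(0, 0, 0, 0, 1, -1),
       "dimerizer"             = c(0, 0, 0, 1, 0, 0))
}

#' Contrast analysis: differences of regression coefficients
#'
#' For contrast vector `c`, the estimate is `c' beta_hat`, its squared
#' standard error `sigma2 * c' (X'X)^-1 c`, tested two-sided on `df_resid`
#' degrees of freedom with BH adjustment across proteins. A positive sign
#' means the first-named variable increases log-LFQ more.
#'
#' @param fit A `regression_fit`.
#' @param contrast A preset name (see [contrast_presets()]) or a numeric
#'   vector with one entry per design column.
#' @param name Label for the output (defaults to the preset name or
#'   `"custom"`).
#' @return data.frame: `protein`, `contrast`, `estimate`, `se`, `t_stat`,
#'   `df`, `p_value`, `q_value`, `sign`, `degenerate`.
#' @export
contrast <- function(fit, contrast, name = NULL) {
  stopifnot(inherits(fit, "regression_fit"))
  if (is.character(contrast) && length(contrast) == 1) {
    name <- name %||% contrast
    cvec <- contrast_presets()[[contrast]]
    if (is.null(cvec)) stop("unknown contrast preset: ", contrast)
  } else {
    cvec <- as.numeric(contrast)
  }
  if (length(cvec) != ncol(fit$coefficients))
    stop("dimension mismatch: contrast has ", length(cvec),
         " entries, design has ", ncol(fit$coefficients), " columns")
  est <- drop(fit$coefficients %*% cvec)
  qf <- max(drop(t(cvec) %*% fit$XtXinv %*% cvec), 0)
  se <- sqrt(fit$sigma2 * qf)
  t_stat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, sign(est) * Inf))
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t_stat), fit$df_resid),
              ifelse(est == 0, 1, 0))
  data.frame(protein = rownames(fit$coefficients),
             contrast = name %||% "custom",
             estimate = est, se = se, t_stat = t_stat, df = fit$df_resid,
             p_value = p, q_value = bh_adjust(p),
             sign = as.integer(sign(est)), degenerate = se == 0,
             stringsAsFactors = FALSE)
}

#' Predicted log-LFQ intensities from the fitted model
#'
#' `X %*% beta_hat` per protein, paired with the measured values when the
#' prediction design equals the training design (the measured-vs-predicted
#' view used to judge how well the one-hot model explains the data).
#'
#' @param fit A `regression_fit`.
#' @param X Design matrix to predict for (default: the training design).
#' @return List with `predicted` (proteins x runs matrix) and `table` (long
#'   data.frame `protein`, `run_id`, `predicted`, `measured`; `measured` is
#'   `NA` for runs outside the training design).
#' @export
predict_logLFQ <- function(fit, X = fit$X) {
  stopifnot(inherits(fit, "regression_fit"),
            ncol(X) == ncol(fit$coefficients))
  pred <- fit$coefficients %*% t(X)                 # proteins x runs
  colnames(pred) <- rownames(X)
  run_ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  measured <- matrix(NA_real_, nrow(pred), ncol(pred))
  if (!is.null(colnames(fit$values))) {
    hit <- match(run_ids, colnames(fit$values))
    measured[, !is.na(hit)] <- fit$values[, hit[!is.na(hit)], drop = FALSE]
  }
  tab <- data.frame(protein = rep(rownames(pred), times = ncol(pred)),
                    run_id = rep(run_ids, each = nrow(pred)),
                    predicted = as.vector(pred),
                    measured = as.vector(measured),
                    stringsAsFactors = FALSE)
  list(predicted = pred, table = tab)
}
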