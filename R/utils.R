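`%||%` <- function(a, b) if (is.null(a)) b else a

#' The five one-hot design variables of the experiment
#'
#' Order matters: it is the column order of [build_design()] after the
#' intercept, and the column order of the `beta` matrix in a [ground_truth()]
#' object.
#' @keywords internal
.DESIGN_VARS <- c("brafwt", "v600e", "dimerizer", "sorafenib", "vemurafenib")

# Stage-local seed derivation so each randomised stage can be re-run
# independently while staying reproducible from one master seed.
# Kept below 2^31 - 1 so the result is always a valid R integer seed.
.derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

# Row-wise sample variance with NA removal; NA where fewer than 2 values.
.row_vars <- function(x) {
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  v <- rowSums((x - m)^2, na.rm = TRUE) / pmax(n - 1, 1)
  v[n < 2] <- NA_real_
  v
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Matrix writer that keeps rownames in a leading identifier column.
.write_matrix_tsv <- function(m, path, id_col = "protein") {
  df <- data.frame(rownames(m) %||% seq_len(nrow(m)), as.data.frame(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  .write_tsv(df, path)
}
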