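#' Principal-component analysis of the samples
#'
#' Projects the samples (runs) onto the principal components of the
#' protein-intensity space after centering each protein. Deterministic up
#' to the usual sign ambiguity of eigenvectors.
#'
#' @param im A fully imputed `intensity_matrix` (or complete numeric
#'   matrix, proteins x runs).
#' @return List of class `lfq_pca`: `scores` (samples x components),
#'   `explained_variance` (fractions, non-increasing, summing to 1),
#'   `loadings`, `design`.
#' @export
run_pca <- function(im) {
  V <- if (inherits(im, "intensity_matrix")) im$values else as.matrix(im)
  if (anyNA(V)) stop("run_pca requires a fully imputed matrix")
  if (ncol(V) < 2) stop("error: fewer than 2 samples")
  pc <- stats::prcomp(t(V), center = TRUE, scale. = FALSE)
  structure(list(scores = pc$x,
                 explained_variance = pc$sdev^2 / sum(pc$sdev^2),
                 loadings = pc$rotation,
                 design = if (inherits(im, "intensity_matrix")) im$design),
            class = "lfq_pca")
}

#' @export
print.lfq_pca <- function(x, ...) {
  cat(sprintf("PCA of %d samples; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$explained_variance[1],
              100 * x$explained_variance[2]))
  invisible(x)
}

#' Flag outlier samples in principal-component space
#'
#' A sample is flagged when its Euclidean distance from its condition
#' centroid in the first two components exceeds the median distance by more
#' than `k_sd` robust standard deviations (MAD) of all distances. The
#' centroid is the componentwise median of the condition's samples, so a
#' corrupted replicate cannot drag the centroid toward itself and implicate
#' its healthy condition-mates. Flagging only: removing a flagged run is a
#' separate, explicit action by the analyst.
#'
#' @param pca An `lfq_pca` object (or a samples x components score matrix
#'   with run-id row names).
#' @param design Run design mapping samples to conditions (defaults to the
#'   one carried by the PCA object).
#' @param k_sd Robust-sd multiplier (default 4); `Inf` flags nothing.
#' @return data.frame: `run_id`, `condition`, `distance`, `robust_z`,
#'   `flagged`.
#' @export
flag_outliers <- function(pca, design = NULL, k_sd = 4) {
  scores <- if (inherits(pca, "lfq_pca")) pca$scores else as.matrix(pca)
  design <- design %||% (if (inherits(pca, "lfq_pca")) pca$design)
  if (is.null(design)) stop("a design is required to group samples by condition")
  idx <- match(rownames(scores), design$run_id)
  if (anyNA(idx)) stop("design error: samples not present in the design")
  cond <- design$condition[idx]
  S <- scores[, seq_len(min(2, ncol(scores))), drop = FALSE]
  cent <- do.call(rbind, lapply(split(seq_along(cond), cond), function(i)
    apply(S[i, , drop = FALSE], 2, stats::median)))
  d <- sqrt(rowSums((S - cent[cond, , drop = FALSE])^2))
  rz <- (d - stats::median(d)) / max(stats::mad(d), 1e-12)
  data.frame(run_id = rownames(scores), condition = cond,
             distance = d, robust_z = rz, flagged = rz > k_sd,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Interactor-set overlap matrix
#'
#' For every ordered pair of conditions (i, j): the numerator is the number
#' of interactors of condition i also found in condition j, and the
#' denominator is the number of interactors of condition i (the row). The
#' diagonal is therefore n/n, and numerators are symmetric.
#'
#' @param sets Named list of interactor identifier vectors, one per
#'   condition. Duplicates within a set are deduplicated with a warning.
#' @return List of class `overlap_matrix`: `labels`, `numerator`
#'   (conditions x conditions intersection counts), `denominator` (set
#'   sizes). Printing renders "numerator/denominator" strings.
#' @export
overlap_matrix <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a named list (one name per condition)")
  dup <- vapply(sets, function(s) anyDuplicated(s) > 0, logical(1))
  if (any(dup)) {
    warning("duplicate identifiers deduplicated in: ",
            paste(names(sets)[dup], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  ids <- sort(unique(unlist(sets, use.names = FALSE)))
  M <- matrix(vapply(sets, function(s) ids %in% s, logical(length(ids))),
              nrow = length(ids), ncol = length(sets))
  num <- crossprod(M)
  storage.mode(num) <- "integer"
  dimnames(num) <- list(names(sets), names(sets))
  structure(list(labels = names(sets), numerator = num,
                 denominator = lengths(sets)),
            class = "overlap_matrix")
}

#' @export
format.overlap_matrix <- function(x, ...) {
  out <- matrix(sprintf("%d/%d", x$numerator,
                        rep(x$denominator, times = length(x$denominator))),
                nrow(x$numerator), dimnames = dimnames(x$numerator))
  out
}

#' @export
print.overlap_matrix <- function(x, ...) {
  print(format(x), quote = FALSE)
  invisible(x)
}

#' @export
as.data.frame.overlap_matrix <- function(x, ...) {
  k <- length(x$labels)
  data.frame(row = rep(x$labels, times = k),
             column = rep(x$labels, each = k),
             numerator = as.vector(x$numerator),
             denominator = rep(unname(x$denominator), times = k),
             stringsAsFactors = FALSE)
}

#' Compare an interactor set against a reference interactor list
#'
#' Intersects the identified interactors with an externally supplied
#' reference list (for example interaction-database entries for the same
#' cell line, exported to a local identifier file; no network access).
#'
#' @param interactors Character vector of identifiers.
#' @param reference Character vector of reference identifiers, or the path
#'   of a text file with one identifier per line (empty lines and lines
#'   starting with `#` are skipped).
#' @return List of class `reference_overlap`: `n_interactors`,
#'   `n_reference`, `n_shared`, `shared` (sorted shared identifiers).
#' @export
compare_reference <- function(interactors, reference) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- readLines(reference, warn = FALSE)
    reference <- trimws(reference)
    reference <- reference[nzchar(reference) & !startsWith(reference, "#")]
  }
  interactors <- unique(as.character(interactors))
  reference <- unique(as.character(reference))
  if (!length(reference)) warning("empty reference list; overlap is empty")
  shared <- sort(intersect(interactors, reference))
  structure(list(n_interactors = length(interactors),
                 n_reference = length(reference),
                 n_shared = length(shared), shared = shared),
            class = "reference_overlap")
}

#' @export
print.reference_overlap <- function(x, ...) {
  cat(sprintf("reference overlap: %d of %d interactors found among %d reference entries\n",
              x$n_shared, x$n_interactors, x$n_reference))
  if (x$n_shared) cat("  ", paste(x$shared, collapse = ", "), "\n")
  invisible(x)
}
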