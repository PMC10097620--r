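#' Read a MaxQuant proteinGroups-dialect table
#'
#' Parses the tab-separated protein-group table: all `LFQ intensity <run>`
#' columns as non-negative numbers, and the three category flag columns
#' ("+" = flagged, empty = not). Both the `Contaminant` (MaxQuant 1.3) and
#' `Potential contaminant` (later versions) header spellings are accepted,
#' as are `Only identified by site` / `Identified only by site`.
#'
#' @param path Path to a tab-separated proteinGroups file.
#' @return A list of class `proteingroups`: `ids` (Protein IDs), `lfq`
#'   (proteins x runs numeric matrix, column names = run ids with the
#'   "LFQ intensity " prefix stripped), `flags` (data.frame `only_site`,
#'   `reverse`, `contaminant`, 0/1), `annotations` (all non-LFQ columns).
#' @export
read_proteingroups <- function(path) {
  if (!file.exists(path)) stop("proteinGroups file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"Protein IDs" %in% names(df))
    stop("proteinGroups schema error: missing column 'Protein IDs'")
  lfq_cols <- grep("^LFQ intensity ", names(df), value = TRUE)
  if (!length(lfq_cols))
    stop("proteinGroups schema error: no 'LFQ intensity <run>' columns")
  find_col <- function(cands) {
    hit <- cands[cands %in% names(df)]
    if (length(hit)) hit[1] else NA_character_
  }
  os <- find_col(c("Only identified by site", "Identified only by site",
                   "Only Identified by site"))
  rv <- find_col("Reverse")
  ct <- find_col(c("Contaminant", "Potential contaminant"))
  parse_flag <- function(cn) {
    if (is.na(cn)) return(rep(0L, nrow(df)))
    x <- df[[cn]]
    as.integer(!is.na(x) & x == "+")
  }
  V <- suppressWarnings(
    matrix(as.numeric(as.matrix(df[lfq_cols])), nrow(df),
           dimnames = list(NULL, sub("^LFQ intensity ", "", lfq_cols))))
  if (anyNA(V))
    stop("proteinGroups data error: non-numeric LFQ intensity values")
  if (any(V < 0))
    stop("proteinGroups data error: negative LFQ intensity")
  structure(list(ids = as.character(df[["Protein IDs"]]),
                 lfq = V,
                 flags = data.frame(only_site = parse_flag(os),
                                    reverse = parse_flag(rv),
                                    contaminant = parse_flag(ct)),
                 annotations = df[setdiff(names(df), lfq_cols)]),
            class = "proteingroups")
}

#' @export
print.proteingroups <- function(x, ...) {
  cat(sprintf("proteinGroups table: %d protein groups x %d runs (%d flagged)\n",
              length(x$ids), ncol(x$lfq), sum(rowSums(x$flags) > 0)))
  invisible(x)
}

#' Remove decoy and contaminant protein groups
#'
#' Drops every row flagged in any of the three categories: only identified
#' by a modification site, reverse (decoy database), or known contaminant.
#' All surviving rows are untouched; removal counts are attached as the
#' `removed` attribute and reported via [message()].
#'
#' @param pg A `proteingroups` object.
#' @return The filtered `proteingroups` object.
#' @export
filter_categories <- function(pg) {
  stopifnot(inherits(pg, "proteingroups"))
  fl <- pg$flags
  keep <- fl$only_site == 0 & fl$reverse == 0 & fl$contaminant == 0
  removed <- c(only_site = sum(fl$only_site > 0),
               reverse = sum(fl$reverse > 0),
               contaminant = sum(fl$contaminant > 0),
               total = sum(!keep))
  out <- pg
  out$ids <- pg$ids[keep]
  out$lfq <- pg$lfq[keep, , drop = FALSE]
  out$flags <- pg$flags[keep, , drop = FALSE]
  out$annotations <- pg$annotations[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  message(sprintf(
    "filter_categories: removed %d/%d rows (only-by-site %d, reverse %d, contaminant %d)",
    removed["total"], length(pg$ids), removed["only_site"],
    removed["reverse"], removed["contaminant"]))
  out
}

#' Intensity matrix with explicit missingness and imputation provenance
#'
#' @param values Proteins x runs numeric matrix on the log2 scale; `NA`
#'   marks missing cells.
#' @param imputed_mask Logical matrix of the same shape marking cells whose
#'   value was imputed; disjoint from the missing cells.
#' @param design Optional `sample_design` carried along for downstream
#'   stages.
#' @return A list of class `intensity_matrix` with `values`, `missing_mask`,
#'   `imputed_mask`, `design`.
#' @export
new_intensity_matrix <- function(values, imputed_mask = NULL, design = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(imputed_mask))
    imputed_mask <- matrix(FALSE, nrow(values), ncol(values))
  stopifnot(identical(dim(imputed_mask), dim(values)))
  missing_mask <- is.na(values)
  if (any(imputed_mask & missing_mask))
    stop("imputed cells cannot also be missing")
  dimnames(imputed_mask) <- dimnames(values)
  structure(list(values = values, missing_mask = missing_mask,
                 imputed_mask = imputed_mask, design = design),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d proteins x %d runs | %.1f%% missing, %.1f%% imputed\n",
              nrow(x$values), ncol(x$values),
              100 * mean(x$missing_mask), 100 * mean(x$imputed_mask)))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

.im_rows <- function(im, keep) {
  new_intensity_matrix(im$values[keep, , drop = FALSE],
                       im$imputed_mask[keep, , drop = FALSE],
                       im$design)
}

# Map intensity-matrix columns to their condition labels via the design.
.im_conditions <- function(im, design = NULL) {
  design <- design %||% im$design
  if (is.null(design))
    stop("a sample design is required (pass `design` or attach it to the matrix)")
  idx <- match(colnames(im$values), design$run_id)
  if (anyNA(idx))
    stop("design error: runs not present in the design: ",
         paste(colnames(im$values)[is.na(idx)], collapse = ", "))
  design$condition[idx]
}

#' Log2-transform raw LFQ intensities
#'
#' Positive intensities become log2 values; zero intensities are not valid
#' on the log scale and become missing cells.
#'
#' @param pg A `proteingroups` object (or a non-negative numeric matrix).
#' @param design Optional `sample_design` to attach.
#' @return An [new_intensity_matrix()] object; row names are the protein
#'   ids.
#' @export
log2_transform <- function(pg, design = NULL) {
  if (inherits(pg, "proteingroups")) {
    V <- pg$lfq
    rownames(V) <- make.unique(pg$ids)
  } else {
    V <- as.matrix(pg)
  }
  if (any(V < 0, na.rm = TRUE)) stop("data error: negative intensities")
  L <- log2(V)
  L[!is.na(V) & V == 0] <- NA_real_
  new_intensity_matrix(L, design = design)
}

#' Keep proteins with enough valid values in at least one condition
#'
#' Retains exactly those proteins with at least `min_valid` originally
#' observed (non-imputed) values in at least one condition group.
#'
#' @param im An `intensity_matrix`.
#' @param design Run design (defaults to the one attached to `im`).
#' @param min_valid Minimum observed values required in some group.
#' @return The filtered `intensity_matrix` (attribute `removed` = number of
#'   rows dropped).
#' @export
filter_min_valid <- function(im, design = NULL, min_valid = 3) {
  stopifnot(inherits(im, "intensity_matrix"), min_valid >= 1)
  cond <- .im_conditions(im, design)
  gs <- table(cond)
  if (min_valid > max(gs))
    stop("configuration error: min_valid (", min_valid,
         ") exceeds the largest group size (", max(gs), ")")
  obs <- !im$missing_mask & !im$imputed_mask
  counts <- vapply(unique(cond),
                   function(g) rowSums(obs[, cond == g, drop = FALSE]),
                   numeric(nrow(obs)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  keep <- apply(counts, 1, max) >= min_valid
  out <- .im_rows(im, keep)
  attr(out, "removed") <- sum(!keep)
  message(sprintf("filter_min_valid: kept %d/%d proteins (>= %d valid in >= 1 group)",
                  sum(keep), length(keep), min_valid))
  out
}

#' Discard proteins too sparse in every (or any) condition
#'
#' With the default quantifier `"every"`, a protein is discarded only when
#' every condition has strictly more than `max_missing` missing values among
#' its runs; a protein fully observed in even a single condition is
#' retained. The `"any"` quantifier discards as soon as one condition
#' exceeds the threshold.
#'
#' @inheritParams filter_min_valid
#' @param max_missing Missing-value threshold per condition (default 2).
#' @param quantifier `"every"` (default) or `"any"`.
#' @return The filtered `intensity_matrix`.
#' @export
filter_max_missing <- function(im, design = NULL, max_missing = 2,
                               quantifier = c("every", "any")) {
  stopifnot(inherits(im, "intensity_matrix"), max_missing >= 0)
  quantifier <- match.arg(quantifier)
  cond <- .im_conditions(im, design)
  miss <- im$missing_mask
  counts <- vapply(unique(cond),
                   function(g) rowSums(miss[, cond == g, drop = FALSE]),
                   numeric(nrow(miss)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  exceed <- counts > max_missing
  discard <- if (quantifier == "every") rowSums(exceed) == ncol(exceed)
             else rowSums(exceed) > 0
  out <- .im_rows(im, !discard)
  attr(out, "removed") <- sum(discard)
  message(sprintf(
    "filter_max_missing: kept %d/%d proteins (> %d missing in %s condition discards)",
    sum(!discard), length(discard), max_missing, quantifier))
  out
}

#' Average technical replicates into one column per biological replicate
#'
#' Optional stage (the default pipeline keeps technical replicates as
#' separate columns, mirroring the per-column treatment of the original
#' workflow). The collapsed cell is the mean of the observed log2 values of
#' the technical replicates; it is missing only when all of them are
#' missing, and marked imputed only when all contributing values were
#' imputed.
#'
#' @inheritParams filter_min_valid
#' @return An `intensity_matrix` with one column per (condition, biological
#'   replicate) and a matching collapsed design attached.
#' @export
collapse_technical_replicates <- function(im, design = NULL) {
  stopifnot(inherits(im, "intensity_matrix"))
  design <- design %||% im$design
  if (is.null(design) || !"bio_rep" %in% names(design))
    stop("collapse_technical_replicates requires a design with bio_rep labels")
  idx <- match(colnames(im$values), design$run_id)
  if (anyNA(idx)) stop("design error: runs not present in the design")
  d <- as.data.frame(design)[idx, , drop = FALSE]
  key <- paste(d$condition, d$bio_rep, sep = "\r")
  keys <- unique(key)
  V <- matrix(NA_real_, nrow(im$values), length(keys))
  IMP <- OBS_ANY <- matrix(FALSE, nrow(im$values), length(keys))
  for (k in seq_along(keys)) {
    cols <- which(key == keys[k])
    sub <- im$values[, cols, drop = FALSE]
    n_ok <- rowSums(!is.na(sub))
    V[, k] <- ifelse(n_ok > 0, rowMeans(sub, na.rm = TRUE), NA_real_)
    obs <- (!im$missing_mask & !im$imputed_mask)[, cols, drop = FALSE]
    OBS_ANY[, k] <- rowSums(obs) > 0
    IMP[, k] <- !OBS_ANY[, k] & rowSums(im$imputed_mask[, cols, drop = FALSE]) > 0
  }
  first <- match(keys, key)
  d2 <- d[first, , drop = FALSE]
  d2$tech_rep <- 1L
  d2$run_id <- sprintf("%s_b%d", .sanitize_label(d2$condition), d2$bio_rep)
  rownames(d2) <- NULL
  class(d2) <- c("sample_design", "data.frame")
  colnames(V) <- d2$run_id
  rownames(V) <- rownames(im$values)
  new_intensity_matrix(V, IMP, design = d2)
}
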