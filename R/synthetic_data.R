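#' The 16 experimental conditions of the dimerization AP-MS study
#'
#' Four control conditions (empty vector; the FRB + FKBP tag-only pair,
#' untreated or treated with Sorafenib or Vemurafenib) and BRAF wild type or
#' BRAF V600E each crossed with \{no drug, Sorafenib, Vemurafenib\} and with
#' or without the A/C heterodimerizer. Each condition carries its one-hot
#' factor values and, for bait conditions, the drug-matched control it is
#' compared against. All controls were treated with the A/C dimerizer, so
#' `dimerizer = 1` on control rows while `brafwt = v600e = 0`.
#'
#' @return A data.frame with one row per condition: `condition`, the five
#'   0/1 factors `brafwt`, `v600e`, `dimerizer`, `sorafenib`, `vemurafenib`,
#'   `is_control`, and `control` (the matched control label, NA for
#'   controls).
#' @export
dimer_conditions <- function() {
  data.frame(
    condition = c("Empty vector", "FRB+FKBP", "FRB+FKBP + S", "FRB+FKBP + V",
                  "BRAF", "BRAF + A/C", "BRAF + S", "BRAF + S + A/C",
                  "BRAF + V", "BRAF + V + A/C",
                  "V600E", "V600E + A/C", "V600E + S", "V600E + S + A/C",
                  "V600E + V", "V600E + V + A/C"),
    brafwt      = c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
    v600e       = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1),
    dimerizer   = c(1, 1, 1, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1),
    sorafenib   = c(0, 0, 1, 0, 0, 0, 1, 1, 0, 0, 0, 0, 1, 1, 0, 0),
    vemurafenib = c(0, 0, 0, 1, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0, 1, 1),
    is_control  = rep(c(TRUE, FALSE), c(4, 12)),
    control     = c(NA, NA, NA, NA,
                    "FRB+FKBP", "FRB+FKBP", "FRB+FKBP + S", "FRB+FKBP + S",
                    "FRB+FKBP + V", "FRB+FKBP + V",
                    "FRB+FKBP", "FRB+FKBP", "FRB+FKBP + S", "FRB+FKBP + S",
                    "FRB+FKBP + V", "FRB+FKBP + V"),
    stringsAsFactors = FALSE)
}

.sanitize_label <- function(x) {
  x <- gsub("A/C", "AC", x, fixed = TRUE)
  x <- gsub("[^A-Za-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

#' Generate the run-level sample design
#'
#' Expands the 16 conditions into one record per MS run, with `n_bio`
#' biological replicates each measured as `n_tech` technical replicates
#' (the study layout is 3 biological x 2 technical, 96 runs).
#'
#' @param n_bio Number of biological replicates per condition (>= 1).
#' @param n_tech Number of technical replicates per biological replicate
#'   (>= 1).
#' @return A `sample_design` data.frame with columns `run_id`, `condition`,
#'   the five one-hot factors, `bio_rep`, `tech_rep`, `is_control`,
#'   `control`. `(condition, bio_rep, tech_rep)` triples are unique.
#' @examples
#' d <- generate_design(3, 2)
#' nrow(d)  # 96
#' @export
generate_design <- function(n_bio = 3, n_tech = 2) {
  stopifnot(n_bio >= 1, n_tech >= 1)
  cond <- dimer_conditions()
  reps <- expand.grid(tech_rep = seq_len(n_tech), bio_rep = seq_len(n_bio),
                      cond_idx = seq_len(nrow(cond)))
  d <- cond[reps$cond_idx, , drop = FALSE]
  d$bio_rep <- reps$bio_rep
  d$tech_rep <- reps$tech_rep
  d$run_id <- sprintf("%s_b%d_t%d", .sanitize_label(d$condition),
                      d$bio_rep, d$tech_rep)
  rownames(d) <- NULL
  d <- d[, c("run_id", "condition", .DESIGN_VARS,
             "bio_rep", "tech_rep", "is_control", "control")]
  stopifnot(!anyDuplicated(d$run_id))
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Default condition-vs-control comparisons
#'
#' Each bait condition is compared against its drug-matched tag-only
#' control (Sorafenib conditions against the Sorafenib-treated control, and
#' so on).
#'
#' @param design A `sample_design` data.frame.
#' @return data.frame with columns `condition` and `control`.
#' @export
default_comparisons <- function(design) {
  cc <- unique(as.data.frame(design)[!design$is_control,
                                     c("condition", "control")])
  rownames(cc) <- NULL
  cc
}

#' Ground truth for a simulated AP-MS dataset
#'
#' @param protein_ids Character identifiers of the prey proteins.
#' @param baseline Per-protein baseline log2 intensity.
#' @param beta Per-protein coefficient matrix (proteins x 5) over the design
#'   variables, log2-intensity units; column names must equal
#'   `c("brafwt","v600e","dimerizer","sorafenib","vemurafenib")`.
#' @param sigma_bio Biological-replicate noise sd (log2 units, shared by the
#'   technical replicates of a biological replicate).
#' @param sigma_tech Technical noise sd (log2 units, per run).
#' @param censor_midpoint Latent log2 intensity at which the missingness
#'   probability is 0.5.
#' @param censor_slope Scale of the logistic missingness curve in log2
#'   units; smaller values give a steeper detection limit, 0 switches
#'   censoring off wherever the midpoint lies below the latent values.
#' @param n_contaminant,n_reverse,n_onlysite Counts of decoy rows carrying
#'   the respective category flag.
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(protein_ids, baseline, beta,
                         sigma_bio = 0.5, sigma_tech = 0.3,
                         censor_midpoint = 22, censor_slope = 1,
                         n_contaminant = 0, n_reverse = 0, n_onlysite = 0) {
  beta <- as.matrix(beta)
  stopifnot(length(protein_ids) == length(baseline),
            nrow(beta) == length(baseline),
            identical(colnames(beta), .DESIGN_VARS),
            sigma_bio >= 0, sigma_tech >= 0, censor_slope >= 0,
            n_contaminant >= 0, n_reverse >= 0, n_onlysite >= 0)
  structure(list(protein_ids = as.character(protein_ids),
                 baseline = as.numeric(baseline), beta = beta,
                 sigma_bio = sigma_bio, sigma_tech = sigma_tech,
                 censor_midpoint = censor_midpoint,
                 censor_slope = censor_slope,
                 n_contaminant = as.integer(n_contaminant),
                 n_reverse = as.integer(n_reverse),
                 n_onlysite = as.integer(n_onlysite)),
            class = "ground_truth")
}

#' Default ground truth emulating the study conditions
#'
#' 600 prey proteins with log-normal LFQ intensities (baseline log2 mean 25,
#' sd 2, the typical dynamic range of LFQ AP-MS pulldowns); about 15% of
#' proteins carry a nonzero interaction effect of 1-3 log2 units on one or
#' two design variables (positive with probability `prop_positive`, since
#' pulldown effects are mostly enrichments but drugs can deplete
#' interactors); replicate noise 0.5 (biological) and 0.3 (technical) log2
#' units; logistic left-censoring centred 3 sd below the baseline mean.
#'
#' @param n_proteins Number of prey proteins.
#' @param prop_active Proportion of proteins with at least one nonzero
#'   effect.
#' @param effect_range Magnitude range (log2 units) of nonzero effects.
#' @param prop_positive Probability that a nonzero effect is positive.
#' @param baseline_mean,baseline_sd Log2-scale location and spread of the
#'   baseline intensities.
#' @inheritParams ground_truth
#' @param seed Seed for drawing baselines and effects.
#' @return A `ground_truth` object.
#' @export
default_ground_truth <- function(n_proteins = 600, prop_active = 0.15,
                                 effect_range = c(1, 3), prop_positive = 0.7,
                                 baseline_mean = 25, baseline_sd = 2,
                                 sigma_bio = 0.5, sigma_tech = 0.3,
                                 censor_midpoint = 22, censor_slope = 1,
                                 n_contaminant = 10, n_reverse = 10,
                                 n_onlysite = 10, seed = 1) {
  stopifnot(n_proteins >= 1, prop_active >= 0, prop_active <= 1,
            length(effect_range) == 2, effect_range[1] <= effect_range[2])
  set.seed(seed)
  baseline <- stats::rnorm(n_proteins, baseline_mean, baseline_sd)
  beta <- matrix(0, n_proteins, length(.DESIGN_VARS),
                 dimnames = list(NULL, .DESIGN_VARS))
  n_active <- round(prop_active * n_proteins)
  if (n_active > 0) {
    active <- sample.int(n_proteins, n_active)
    for (i in active) {
      k <- sample(1:2, 1)
      vars <- sample.int(length(.DESIGN_VARS), k)
      mag <- stats::runif(k, effect_range[1], effect_range[2])
      sgn <- ifelse(stats::runif(k) < prop_positive, 1, -1)
      beta[i, vars] <- sgn * mag
    }
  }
  ground_truth(sprintf("P%05d", seq_len(n_proteins)), baseline, beta,
               sigma_bio = sigma_bio, sigma_tech = sigma_tech,
               censor_midpoint = censor_midpoint, censor_slope = censor_slope,
               n_contaminant = n_contaminant, n_reverse = n_reverse,
               n_onlysite = n_onlysite)
}

#' Simulate label-free quantification intensities with known ground truth
#'
#' Latent log2 intensity of a protein in a run is
#' `baseline + design %*% beta + bio + tech`, where `bio` is a biological
#' replicate random effect (sd `sigma_bio`) shared by the technical
#' replicates of the same biological replicate, and `tech` is independent
#' per-run noise (sd `sigma_tech`). Each cell is then independently censored
#' (missing not at random) with probability
#' `plogis((censor_midpoint - latent) / max(censor_slope, 1e-8))`; censored
#' cells carry raw intensity 0. Decoy rows (contaminant / reverse / only-by-
#' site) draw their baselines from the same distribution as the prey
#' proteins and exist solely to exercise the category filter.
#'
#' @param design A `sample_design` data.frame (see [generate_design()]).
#' @param truth A [ground_truth()] object.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A list of class `lfq_sim` with elements `intensity` (linear-scale
#'   matrix, rows = proteins + decoys, columns = runs, 0 where censored),
#'   `latent` (pre-censoring log2 matrix), `censored` (logical mask),
#'   `flags`, `protein_ids`, `annotations`, `design`, `truth`.
#' @export
simulate_lfq <- function(design, truth, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"),
            all(.DESIGN_VARS %in% names(design)))
  X <- as.matrix(as.data.frame(design)[, .DESIGN_VARS])
  if (ncol(X) != ncol(truth$beta))
    stop("dimension mismatch between design factors and truth$beta")
  set.seed(seed)
  n <- length(truth$protein_ids)
  r <- nrow(design)
  mu <- matrix(truth$baseline, n, r) + truth$beta %*% t(X)

  n_dec <- truth$n_contaminant + truth$n_reverse + truth$n_onlysite
  if (n_dec > 0) {
    bsd <- stats::sd(truth$baseline)
    if (!is.finite(bsd) || bsd == 0) bsd <- 1
    base_dec <- stats::rnorm(n_dec, mean(truth$baseline), bsd)
    mu <- rbind(mu, matrix(base_dec, n_dec, r))
  }
  N <- n + n_dec

  bio_key <- paste(design$condition, design$bio_rep)
  keys <- unique(bio_key)
  kidx <- match(bio_key, keys)
  bio <- matrix(stats::rnorm(N * length(keys), 0, truth$sigma_bio), N)
  tech <- matrix(stats::rnorm(N * r, 0, truth$sigma_tech), N, r)
  latent <- mu + bio[, kidx, drop = FALSE] + tech

  p_miss <- stats::plogis((truth$censor_midpoint - latent) /
                            max(truth$censor_slope, 1e-8))
  censored <- matrix(stats::runif(N * r), N, r) < p_miss
  intensity <- ifelse(censored, 0, 2^latent)
  colnames(intensity) <- colnames(latent) <- colnames(censored) <- design$run_id

  ids <- c(truth$protein_ids,
           sprintf("CON__C%04d", seq_len(truth$n_contaminant)),
           sprintf("REV__R%04d", seq_len(truth$n_reverse)),
           sprintf("S%05d", seq_len(truth$n_onlysite)))
  cnt <- c(n, truth$n_contaminant, truth$n_reverse, truth$n_onlysite)
  flags <- data.frame(only_site   = rep(c(0L, 0L, 0L, 1L), cnt),
                      reverse     = rep(c(0L, 0L, 1L, 0L), cnt),
                      contaminant = rep(c(0L, 1L, 0L, 0L), cnt))
  annotations <- data.frame(
    gene = c(sprintf("PREY%04d", seq_len(n)),
             if (n_dec > 0) sprintf("DECOY%04d", seq_len(n_dec))),
    unique_peptides = pmax(1L, stats::rpois(N, 8)),
    coverage = round(stats::runif(N, 5, 80), 1),
    mol_weight = round(stats::runif(N, 10, 300), 2),
    stringsAsFactors = FALSE)

  structure(list(intensity = intensity, latent = latent, censored = censored,
                 flags = flags, protein_ids = ids, annotations = annotations,
                 design = design, truth = truth),
            class = "lfq_sim")
}

#' Write a simulated dataset in the MaxQuant proteinGroups dialect
#'
#' Tab-separated UTF-8 table with one row per protein group: identifier and
#' annotation columns (`Protein IDs`, `Majority protein IDs`,
#' `Protein names`, `Gene names`, `Unique peptides`,
#' `Sequence coverage [\%]`, `Mol. weight [kDa]`), the three category flag
#' columns (`Only identified by site`, `Reverse`, `Contaminant`) using "+"
#' for flagged rows and empty strings otherwise, and one
#' `LFQ intensity <run_id>` column per run. Intensities are printed with 17
#' significant digits so a write/read round trip is numerically exact.
#'
#' @param sim An `lfq_sim` object from [simulate_lfq()].
#' @param path Output file path.
#' @param design Run design matching the intensity columns.
#' @return `path`, invisibly.
#' @export
write_proteingroups <- function(sim, path, design = sim$design) {
  stopifnot(inherits(sim, "lfq_sim"))
  V <- sim$intensity
  if (!identical(colnames(V), design$run_id))
    stop("design runs do not match the intensity columns")
  flag_chr <- function(f) ifelse(f > 0, "+", "")
  ann <- sim$annotations
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    `Protein IDs` = sim$protein_ids,
    `Majority protein IDs` = sim$protein_ids,
    `Protein names` = paste("Synthetic protein", ann$gene),
    `Gene names` = ann$gene,
    `Unique peptides` = ann$unique_peptides,
    `Sequence coverage [%]` = ann$coverage,
    `Mol. weight [kDa]` = ann$mol_weight,
    `Only identified by site` = flag_chr(sim$flags$only_site),
    `Reverse` = flag_chr(sim$flags$reverse),
    `Contaminant` = flag_chr(sim$flags$contaminant))
  lfq <- as.data.frame(matrix(sprintf("%.17g", V), nrow(V)),
                       stringsAsFactors = FALSE)
  names(lfq) <- paste("LFQ intensity", colnames(V))
  .write_tsv(cbind(out, lfq), path)
}

#' @rdname write_proteingroups
#' @export
write_sample_design <- function(design, path) {
  .write_tsv(as.data.frame(design), path)
}

#' Read a sample-design table written by [write_sample_design()]
#' @param path Tab-separated design file with at least `run_id` and
#'   `condition` columns.
#' @return A `sample_design` data.frame.
#' @export
read_sample_design <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("run_id", "condition")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("design schema error: missing column(s) ", paste(miss, collapse = ", "))
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Write / read the ground-truth sidecar (JSON) for test harnesses
#' @param truth A `ground_truth` object.
#' @param path JSON file path.
#' @return `path` (writer) or a `ground_truth` object (reader).
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  obj <- unclass(truth)
  obj$beta <- as.data.frame(obj$beta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::fromJSON(path)
  beta <- as.matrix(obj$beta[, .DESIGN_VARS])
  rownames(beta) <- NULL
  ground_truth(obj$protein_ids, obj$baseline, beta,
               sigma_bio = obj$sigma_bio, sigma_tech = obj$sigma_tech,
               censor_midpoint = obj$censor_midpoint,
               censor_slope = obj$censor_slope,
               n_contaminant = obj$n_contaminant,
               n_reverse = obj$n_reverse, n_onlysite = obj$n_onlysite)
}
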