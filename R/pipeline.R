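#' Default pipeline configuration
#'
#' One structured list with a simulation block (swap it for an `input` block
#' with `proteingroups` and `design` paths to analyse real tables), the
#' analysis parameters (see [analysis_params()]), stage toggles, the
#' contrast list and the output directory. Every entry has a config-file
#' twin; [read_pipeline_config()] merges a YAML file over these defaults.
#'
#' @return Nested list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    simulation = list(n_proteins = 600, prop_active = 0.15,
                      effect_range = c(1, 3), n_bio = 3, n_tech = 2,
                      n_contaminant = 10, n_reverse = 10, n_onlysite = 10),
    input = NULL,
    params = list(width = 0.3, downshift = 1.8, s0 = 0.1, target_fdr = 0.1,
                  n_randomisations = 250, fold_change = 1.5, alpha = 0.05,
                  min_valid = 3, max_missing_per_condition = 2, seed = 1),
    stages = list(collapse_technical = FALSE,
                  imputation = "lognormal",
                  differential = "both"),
    comparisons = NULL,
    contrasts = c("v600e-brafwt", "sorafenib-vemurafenib", "dimerizer"),
    reference = NULL,
    output_dir = "dimerscope_out")
}

#' Read a pipeline configuration file
#'
#' YAML file mirroring [default_pipeline_config()]; supplied keys override
#' the defaults, everything else keeps its default. Supplying an `input`
#' block disables the simulation block (supplying both is an error).
#'
#' @param path YAML config file.
#' @return Normalized config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  .normalize_config(yaml::read_yaml(path))
}

.normalize_config <- function(user) {
  stopifnot(is.list(user))
  def <- default_pipeline_config()
  if (!is.null(user$input)) {
    if (!is.null(user$simulation))
      stop("config error: exactly one of 'input' and 'simulation' may be given")
    def$simulation <- NULL
  }
  cfg <- utils::modifyList(def, user, keep.null = TRUE)
  cfg
}

.stage_error <- function(stage, code, msg) {
  stop(structure(class = c("dimerscope_stage_error", "error", "condition"),
                 list(message = sprintf("[%s] %s: %s", stage, code, msg),
                      call = NULL, stage = stage, code = code)))
}

# Validate before any computation: config shape, stage names, and that every
# comparison / contrast refers to something that exists.
.validate_config <- function(cfg) {
  if (is.null(cfg$input) == is.null(cfg$simulation))
    .stage_error("config", "E_INPUT",
                 "exactly one of 'input' and 'simulation' must be present")
  if (!cfg$stages$imputation %in% c("lognormal", "downshift"))
    .stage_error("config", "E_STAGE",
                 "stages$imputation must be 'lognormal' or 'downshift'")
  if (!cfg$stages$differential %in% c("bh", "perm", "both"))
    .stage_error("config", "E_STAGE",
                 "stages$differential must be 'bh', 'perm' or 'both'")
  known <- if (!is.null(cfg$simulation)) dimer_conditions()$condition
           else unique(read_sample_design(cfg$input$design)$condition)
  comps <- cfg$comparisons
  if (!is.null(comps)) {
    comps <- .parse_comparisons(comps)
    bad <- setdiff(unique(c(comps$condition, comps$control)), known)
    if (length(bad))
      .stage_error("config", "E_CONDITION",
                   paste("unknown condition(s) in comparisons:",
                         paste(bad, collapse = ", ")))
  }
  for (ct in cfg$contrasts) {
    if (is.character(ct) && !ct %in% names(contrast_presets()))
      .stage_error("config", "E_CONTRAST", paste("unknown contrast preset:", ct))
    if (is.numeric(ct) && length(ct) != 6)
      .stage_error("config", "E_CONTRAST", "numeric contrasts need 6 entries")
  }
  invisible(cfg)
}

.parse_comparisons <- function(comps) {
  if (is.data.frame(comps)) return(comps[, c("condition", "control")])
  parts <- strsplit(as.character(comps), ":", fixed = TRUE)
  if (any(lengths(parts) != 2))
    .stage_error("config", "E_COMPARISON",
                 "comparisons must be 'condition:control' strings")
  data.frame(condition = vapply(parts, `[`, "", 1),
             control = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) a proteinGroups table, apply the category and
#' valid-value filters, impute, call differential interactors (BH branch on
#' the log-normal-imputed matrix, permutation-FDR branch on the
#' downshift-imputed matrix, or both), fit the one-hot regression with
#' contrasts, run the PCA/outlier QC and the interactor overlap matrix, and
#' write every result table plus a run manifest to the output directory.
#' Identical config and seed give byte-identical result tables.
#'
#' @param config Config list (see [default_pipeline_config()]) or the path
#'   of a YAML config file.
#' @param output_dir Optional override of the config's output directory.
#' @return Invisibly, a list with the intermediate objects and result
#'   tables (`design`, `truth`, `matrix_main`, `differential_bh`,
#'   `perm_results`, `fit`, `contrasts`, `pca`, `outliers`, `overlap`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else .normalize_config(config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  .validate_config(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- do.call(analysis_params, cfg$params)
  counts <- list()
  out_file <- function(name) file.path(cfg$output_dir, name)

  ## --- input -------------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$simulation)) {
    s <- cfg$simulation
    design <- generate_design(s$n_bio %||% 3, s$n_tech %||% 2)
    truth <- default_ground_truth(
      n_proteins = s$n_proteins %||% 600,
      prop_active = s$prop_active %||% 0.15,
      effect_range = s$effect_range %||% c(1, 3),
      n_contaminant = s$n_contaminant %||% 10,
      n_reverse = s$n_reverse %||% 10,
      n_onlysite = s$n_onlysite %||% 10,
      seed = .derive_seed(p$seed, "truth"))
    sim <- simulate_lfq(design, truth, seed = .derive_seed(p$seed, "lfq"))
    write_proteingroups(sim, out_file("proteingroups.txt"))
    write_sample_design(design, out_file("sample_design.tsv"))
    write_ground_truth(truth, out_file("ground_truth.json"))
    pg <- read_proteingroups(out_file("proteingroups.txt"))
  } else {
    pg <- tryCatch(read_proteingroups(cfg$input$proteingroups),
                   error = function(e) .stage_error("input", "E_READ",
                                                    conditionMessage(e)))
    design <- read_sample_design(cfg$input$design)
  }
  counts$protein_groups <- length(pg$ids)

  ## --- filtering ---------------------------------------------------------
  pg <- filter_categories(pg)
  counts$after_category_filter <- length(pg$ids)
  im <- log2_transform(pg, design)
  im <- filter_min_valid(im, min_valid = p$min_valid)
  counts$after_min_valid <- nrow(im$values)
  if (isTRUE(cfg$stages$collapse_technical)) {
    im <- collapse_technical_replicates(im)
    design <- im$design
  }
  counts$missing_cells <- sum(im$missing_mask)

  comparisons <- if (!is.null(cfg$comparisons)) .parse_comparisons(cfg$comparisons)
                 else default_comparisons(design)

  ## --- imputation (two branches, mirroring the two parallel analyses) ----
  main_method <- cfg$stages$imputation
  if (main_method == "lognormal") {
    im_main <- filter_max_missing(im, max_missing = p$max_missing_per_condition)
    counts$after_max_missing <- nrow(im_main$values)
    im_main <- impute_lognormal(im_main, seed = p$seed)
  } else {
    im_main <- impute_downshift(im, p$width, p$downshift, seed = p$seed)
  }
  counts$cells_imputed_main <- sum(im_main$imputed_mask)
  .write_matrix_tsv(im_main$values, out_file("imputed_matrix.tsv"))
  .write_matrix_tsv(im_main$imputed_mask * 1L, out_file("imputed_mask.tsv"))

  ## --- differential ------------------------------------------------------
  method <- cfg$stages$differential
  diff_bh <- NULL
  if (method %in% c("bh", "both")) {
    tabs <- lapply(seq_len(nrow(comparisons)), function(i)
      right_tailed_ttest(im_main, comparisons$condition[i],
                         comparisons$control[i]))
    diff_bh <- call_differential(do.call(rbind, tabs),
                                 fold_change = p$fold_change, alpha = p$alpha)
    .write_tsv(diff_bh, out_file("differential_bh.tsv"))
    counts$bh_significant <- sum(diff_bh$significant_bh, na.rm = TRUE)
  }
  perm_results <- NULL
  if (method %in% c("perm", "both")) {
    im_perm <- impute_downshift(im, p$width, p$downshift, seed = p$seed)
    perm_results <- lapply(seq_len(nrow(comparisons)), function(i)
      permutation_fdr(im_perm, comparisons$condition[i],
                      comparisons$control[i], s0 = p$s0,
                      target_fdr = p$target_fdr,
                      n_randomisations = p$n_randomisations, seed = p$seed))
    names(perm_results) <- comparisons$condition
    perm_tab <- do.call(rbind, lapply(perm_results, `[[`, "table"))
    rownames(perm_tab) <- NULL
    .write_tsv(perm_tab, out_file("differential_perm.tsv"))
    curves <- do.call(rbind, lapply(names(perm_results), function(nm) {
      cv <- perm_results[[nm]]$curve
      if (is.null(cv)) return(NULL)
      cbind(comparison = nm, cv)
    }))
    if (!is.null(curves)) .write_tsv(curves, out_file("volcano_curves.tsv"))
    .write_tsv(data.frame(
      condition = comparisons$condition, control = comparisons$control,
      threshold = vapply(perm_results, `[[`, 0, "threshold"),
      n_significant = vapply(perm_results,
                             function(r) length(r$significant), 0L)),
      out_file("perm_thresholds.tsv"))
    counts$perm_significant <- sum(vapply(perm_results,
                                          function(r) length(r$significant), 0L))
  }

  ## --- regression --------------------------------------------------------
  fit <- fit_ols(im_main)
  coef_tab <- coefficient_tests(fit)
  .write_matrix_tsv(fit$coefficients, out_file("coefficients.tsv"))
  .write_tsv(coef_tab, out_file("coefficient_tests.tsv"))
  ctr_tab <- do.call(rbind, lapply(cfg$contrasts, function(ct) contrast(fit, ct)))
  .write_tsv(ctr_tab, out_file("contrasts.tsv"))
  pred <- predict_logLFQ(fit)
  .write_tsv(pred$table, out_file("measured_vs_predicted.tsv"))

  ## --- QC and overlap -----------------------------------------------------
  pca <- run_pca(im_main)
  .write_matrix_tsv(round(pca$scores, 8), out_file("pca_scores.tsv"),
                    id_col = "run_id")
  .write_tsv(data.frame(component = seq_along(pca$explained_variance),
                        explained_variance = pca$explained_variance),
             out_file("pca_variance.tsv"))
  outliers <- flag_outliers(pca, k_sd = 4)
  .write_tsv(outliers, out_file("pca_outliers.tsv"))

  sets <- if (!is.null(diff_bh)) attr(diff_bh, "interactors")
          else lapply(perm_results, `[[`, "significant")
  names(sets) <- sub(" vs .*$", "", names(sets))
  overlap <- overlap_matrix(sets)
  .write_matrix_tsv(format(overlap), out_file("overlap_matrix.tsv"),
                    id_col = "condition")
  .write_tsv(as.data.frame(overlap), out_file("overlap_long.tsv"))

  ref <- NULL
  if (!is.null(cfg$reference)) {
    ref <- compare_reference(unique(unlist(sets, use.names = FALSE)),
                             cfg$reference)
    .write_tsv(data.frame(shared = ref$shared),
               out_file("reference_overlap.tsv"))
    counts$reference_shared <- ref$n_shared
  }

  ## --- manifest ----------------------------------------------------------
  manifest <- list(package = "dimerscope",
                   version = as.character(utils::packageVersion("dimerscope")),
                   params = unclass(p), stages = cfg$stages,
                   comparisons = comparisons, counts = counts,
                   files = sort(list.files(cfg$output_dir)))
  jsonlite::write_json(manifest, out_file("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(config = cfg, design = design, truth = truth,
                 matrix_main = im_main, differential_bh = diff_bh,
                 perm_results = perm_results, fit = fit,
                 contrasts = ctr_tab, pca = pca, outliers = outliers,
                 overlap = overlap, reference = ref, manifest = manifest))
}
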