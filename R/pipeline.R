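# End-to-end orchestration: simulate -> preprocess -> fit -> downstream
# stages as one reproducible run with a hash-chained manifest.

default_run_config <- function() {
  list(
    cohort = list(),          # overrides passed to cohort_config()
    recipe = "synthetic",     # synthetic | munich | groningen
    factors = 10,
    enrich = list(direction = "all", min_coverage = 0.2),
    communication = list(top_fraction = 0.05, sign = "positive",
                         potential_quantile = 0.97, min_abs_rho = 0.4, lag = 0),
    predict = list(factor = NULL, timepoint = "TP1", rule = "munich"),
    seed = 1L
  )
}

recipe_criteria <- function(recipe) {
  switch(recipe,
         synthetic = filter_criteria(c(20, 50)),
         munich = munich_gene_criteria(),
         groningen = groningen_gene_criteria(),
         abort(sprintf("unknown recipe '%s'", recipe)))
}

#' Validate a pipeline run configuration
#'
#' Configurations are nested lists (or a YAML file path) mirroring the stage
#' parameters; unknown keys are rejected so typos cannot silently fall back
#' to defaults.
#'
#' @param config Nested list or path to a YAML file.
#' @return The merged, validated configuration.
#' @export
validate_run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_run_config()
  check_keys <- function(given, known, where) {
    unknown <- setdiff(names(given), known)
    if (length(unknown)) {
      abort(sprintf("unknown config key%s in %s: %s",
                    if (length(unknown) > 1) "s" else "", where,
                    paste(unknown, collapse = ", ")))
    }
  }
  check_keys(config, names(defaults), "top level")
  for (sec in c("enrich", "communication", "predict")) {
    if (!is.null(config[[sec]])) check_keys(config[[sec]], names(defaults[[sec]]), sec)
  }
  if (!is.null(config$cohort)) {
    check_keys(config$cohort, names(formals(cohort_config)), "cohort")
  }
  cfg <- modifyList(defaults, config)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

hash_file <- function(path) unname(tools::md5sum(path))

#' Run the full pipeline
#'
#' Simulates a cohort (or reads one from `cohort_dir`), harmonizes it, fits
#' the factor model, and runs the downstream stages: variance decomposition,
#' feature ranking, trajectory summary, communication scoring and outcome
#' prediction. Every artifact is written under `out_dir` together with a
#' manifest recording the configuration and the MD5 hash of each output, so
#' a rerun with the same configuration reproduces the run bit-identically.
#'
#' @param config Run configuration (list or YAML path); see
#'   [validate_run_config()].
#' @param out_dir Output directory.
#' @param cohort_dir Optional directory with an existing cohort (as written
#'   by [write_cohort()]); when `NULL` a cohort is simulated from
#'   `config$cohort` and `config$seed`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir, cohort_dir = NULL) {
  cfg <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  add <- function(x) artifacts <<- c(artifacts, x)

  if (is.null(cohort_dir)) {
    gen_cfg <- do.call(cohort_config, modifyList(list(seed = cfg$seed), cfg$cohort))
    sim <- generate_cohort(gen_cfg)
    cohort <- sim$cohort
    truth <- sim$truth
    cohort_dir <- file.path(out_dir, "cohort")
    write_cohort(cohort, cohort_dir)
    add(list.files(cohort_dir, recursive = TRUE, full.names = TRUE))
  } else {
    cohort <- read_cohort(cohort_dir)
    truth <- NULL
  }

  dataset <- preprocess_cohort(cohort, gene_criteria = recipe_criteria(cfg$recipe),
                               seed = cfg$seed)
  fit <- fit_gfa(dataset, K = cfg$factors)
  model_dir <- file.path(out_dir, "model")
  serialize_model(fit, model_dir)
  add(list.files(model_dir, recursive = TRUE, full.names = TRUE))

  vd <- variance_explained(fit, dataset)
  readr::write_tsv(vd$by_factor, file.path(out_dir, "variance_by_factor.tsv"),
                   progress = FALSE)
  readr::write_tsv(vd$totals, file.path(out_dir, "variance_totals.tsv"),
                   progress = FALSE)
  add(file.path(out_dir, c("variance_by_factor.tsv", "variance_totals.tsv")))

  lead <- vd$by_factor |>
    dplyr::group_by(.data$factor) |>
    dplyr::summarise(r2 = sum(pmax(.data$r2, 0)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$r2))
  top <- rank_features(fit, lead$factor[1], fraction = 0.01)
  readr::write_tsv(top, file.path(out_dir, "top_features.tsv"), progress = FALSE)
  add(file.path(out_dir, "top_features.tsv"))

  traj <- summarize_trajectory(fit$Z, dataset$meta, lead$factor[1])
  readr::write_tsv(traj, file.path(out_dir, "trajectory.tsv"), progress = FALSE)
  add(file.path(out_dir, "trajectory.tsv"))

  if (!is.null(cohort$network)) {
    cc <- cfg$communication
    targets <- select_targets(fit, lead$factor[1], top_fraction = cc$top_fraction,
                              sign = cc$sign)
    cand <- candidate_pairs(cohort$network, targets,
                            potential_quantile = cc$potential_quantile)
    rel <- reliable_receptors(dataset$prevalence,
                              unique(cohort$network$lr_edges$receptor))
    pairs <- correlate_pairs(dataset, cand, rel, cohort$network,
                             min_abs_rho = cc$min_abs_rho, lag = cc$lag)
    readr::write_tsv(pairs, file.path(out_dir, "communication.tsv"), progress = FALSE)
    add(file.path(out_dir, "communication.tsv"))
  }

  rule <- switch(cfg$predict$rule, munich = munich_rule(),
                 groningen = groningen_rule(), abort("unknown outcome rule"))
  meta_lab <- label_outcome(dataset$meta, rule)
  tp1 <- meta_lab$timepoint == cfg$predict$timepoint & meta_lab$outcome != "unknown"
  pred <- NULL
  if (sum(tp1) >= 4 && dplyr::n_distinct(meta_lab$outcome[tp1]) == 2) {
    pf <- cfg$predict$factor %||% lead$factor[1]
    scores <- minmax_scale(fit$Z[meta_lab$sample_id[tp1], pf])
    roc <- roc_auc(scores, meta_lab$outcome[tp1], positive = "poor")
    pred <- tibble::tibble(factor = pf, timepoint = cfg$predict$timepoint,
                           auc = max(roc$auc, 1 - roc$auc))
    readr::write_tsv(pred, file.path(out_dir, "prediction.tsv"), progress = FALSE)
    add(file.path(out_dir, "prediction.tsv"))
  }

  artifacts <- unlist(artifacts)
  manifest <- list(
    config = cfg,
    artifacts = lapply(setNames(artifacts, sub(paste0("^", out_dir, "/?"), "", artifacts)),
                       hash_file),
    n_samples = nrow(dataset$meta),
    converged = fit$converged
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Verify a run manifest
#'
#' Recomputes the MD5 hash of every artifact listed in a run's manifest and
#' compares.
#'
#' @param out_dir Run directory containing `manifest.json`.
#' @return TRUE when all hashes match; otherwise an error naming the first
#'   mismatch.
#' @export
verify_manifest <- function(out_dir) {
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  for (rel in names(manifest$artifacts)) {
    h <- hash_file(file.path(out_dir, rel))
    if (!identical(h, manifest$artifacts[[rel]])) {
      abort(sprintf("artifact hash mismatch: %s", rel))
    }
  }
  TRUE
}
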