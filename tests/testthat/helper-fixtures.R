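# Shared fixtures, built in code. Heavy objects are cached for the session.

tiny_config <- function(seed = 1, ...) {
  args <- modifyList(
    list(n_patients_per_group = 3, n_clusters = 2, genes_per_cluster = 8,
         n_receptor_genes = 3, cells_per_sample = 40, n_cytokines = 8,
         n_proteins = 10, n_neutrophil_genes = 12, seed = seed),
    list(...))
  do.call(cohort_config, args)
}

# a small hand-made cell matrix: 2 samples x 2 clusters x 4 genes
toy_cells <- function() {
  counts <- rbind(
    c(2, 0, 1, 0), c(4, 0, 3, 0),                 # s1 / cA
    c(0, 5, 0, 1), c(0, 3, 0, 0), c(0, 4, 2, 0),  # s1 / cB
    c(1, 0, 0, 0), c(3, 0, 1, 0),                 # s2 / cA
    c(0, 2, 0, 2)                                 # s2 / cB
  )
  colnames(counts) <- c("g1", "g2", "g3", "g4")
  meta <- tibble::tibble(
    cell_id = sprintf("cell%02d", 1:8),
    sample_id = c("s1", "s1", "s1", "s1", "s1", "s2", "s2", "s2"),
    cluster = c("cA", "cA", "cB", "cB", "cB", "cA", "cA", "cB"))
  rownames(counts) <- meta$cell_id
  cell_matrix(counts, meta)
}

make_view <- function(values, name = "v", oor = NULL, mask = NULL) {
  if (is.null(rownames(values))) rownames(values) <- sprintf("s%d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("%s::f%d", name, seq_len(ncol(values)))
  view_matrix(values, name, oor = oor, mask = mask)
}

toy_meta <- function(sample_ids) {
  tibble::tibble(sample_id = sample_ids,
                 patient_id = sample_ids,
                 timepoint = "TP0", group = "CCS", delta_EF = NA_real_)
}

# a small fitted model on a deterministic synthetic dataset, cached
cached_small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- generate_cohort(tiny_config(seed = 7))
      ds <- preprocess_cohort(sim$cohort)
      cache <<- list(sim = sim, dataset = ds, fit = fit_gfa(ds, K = 4))
    }
    cache
  }
})

# the default study-scale cohort, cached for the acceptance checks
cached_default_sim <- local({
  cache <- NULL
  function(seed = 1) {
    if (is.null(cache) || cache$seed != seed) {
      sim <- generate_cohort(cohort_config(seed = seed))
      ds <- preprocess_cohort(sim$cohort)
      cache <<- list(seed = seed, sim = sim, dataset = ds)
    }
    cache
  }
})

# match the fitted factor that best tracks a true factor's scores
match_factor <- function(fit, truth, which = c("trajectory", "outcome")) {
  which <- match.arg(which)
  k_true <- if (which == "trajectory") truth$trajectory_factor else truth$outcome_factor
  # collapsed (ARD-pruned) factors have ~constant scores; their correlation
  # is undefined and irrelevant
  cc <- suppressWarnings(cor(fit$Z, truth$Z_true[rownames(fit$Z), k_true]))
  cc[is.na(cc)] <- 0
  list(index = which.max(abs(cc)), cor = cc[which.max(abs(cc))])
}

# per-seed study-scale cohorts with a fitted model, cached for reuse across
# the recovery, enrichment, communication and robustness checks
cached_seed_fit <- local({
  cache <- list()
  function(seed, K = 10) {
    key <- sprintf("%d_%d", seed, K)
    if (is.null(cache[[key]])) {
      sim <- generate_cohort(cohort_config(seed = seed))
      ds <- preprocess_cohort(sim$cohort)
      cache[[key]] <<- list(sim = sim, dataset = ds, fit = fit_gfa(ds, K = K))
    }
    cache[[key]]
  }
})

# 12-vs-12 outcome cohort used by the prediction checks
outcome_config <- function(seed, ...) {
  args <- modifyList(
    list(n_patients_per_group = c(sterile_ACS = 24, CCS = 8, non_CCS = 8),
         seed = seed),
    list(...))
  do.call(cohort_config, args)
}

# AUC of the fitted factor matched to the true outcome factor, at TP1.
# Orientation is fixed by the sign of the factor match (poor outcome is
# planted low on the truth-aligned axis), so a null cohort stays at 0.5.
outcome_factor_auc <- function(sim, ds, fit) {
  meta <- label_outcome(ds$meta, munich_rule())
  mt <- match_factor(fit, sim$truth, "outcome")
  tp1 <- meta$timepoint == "TP1" & meta$outcome != "unknown"
  aligned <- -sign(mt$cor) * fit$Z[meta$sample_id[tp1], mt$index]
  roc_auc(minmax_scale(aligned), meta$outcome[tp1], positive = "poor")$auc
}
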