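# Synthetic longitudinal multiomic cohort with known latent structure.
#
# The generator emulates the design of a longitudinal acute-coronary-syndrome
# (ACS) immune-profiling study: ACS patients sampled at four in-hospital
# timepoints (TP1..TP4), chronic (CCS) and ruled-out (non_CCS) controls at a
# single timepoint (TP0); data views are per-cluster single-cell pseudobulk
# expression, a multiplex cytokine panel with out-of-range (OOR) readings,
# plasma proteomics with left-censored missingness, a bulk neutrophil
# transcriptome, and clinical markers. All views share a linear latent-factor
# structure: one factor follows a rise-then-decay ischemia trajectory over
# TP1..TP4, one factor is shifted at TP1 in patients with poor outcome.

#' Generator configuration
#'
#' Validated configuration for [generate_cohort()]. Defaults encode the
#' study conditions the package is tested under: 8 patients per group,
#' 4 true factors, 6 factor views at a per-feature signal-to-noise ratio of 2
#' (unit signal scale, `noise_sd = 0.5`).
#'
#' @param n_patients_per_group Patients per group, a single count or a named
#'   vector over `sterile_ACS`, `CCS`, `non_CCS`.
#' @param timepoints_acs Ordered timepoint labels for ACS patients.
#' @param timepoint_control Timepoint label for control groups.
#' @param n_factors_true Number of true latent factors.
#' @param n_clusters Number of cell-type clusters (each yields one pseudobulk
#'   view).
#' @param genes_per_cluster Size of each cluster's informative gene panel.
#' @param n_receptor_genes Shared receptor genes expressed in every cluster.
#' @param cells_per_sample Cells drawn per sample.
#' @param n_cytokines,n_proteins,n_neutrophil_genes,n_clinical Feature counts
#'   of the bulk views.
#' @param noise_sd View noise standard deviation (signal scale is 1, so
#'   SNR = 1 / noise_sd).
#' @param trajectory_factor_index Index of the factor carrying the
#'   rise-then-decay ACS trajectory.
#' @param outcome_factor_index Index of the factor shifted at TP1 for
#'   poor-outcome patients.
#' @param outcome_effect Size of that TP1 shift in factor-score SD units
#'   (subtracted for poor outcome).
#' @param missing_view_rate Fraction of samples absent per view.
#' @param oor_rate Fraction of cytokine readings flagged OOR (the lowest
#'   values per cytokine, as below-range readings are in multiplex assays).
#' @param protein_missing_rate Mean proteomics missingness; dropout
#'   probability decreases logistically in the value's within-protein z-score
#'   (left censoring).
#' @param n_planted_pairs Number of planted ligand-target communication pairs.
#' @param nb_dispersion Negative-binomial dispersion of all count data.
#' @param library_size_sd SD of the per-cell log-normal library-size factor.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients_per_group = 8,
                          timepoints_acs = c("TP1", "TP2", "TP3", "TP4"),
                          timepoint_control = "TP0",
                          n_factors_true = 4,
                          n_clusters = 3,
                          genes_per_cluster = 50,
                          n_receptor_genes = 8,
                          cells_per_sample = 300,
                          n_cytokines = 40,
                          n_proteins = 60,
                          n_neutrophil_genes = 80,
                          n_clinical = 4,
                          noise_sd = 0.5,
                          trajectory_factor_index = 1,
                          outcome_factor_index = 2,
                          outcome_effect = 1.5,
                          missing_view_rate = 0.1,
                          oor_rate = 0.05,
                          protein_missing_rate = 0.15,
                          n_planted_pairs = 3,
                          nb_dispersion = 0.1,
                          library_size_sd = 0.3,
                          seed = 1L) {
  groups <- c("sterile_ACS", "CCS", "non_CCS")
  if (length(n_patients_per_group) == 1) {
    n_patients_per_group <- setNames(rep(n_patients_per_group, 3), groups)
  }
  if (!all(groups %in% names(n_patients_per_group))) {
    abort("n_patients_per_group must cover sterile_ACS, CCS, non_CCS")
  }
  for (g in groups) assert_count(n_patients_per_group[[g]], g)
  cfg <- list(
    n_patients_per_group = n_patients_per_group[groups],
    timepoints_acs = timepoints_acs, timepoint_control = timepoint_control,
    n_factors_true = assert_count(n_factors_true, "n_factors_true"),
    n_clusters = assert_count(n_clusters, "n_clusters"),
    genes_per_cluster = assert_count(genes_per_cluster, "genes_per_cluster"),
    n_receptor_genes = assert_count(n_receptor_genes, "n_receptor_genes", min = 0),
    cells_per_sample = assert_count(cells_per_sample, "cells_per_sample"),
    n_cytokines = assert_count(n_cytokines, "n_cytokines"),
    n_proteins = assert_count(n_proteins, "n_proteins"),
    n_neutrophil_genes = assert_count(n_neutrophil_genes, "n_neutrophil_genes"),
    n_clinical = assert_count(n_clinical, "n_clinical"),
    noise_sd = noise_sd,
    trajectory_factor_index = assert_count(trajectory_factor_index, "trajectory_factor_index"),
    outcome_factor_index = assert_count(outcome_factor_index, "outcome_factor_index"),
    outcome_effect = as.numeric(outcome_effect),
    missing_view_rate = assert_fraction(missing_view_rate, "missing_view_rate"),
    oor_rate = assert_fraction(oor_rate, "oor_rate"),
    protein_missing_rate = assert_fraction(protein_missing_rate, "protein_missing_rate"),
    n_planted_pairs = assert_count(n_planted_pairs, "n_planted_pairs", min = 0),
    nb_dispersion = as.numeric(nb_dispersion),
    library_size_sd = as.numeric(library_size_sd),
    seed = as.integer(seed)
  )
  if (cfg$trajectory_factor_index > cfg$n_factors_true ||
      cfg$outcome_factor_index > cfg$n_factors_true) {
    abort("trajectory/outcome factor indices must not exceed n_factors_true")
  }
  if (any(cfg$noise_sd <= 0)) abort("noise_sd must be positive")
  structure(cfg, class = "cohort_config")
}

# rise-then-decay trajectory over the ACS timepoints, near zero for controls
trajectory_pattern <- function(timepoints_acs) {
  k <- length(timepoints_acs)
  base <- c(0.6, 1.6, 1.0, 0.25)
  setNames(if (k <= 4) base[seq_len(k)] else approx(seq_len(4), base, n = k)$y,
           timepoints_acs)
}

cohort_view_names <- function(config) {
  c(paste0("cluster", seq_len(config$n_clusters) - 1),
    "cytokines", "proteomics", "neutrophils")
}

# gene universe: disjoint informative panels per cluster + shared receptors
cohort_gene_panels <- function(config) {
  panels <- lapply(seq_len(config$n_clusters), function(k) {
    sprintf("G%d_%03d", k - 1, seq_len(config$genes_per_cluster))
  })
  names(panels) <- paste0("cluster", seq_len(config$n_clusters) - 1)
  receptors <- if (config$n_receptor_genes > 0) {
    sprintf("RCP%02d", seq_len(config$n_receptor_genes))
  } else character()
  list(panels = panels, receptors = receptors,
       all_genes = c(unlist(panels, use.names = FALSE), receptors))
}

# sparse-ish weight matrix: every feature has one primary factor among the
# view's active factors plus weak cross-loadings; rows unit norm so the
# per-feature signal variance is 1.
draw_weights <- function(n_features, active, K) {
  W <- matrix(0, n_features, K)
  act <- which(active)
  primary <- act[(seq_len(n_features) - 1) %% length(act) + 1]
  for (j in seq_len(n_features)) {
    W[j, act] <- rnorm(length(act), 0, 0.15)
    W[j, primary[j]] <- sample(c(-1, 1), 1) * rnorm(1, 1, 0.2)
  }
  W / sqrt(rowSums(W^2))
}

#' Generate a synthetic multiomic cohort
#'
#' Produces the full cohort (cell-level counts, raw view tables with their
#' characteristic artefacts, sample metadata, prior ligand-target network) and
#' the ground truth used for recovery testing (true factor scores and
#' weights, the view-by-factor activity mask, outcome labels, planted
#' ligand-target pairs). Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param share_weights_from Optional `ifa_truth` from another cohort: its
#'   true weight matrices, activity mask and gene universe are reused so the
#'   two cohorts share the same latent axes (the replication setting), while
#'   patients, factor scores, noise and artefacts are drawn fresh.
#' @return A list with elements `cohort` (class `ifa_cohort`: `cells`,
#'   `views`, `meta`, `network`) and `truth` (class `ifa_truth`).
#' @export
generate_cohort <- function(config, share_weights_from = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(derive_seed(config$seed, 0L), {
    truth <- generate_truth_(config)
  })
  if (!is.null(share_weights_from)) {
    stopifnot(inherits(share_weights_from, "ifa_truth"))
    truth$W_true <- share_weights_from$W_true
    truth$activity <- share_weights_from$activity
    truth$genes <- share_weights_from$genes
  }
  cells <- generate_single_cell_counts(config, truth)
  withr::with_seed(derive_seed(config$seed, 3L), {
    views <- generate_bulk_views_(config, truth)
  })
  network <- generate_prior_network(config, truth)
  truth$planted_pairs <- network$planted_pairs
  cohort <- structure(list(cells = cells, views = views, meta = truth$meta,
                           network = network, config = config),
                      class = "ifa_cohort")
  list(cohort = cohort, truth = truth)
}

# truth: metadata, outcome labels, Z_true, per-view W_true, activity mask
generate_truth_ <- function(config) {
  K <- config$n_factors_true
  npg <- config$n_patients_per_group
  meta <- dplyr::bind_rows(
    tidyr::expand_grid(patient_id = sprintf("ACS%02d", seq_len(npg[["sterile_ACS"]])),
                       timepoint = config$timepoints_acs) |>
      dplyr::mutate(group = "sterile_ACS"),
    tidyr::expand_grid(patient_id = sprintf("CCS%02d", seq_len(npg[["CCS"]])),
                       timepoint = config$timepoint_control) |>
      dplyr::mutate(group = "CCS"),
    tidyr::expand_grid(patient_id = sprintf("NCC%02d", seq_len(npg[["non_CCS"]])),
                       timepoint = config$timepoint_control) |>
      dplyr::mutate(group = "non_CCS")
  )
  meta$sample_id <- paste(meta$patient_id, meta$timepoint, sep = "_")
  tp_levels <- c(config$timepoint_control, config$timepoints_acs)
  meta$timepoint <- factor(meta$timepoint, levels = tp_levels, ordered = TRUE)
  meta <- meta[order(meta$patient_id, meta$timepoint), ]
  n <- nrow(meta)

  # outcome: balanced good/poor among ACS patients, encoded in delta_EF
  acs_patients <- unique(meta$patient_id[meta$group == "sterile_ACS"])
  n_poor <- floor(length(acs_patients) / 2)
  poor <- sample(acs_patients, n_poor)
  outcome_labels <- tibble::tibble(
    patient_id = acs_patients,
    outcome = ifelse(acs_patients %in% poor, "poor", "good"))
  meta$delta_EF <- NA_real_
  is_acs <- meta$group == "sterile_ACS"
  ef_mag <- runif(n, 2, 12)
  meta$delta_EF[is_acs] <- ifelse(meta$patient_id[is_acs] %in% poor,
                                  -ef_mag[is_acs], ef_mag[is_acs])
  # one delta_EF per patient
  meta <- meta |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(delta_EF = .data$delta_EF[1]) |>
    dplyr::ungroup()

  # factor scores
  Z <- matrix(rnorm(n * K), n, K, dimnames = list(meta$sample_id, NULL))
  tf <- config$trajectory_factor_index
  pat <- trajectory_pattern(config$timepoints_acs)
  z_traj <- ifelse(is_acs, pat[as.character(meta$timepoint)] + rnorm(n, 0, 0.25),
                   rnorm(n, 0, 0.15))
  Z[, tf] <- z_traj / sd(z_traj)
  of <- config$outcome_factor_index
  at_tp1 <- is_acs & meta$timepoint == config$timepoints_acs[1]
  is_poor <- meta$patient_id %in% poor
  Z[at_tp1 & is_poor, of] <- Z[at_tp1 & is_poor, of] - config$outcome_effect

  # view-by-factor activity: each factor is silent in two views, the pairs
  # distinct across factors. Planted active pairs then hold a clearly
  # non-trivial share of their view's variance, silent pairs are exactly
  # zero in truth, and no two factors share an activity pattern (identical
  # patterns would leave the factor pair rotationally unidentifiable)
  view_names <- cohort_view_names(config)
  M <- length(view_names)
  activity <- matrix(TRUE, M, K, dimnames = list(view_names, NULL))
  for (k in seq_len(K)) {
    activity[(k - 1) %% M + 1, k] <- FALSE
    activity[(k + 1) %% M + 1, k] <- FALSE
  }

  genes <- cohort_gene_panels(config)
  W <- list()
  for (ci in seq_len(config$n_clusters)) {
    vn <- view_names[ci]
    Wp <- draw_weights(config$genes_per_cluster, activity[vn, ], K)
    rownames(Wp) <- genes$panels[[vn]]
    # receptor genes carry no factor signal
    Wr <- matrix(0, length(genes$receptors), K, dimnames = list(genes$receptors, NULL))
    W[[vn]] <- rbind(Wp, Wr)
    rownames(W[[vn]]) <- make_feature_ids(vn, rownames(W[[vn]]))
  }
  for (vn in c("cytokines", "proteomics", "neutrophils")) {
    nf <- switch(vn, cytokines = config$n_cytokines,
                 proteomics = config$n_proteins,
                 neutrophils = config$n_neutrophil_genes)
    ids <- switch(vn,
                  cytokines = sprintf("CYT%02d", seq_len(nf)),
                  proteomics = sprintf("PRT%03d", seq_len(nf)),
                  neutrophils = sprintf("NEU%03d", seq_len(nf)))
    W[[vn]] <- draw_weights(nf, activity[vn, ], K)
    rownames(W[[vn]]) <- make_feature_ids(vn, ids)
  }

  structure(list(Z_true = Z, W_true = W, activity = activity,
                 outcome_labels = outcome_labels, meta = tibble::as_tibble(meta),
                 trajectory_factor = tf, outcome_factor = of,
                 genes = genes, config = config),
            class = "ifa_truth")
}

#' Generate cell-level counts from the cohort truth
#'
#' Per cell, the cluster label is drawn from sample-specific cluster
#' proportions (Dirichlet with a timepoint-dependent concentration for the
#' first cluster, whose abundance declines over the ACS time course); gene
#' counts are negative binomial with log-mean `baseline + W_true %*% z` for
#' the cell's cluster panel, baseline only for receptor genes, and a low
#' background for off-panel genes, everything multiplied by a per-cell
#' log-normal library-size factor. Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param truth The truth object from [generate_cohort()].
#' @return An `ifa_cells`.
#' @export
generate_single_cell_counts <- function(config, truth) {
  withr::with_seed(derive_seed(config$seed, 1L), {
    genes <- truth$genes
    G <- length(genes$all_genes)
    meta <- truth$meta
    clusters <- names(genes$panels)
    size <- 1 / config$nb_dispersion
    # baselines, fixed across samples
    panel_base <- lapply(genes$panels, function(p) rnorm(length(p), log(3), 0.4))
    receptor_base <- rnorm(length(genes$receptors), log(4), 0.2)
    background <- log(0.05)
    # timepoint effect on the first cluster's abundance
    tp_mult <- setNames(c(1, 1.5, 1.0, 0.7, 0.5)[seq_len(1 + length(config$timepoints_acs))],
                        c(config$timepoint_control, config$timepoints_acs))
    counts_list <- vector("list", nrow(meta))
    meta_list <- vector("list", nrow(meta))
    for (i in seq_len(nrow(meta))) {
      sid <- meta$sample_id[i]
      conc <- rep(10, config$n_clusters)
      conc[1] <- conc[1] * tp_mult[[as.character(meta$timepoint[i])]]
      gam <- rgamma(config$n_clusters, shape = conc, rate = 1)
      props <- gam / sum(gam)
      labels <- sample(clusters, config$cells_per_sample, replace = TRUE, prob = props)
      libf <- exp(rnorm(config$cells_per_sample, 0, config$library_size_sd))
      z <- truth$Z_true[sid, ]
      logmu <- matrix(background, config$cells_per_sample, G,
                      dimnames = list(NULL, genes$all_genes))
      if (length(genes$receptors)) {
        logmu[, genes$receptors] <- rep(receptor_base, each = config$cells_per_sample)
      }
      for (cl in clusters) {
        rows <- which(labels == cl)
        if (!length(rows)) next
        pw <- truth$W_true[[cl]][make_feature_ids(cl, genes$panels[[cl]]), , drop = FALSE]
        sig <- panel_base[[cl]] + drop(pw %*% z)
        logmu[rows, genes$panels[[cl]]] <- rep(sig, each = length(rows))
      }
      mu <- libf * exp(logmu)
      cnt <- matrix(rnbinom(length(mu), mu = mu, size = size), nrow(mu), ncol(mu))
      colnames(cnt) <- genes$all_genes
      rownames(cnt) <- sprintf("%s_c%04d", sid, seq_len(nrow(cnt)))
      counts_list[[i]] <- cnt
      meta_list[[i]] <- tibble::tibble(cell_id = rownames(cnt), sample_id = sid,
                                       cluster = labels)
    }
    counts <- do.call(rbind, counts_list)
    storage.mode(counts) <- "integer"
    out <- cell_matrix(counts, dplyr::bind_rows(meta_list))
    attr(out, "baselines") <- list(panel = panel_base, receptor = receptor_base,
                                   background = background)
    out
  })
}

# bulk views: cytokines (OOR sentinels), proteomics (left-censored missing),
# neutrophil counts, clinical markers; per-view missing-sample masks
generate_bulk_views_ <- function(config, truth) {
  meta <- truth$meta
  n <- nrow(meta)
  Z <- truth$Z_true
  noise <- function(d) matrix(rnorm(n * d, 0, config$noise_sd), n, d)
  miss_samples <- function() {
    k <- floor(config$missing_view_rate * n)
    if (k == 0) character() else sample(meta$sample_id, k)
  }
  views <- list()

  # cytokines: concentration scale; lowest oor_rate per analyte below range
  Wc <- truth$W_true$cytokines
  base_c <- rnorm(nrow(Wc), 3, 0.6)
  sig <- Z %*% t(Wc) + noise(nrow(Wc)) + rep(base_c, each = n)
  vals <- expm1(pmax(sig, 0))
  dimnames(vals) <- list(meta$sample_id, rownames(Wc))
  oor <- matrix(FALSE, n, ncol(vals), dimnames = dimnames(vals))
  if (config$oor_rate > 0) {
    for (j in seq_len(ncol(vals))) {
      low <- order(vals[, j])[seq_len(max(1, round(config$oor_rate * n)))]
      oor[low, j] <- TRUE
    }
  }
  vals[oor] <- NA_real_
  absent <- miss_samples()
  mask <- setNames(!(meta$sample_id %in% absent), meta$sample_id)
  vals[!mask, ] <- NA_real_
  oor[!mask, ] <- FALSE
  views$cytokines <- view_matrix(vals, "cytokines", oor = oor, mask = mask)

  # proteomics: log intensities, dropout probability logistic in the z-score
  Wp <- truth$W_true$proteomics
  base_p <- rnorm(nrow(Wp), 20, 2)
  vals <- Z %*% t(Wp) + noise(nrow(Wp)) + rep(base_p, each = n)
  dimnames(vals) <- list(meta$sample_id, rownames(Wp))
  if (config$protein_missing_rate > 0) {
    zsc <- scale(vals)
    pmiss <- pmin(1, 2 * config$protein_missing_rate * plogis(-2 * zsc))
    drop <- matrix(runif(length(vals)) < pmiss, n, ncol(vals))
    vals[drop] <- NA_real_
  }
  absent <- miss_samples()
  mask <- setNames(!(meta$sample_id %in% absent), meta$sample_id)
  vals[!mask, ] <- NA_real_
  views$proteomics <- view_matrix(vals, "proteomics", mask = mask)

  # neutrophils: negative-binomial counts with per-sample depth factor
  Wn <- truth$W_true$neutrophils
  base_n <- rnorm(nrow(Wn), 3, 0.4)
  depth <- exp(rnorm(n, 0, 0.2))
  mu <- depth * exp(Z %*% t(Wn) + rep(base_n, each = n))
  vals <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                 n, ncol(mu), dimnames = list(meta$sample_id, rownames(Wn)))
  absent <- miss_samples()
  mask <- setNames(!(meta$sample_id %in% absent), meta$sample_id)
  vals[!mask, ] <- NA_real_
  views$neutrophils <- view_matrix(vals, "neutrophils", mask = mask)

  # clinical markers: driven by the trajectory and outcome factors
  markers <- c("CK", "CKMB", "TNT", "CRP")[seq_len(min(4, config$n_clinical))]
  if (config$n_clinical > 4) {
    markers <- c(markers, sprintf("CLIN%02d", seq_len(config$n_clinical - 4)))
  }
  b_traj <- runif(length(markers), 0.6, 1.2)
  b_out <- runif(length(markers), 0.2, 0.6)
  base_cl <- runif(length(markers), 3, 5)
  sig <- outer(Z[, truth$trajectory_factor], b_traj) +
    outer(Z[, truth$outcome_factor], b_out) +
    matrix(rnorm(n * length(markers), 0, config$noise_sd), n) +
    rep(base_cl, each = n)
  vals <- expm1(pmax(sig, 0))
  dimnames(vals) <- list(meta$sample_id, make_feature_ids("clinical", markers))
  views$clinical <- view_matrix(vals, "clinical")

  views
}

#' Generate the prior ligand-target network
#'
#' Builds a ligand-receptor edge list and a ligand-by-target
#' regulatory-potential matrix. `n_planted_pairs` true communication pairs
#' (a cytokine ligand and a cluster-panel target gene sharing the trajectory
#' factor) receive potential scores above the 97% quantile of the matrix and
#' a receptor edge expressed reliably in the target's cluster; all other
#' entries are i.i.d. decoys. Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param truth The truth object from [generate_cohort()].
#' @return An object of class `ifa_network`: `lr_edges` (tibble
#'   `ligand`, `receptor`), `potential` (ligand x target matrix) and
#'   `planted_pairs` (tibble, also recorded in the truth object by
#'   [generate_cohort()]).
#' @export
generate_prior_network <- function(config, truth) {
  withr::with_seed(derive_seed(config$seed, 2L), {
    ligands <- feature_gene(rownames(truth$W_true$cytokines))
    targets <- truth$genes$all_genes
    receptors <- truth$genes$receptors
    potential <- matrix(rexp(length(ligands) * length(targets)),
                        length(ligands), length(targets),
                        dimnames = list(ligands, targets))
    # ligand-receptor edges: one or two receptors per ligand
    lr <- purrr::map_dfr(ligands, function(lg) {
      k <- sample(1:2, 1)
      tibble::tibble(ligand = lg,
                     receptor = sample(receptors, min(k, length(receptors))))
    })
    planted <- NULL
    if (config$n_planted_pairs > 0) {
      tf <- truth$trajectory_factor
      # ligands most loaded on the trajectory factor
      wl <- truth$W_true$cytokines[, tf]
      lig_rank <- order(-abs(wl))
      # clusters where the trajectory factor is active
      cl_ok <- rownames(truth$activity)[truth$activity[, tf]]
      cl_ok <- intersect(cl_ok, names(truth$genes$panels))
      picks <- purrr::map_dfr(seq_len(config$n_planted_pairs), function(i) {
        lg <- ligands[lig_rank[i]]
        cl <- cl_ok[(i - 1) %% length(cl_ok) + 1]
        wt <- truth$W_true[[cl]][make_feature_ids(cl, truth$genes$panels[[cl]]), tf]
        # pick the panel gene whose trajectory weight sign matches the ligand
        cand <- order(-(sign(wl[lig_rank[i]]) * wt))
        gene <- truth$genes$panels[[cl]][cand[(i - 1) %/% length(cl_ok) + 1]]
        tibble::tibble(ligand = lg, target = gene, target_cluster = cl,
                       ligand_feature = rownames(truth$W_true$cytokines)[lig_rank[i]],
                       target_feature = make_feature_ids(cl, gene))
      })
      hi <- quantile(potential, 0.999, names = FALSE) * 1.05
      for (i in seq_len(nrow(picks))) {
        potential[picks$ligand[i], picks$target[i]] <- hi
      }
      planted <- picks
    }
    structure(list(lr_edges = lr, potential = potential,
                   planted_pairs = planted),
              class = "ifa_network")
  })
}

#' @export
print.ifa_network <- function(x, ...) {
  cat(sprintf("<ifa_network> %d ligand-receptor edges, %d x %d potential matrix, %d planted pairs\n",
              nrow(x$lr_edges), nrow(x$potential), ncol(x$potential),
              if (is.null(x$planted_pairs)) 0L else nrow(x$planted_pairs)))
  invisible(x)
}

#' Write or read a cohort directory
#'
#' On-disk layout: `cells/` (MatrixMarket counts plus annotation TSVs), one
#' TSV per raw view (`view_<name>.tsv`, OOR sentinels written literally),
#' `meta.tsv`, and the prior network as `network_edges.tsv` /
#' `network_potential.tsv` (long format `ligand`, `target`, `score`).
#'
#' @param cohort An `ifa_cohort` from [generate_cohort()].
#' @param dir Target directory.
#' @return `dir` (write) or an `ifa_cohort` (read).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cell_matrix(cohort$cells, file.path(dir, "cells"))
  for (v in cohort$views) {
    write_view_table(v, file.path(dir, sprintf("view_%s.tsv", v$view_name)))
  }
  meta <- cohort$meta
  meta$timepoint <- as.character(meta$timepoint)
  readr::write_tsv(meta[, c("sample_id", "patient_id", "timepoint", "group", "delta_EF")],
                   file.path(dir, "meta.tsv"), progress = FALSE)
  write_network(cohort$network, dir)
  invisible(dir)
}

#' @rdname write_cohort
#' @param timepoint_levels Ordered timepoint labels used to parse `meta.tsv`.
#' @export
read_cohort <- function(dir, timepoint_levels = c("TP0", "TP1", "TP2", "TP3", "TP4")) {
  files <- list.files(dir, pattern = "^view_.*\\.tsv$")
  views <- lapply(files, function(f) {
    vn <- sub("^view_(.*)\\.tsv$", "\\1", f)
    read_view_table(file.path(dir, f), vn)
  })
  names(views) <- vapply(views, `[[`, character(1), "view_name")
  structure(list(cells = read_cell_matrix(file.path(dir, "cells")),
                 views = views,
                 meta = read_sample_meta(file.path(dir, "meta.tsv"), timepoint_levels),
                 network = read_network(dir)),
            class = "ifa_cohort")
}

#' Write / read a prior network as TSV
#'
#' @param network An `ifa_network`.
#' @param dir Directory for `network_edges.tsv` and `network_potential.tsv`.
#' @return `dir` (write) or an `ifa_network` (read; `planted_pairs` is not
#'   part of the on-disk interchange format and comes back `NULL`).
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(network$lr_edges, file.path(dir, "network_edges.tsv"),
                   progress = FALSE)
  long <- tibble::tibble(
    ligand = rep(rownames(network$potential), times = ncol(network$potential)),
    target = rep(colnames(network$potential), each = nrow(network$potential)),
    score = sprintf("%.17g", as.vector(network$potential)))
  readr::write_tsv(long, file.path(dir, "network_potential.tsv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  lr <- readr::read_tsv(file.path(dir, "network_edges.tsv"),
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  long <- readr::read_tsv(file.path(dir, "network_potential.tsv"),
                          col_types = readr::cols(ligand = readr::col_character(),
                                                  target = readr::col_character(),
                                                  score = readr::col_double()),
                          progress = FALSE)
  ligands <- unique(long$ligand)
  targets <- unique(long$target)
  potential <- matrix(NA_real_, length(ligands), length(targets),
                      dimnames = list(ligands, targets))
  potential[cbind(long$ligand, long$target)] <- long$score
  structure(list(lr_edges = lr, potential = potential, planted_pairs = NULL),
            class = "ifa_network")
}
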