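# View-specific harmonization: pseudobulk construction, reliability filters,
# per-view normalization recipes, and the feature-wise inverse-normal
# transform applied before factor-model fitting.

#' Pseudobulk aggregation of single-cell counts
#'
#' For each cell-type cluster, computes the mean raw count over all cells of a
#' sample in that cluster, then rescales each sample row by a scaling factor
#' so that all rows of a cluster view share the same total count (the mean of
#' the raw row totals), removing differences in sequencing depth. Samples with
#' zero cells in a cluster are masked absent in that cluster's view, not
#' zero-filled, mirroring the per-view missingness the factor model accepts.
#'
#' @param cells An `ifa_cells` object.
#' @param clusters Optional subset of clusters to aggregate (default all).
#' @return Named list of `ifa_view` objects, one per cluster, with feature ids
#'   `cluster::gene`.
#' @export
pseudobulk <- function(cells, clusters = NULL) {
  meta <- cells$cell_meta
  clusters <- clusters %||% sort(unique(meta$cluster))
  samples <- sort(unique(meta$sample_id))
  out <- list()
  for (cl in clusters) {
    idx <- which(meta$cluster == cl)
    by_sample <- split(idx, meta$sample_id[idx])
    vals <- matrix(NA_real_, length(samples), ncol(cells$counts),
                   dimnames = list(samples, make_feature_ids(cl, colnames(cells$counts))))
    for (s in names(by_sample)) {
      sub <- cells$counts[by_sample[[s]], , drop = FALSE]
      vals[s, ] <- Matrix::colMeans(sub)
    }
    present <- samples %in% names(by_sample)
    totals <- rowSums(vals[present, , drop = FALSE])
    target <- mean(totals)
    if (target > 0) {
      scale <- ifelse(totals > 0, target / totals, 1)
      vals[present, ] <- vals[present, , drop = FALSE] * scale
    }
    out[[as.character(cl)]] <- view_matrix(vals, as.character(cl),
                                           mask = setNames(present, samples))
  }
  out
}

#' Expression prevalence per (cluster, gene)
#'
#' A gene counts as expressed in a cell when its count is > 0. The percentage
#' is computed over all cells of the cluster pooled across samples.
#'
#' @param cells An `ifa_cells`.
#' @return Tibble with columns `cluster`, `gene`, `n_cells_expressing`,
#'   `n_cells_total`, `pct_cells_expressing` (0-100).
#' @export
compute_prevalence <- function(cells) {
  meta <- cells$cell_meta
  clusters <- sort(unique(meta$cluster))
  purrr::map_dfr(clusters, function(cl) {
    sub <- cells$counts[meta$cluster == cl, , drop = FALSE]
    n_expr <- Matrix::colSums(sub > 0)
    tibble::tibble(cluster = as.character(cl), gene = colnames(sub),
                   n_cells_expressing = as.integer(n_expr),
                   n_cells_total = nrow(sub),
                   pct_cells_expressing = unname(100 * n_expr / nrow(sub)))
  })
}

#' Reliability filter criteria
#'
#' A list of `(min_pct, min_n)` pairs. A gene is kept when it satisfies at
#' least one pair, each pair requiring strictly `pct > min_pct` AND
#' `n > min_n`. `munich_gene_criteria()` and `groningen_gene_criteria()`
#' encode the two cohort recipes; `receptor_criteria()` the looser thresholds
#' used to call a receptor reliably measured in a cluster.
#'
#' @param ... Numeric length-2 vectors `c(min_pct, min_n)`.
#' @return An object of class `ifa_criteria`.
#' @export
filter_criteria <- function(...) {
  pairs <- list(...)
  if (!length(pairs)) abort("at least one (min_pct, min_n) pair required")
  for (p in pairs) stopifnot(is.numeric(p), length(p) == 2)
  structure(lapply(pairs, function(p) list(min_pct = p[1], min_n = p[2])),
            class = "ifa_criteria")
}

#' @rdname filter_criteria
#' @export
munich_gene_criteria <- function() filter_criteria(c(50, 1200), c(40, 3000))

#' @rdname filter_criteria
#' @export
groningen_gene_criteria <- function() filter_criteria(c(30, 1000), c(20, 2500))

#' @rdname filter_criteria
#' @export
receptor_criteria <- function() filter_criteria(c(30, 600), c(10, 1200))

criteria_keep <- function(pct, n, criteria) {
  keep <- rep(FALSE, length(pct))
  for (p in criteria) keep <- keep | (pct > p$min_pct & n > p$min_n)
  keep
}

#' Filter genes by expression prevalence
#'
#' @param prevalence Output of [compute_prevalence()].
#' @param criteria An `ifa_criteria` object.
#' @return Tibble `cluster`, `gene`, `kept` plus the triggering rule index
#'   (`rule`, NA when dropped), so every filter decision is reproducible from
#'   the log.
#' @export
filter_genes <- function(prevalence, criteria) {
  stopifnot(inherits(criteria, "ifa_criteria"))
  rule <- rep(NA_integer_, nrow(prevalence))
  for (i in seq_along(criteria)) {
    p <- criteria[[i]]
    hit <- is.na(rule) & prevalence$pct_cells_expressing > p$min_pct &
      prevalence$n_cells_expressing > p$min_n
    rule[hit] <- i
  }
  dplyr::mutate(prevalence, kept = !is.na(rule), rule = rule)
}

# across-sample quantile normalization; reference = mean of order statistics,
# ties share the mean of the reference values they span. Rows are samples.
quantile_normalize_rows <- function(m) {
  if (nrow(m) < 2 || ncol(m) < 2) return(m)
  t(limma::normalizeQuantiles(t(m), ties = TRUE))
}

#' Log-transform and quantile-normalize a pseudobulk view
#'
#' Applies `log(x + 1)` and then across-sample quantile normalization: each
#' present sample's sorted values are replaced by the mean of the order
#' statistics across samples, ties sharing the mean of their spanned reference
#' values. Absent samples stay masked.
#'
#' @param view An `ifa_view` of non-negative pseudobulk means.
#' @return The normalized `ifa_view`.
#' @export
normalize_pseudobulk <- function(view) {
  present <- view$mask[view$sample_ids]
  vals <- view$values
  lg <- log1p(vals[present, , drop = FALSE])
  vals[present, ] <- quantile_normalize_rows(lg)
  view_matrix(vals, view$view_name, mask = view$mask)
}

#' Harmonize a cytokine table
#'
#' Cytokines with valid (measured, non-OOR) values in fewer than
#' `min_valid_fraction` of assayed samples are excluded; validity is assessed
#' before any substitution. Then out-of-range (OOR) readings are set to 0 and
#' all values are `log(x + 1)` transformed.
#'
#' @param view An `ifa_view` whose `oor` mask flags OOR sentinels (as produced
#'   by [read_view_table()]).
#' @param min_valid_fraction Minimum fraction of valid values per cytokine
#'   (default 0.2).
#' @return The harmonized `ifa_view`; dropped cytokines are recorded in the
#'   `dropped` attribute.
#' @export
preprocess_cytokines <- function(view, min_valid_fraction = 0.2) {
  present <- view$mask[view$sample_ids]
  vals <- view$values[present, , drop = FALSE]
  oor <- view$oor[present, , drop = FALSE]
  valid_frac <- colMeans(!is.na(vals) & !oor)
  keep <- valid_frac >= min_valid_fraction
  dropped <- colnames(vals)[!keep]
  vals <- vals[, keep, drop = FALSE]
  oor <- oor[, keep, drop = FALSE]
  vals[oor] <- 0
  out <- view$values[, keep, drop = FALSE]
  out[present, ] <- log1p(vals)
  res <- view_matrix(out, view$view_name, mask = view$mask)
  attr(res, "dropped") <- dropped
  res
}

#' Harmonize a bulk neutrophil count table
#'
#' Steps, in order: drop mitochondrial/ribosomal genes (id prefixes `MT-`,
#' `RPL`, `RPS` by default); drop genes not expressed (count > 0) in at least
#' 80% of samples; drop samples without reads in at least 90% of the remaining
#' genes; rescale each sample to the common mean total (sequencing-depth
#' scaling); `log(x + 1)`; drop genes whose variance lies below the 25%
#' quantile of the variance distribution (linear-interpolation quantile,
#' strictly-below removed, ties at the threshold kept); across-sample quantile
#' normalization.
#'
#' @param view An `ifa_view` of raw counts.
#' @param min_sample_fraction Gene rule: minimum fraction of samples with
#'   reads (default 0.8).
#' @param min_gene_fraction Sample rule: minimum fraction of retained genes
#'   with reads (default 0.9).
#' @param var_quantile Variance filter quantile (default 0.25).
#' @param flag_prefixes Gene-id prefixes removed up front.
#' @return The harmonized `ifa_view` (samples failing the 90% rule are masked
#'   absent); the `log` attribute records every filter decision.
#' @export
preprocess_neutrophils <- function(view, min_sample_fraction = 0.8,
                                   min_gene_fraction = 0.9, var_quantile = 0.25,
                                   flag_prefixes = c("MT-", "RPL", "RPS")) {
  present <- view$mask[view$sample_ids]
  vals <- view$values[present, , drop = FALSE]
  log_steps <- list()
  genes <- feature_gene(colnames(vals))
  flagged <- Reduce(`|`, lapply(flag_prefixes, function(p) startsWith(genes, p)))
  log_steps$flagged_genes <- colnames(vals)[flagged]
  vals <- vals[, !flagged, drop = FALSE]
  expr_frac <- colMeans(vals > 0)
  keep_gene <- expr_frac >= min_sample_fraction
  log_steps$low_prevalence_genes <- colnames(vals)[!keep_gene]
  vals <- vals[, keep_gene, drop = FALSE]
  gene_frac <- rowMeans(vals > 0)
  keep_sample <- gene_frac >= min_gene_fraction
  log_steps$dropped_samples <- rownames(vals)[!keep_sample]
  vals <- vals[keep_sample, , drop = FALSE]
  if (!nrow(vals)) abort("all neutrophil samples removed by the 90% gene-coverage rule")
  totals <- rowSums(vals)
  vals <- vals * (mean(totals) / totals)
  vals <- log1p(vals)
  v <- apply(vals, 2, var)
  thr <- quantile(v, var_quantile, type = 7, names = FALSE)
  keep_var <- v >= thr
  log_steps$low_variance_genes <- colnames(vals)[!keep_var]
  vals <- vals[, keep_var, drop = FALSE]
  vals <- quantile_normalize_rows(vals)
  out <- matrix(NA_real_, length(view$sample_ids), ncol(vals),
                dimnames = list(view$sample_ids, colnames(vals)))
  out[rownames(vals), ] <- vals
  mask <- setNames(view$sample_ids %in% rownames(vals), view$sample_ids)
  res <- view_matrix(out, view$view_name, mask = mask)
  attr(res, "log") <- log_steps
  res
}

#' Filter, center and impute a plasma proteomics view
#'
#' Operates on log-scale intensities with missing entries. Proteins with fewer
#' than `min_valid` valid values are removed first, then samples with fewer
#' than `min_valid` valid values over the retained proteins. Each protein is
#' median-centered, and remaining missing entries are imputed from a
#' downshifted Gaussian
#' `Normal(mu_p - downshift * sigma_p, (width * sigma_p)^2)` where `mu_p`,
#' `sigma_p` are the protein's observed mean and standard deviation —
#' emulating intensity-dependent (left-censored) dropout. Deterministic given
#' `seed`.
#'
#' @param view An `ifa_view` of log intensities (NA = missing).
#' @param min_valid Minimum valid fraction per protein and per sample
#'   (default 0.8).
#' @param downshift Imputation downshift in protein SD units (default 1.8).
#' @param width Imputation width in protein SD units (default 0.3).
#' @param seed Integer seed for the imputation draws.
#' @return The completed `ifa_view` (samples failing the validity rule are
#'   masked absent).
#' @export
preprocess_proteomics <- function(view, min_valid = 0.8, downshift = 1.8,
                                  width = 0.3, seed = 1L) {
  present <- view$mask[view$sample_ids]
  vals <- view$values[present, , drop = FALSE]
  keep_p <- colMeans(!is.na(vals)) >= min_valid
  vals <- vals[, keep_p, drop = FALSE]
  keep_s <- rowMeans(!is.na(vals)) >= min_valid
  vals <- vals[keep_s, , drop = FALSE]
  med <- apply(vals, 2, median, na.rm = TRUE)
  vals <- sweep(vals, 2, med)
  mu <- colMeans(vals, na.rm = TRUE)
  sigma <- apply(vals, 2, sd, na.rm = TRUE)
  sigma[is.na(sigma)] <- 0
  withr::with_seed(seed, {
    for (j in seq_len(ncol(vals))) {
      miss <- which(is.na(vals[, j]))
      if (length(miss)) {
        vals[miss, j] <- rnorm(length(miss),
                               mean = mu[j] - downshift * sigma[j],
                               sd = width * sigma[j])
      }
    }
  })
  out <- matrix(NA_real_, length(view$sample_ids), ncol(vals),
                dimnames = list(view$sample_ids, colnames(vals)))
  out[rownames(vals), ] <- vals
  mask <- setNames(view$sample_ids %in% rownames(vals), view$sample_ids)
  view_matrix(out, view$view_name, mask = mask)
}

#' Log-transform clinical markers
#'
#' Clinical laboratory values (CK, CK-MB, troponin, CRP) are `log(x + 1)`
#' transformed. Negative values are a hard error: these assays report
#' non-negative concentrations, so a negative value indicates a parsing or
#' unit problem upstream.
#'
#' @param view An `ifa_view` of non-negative marker values.
#' @return The transformed `ifa_view`.
#' @export
preprocess_clinical <- function(view) {
  if (any(view$values < 0, na.rm = TRUE)) {
    bad <- which(view$values < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative clinical value at sample '%s', marker '%s'",
                  rownames(view$values)[bad[1]], colnames(view$values)[bad[2]]))
  }
  vals <- log1p(view$values)
  view_matrix(vals, view$view_name, mask = view$mask)
}

#' Feature-wise inverse-normal (rank) transform
#'
#' Maps each feature onto the quantiles of the standard normal distribution:
#' value -> `qnorm(r / (n + 1))` with average ranks for ties, computed over
#' the samples present in the feature's view. Missing entries are untouched;
#' a feature constant across samples maps to all zeros. Applied to every view
#' of a dataset as the last harmonization step before model fitting, making
#' the per-view distributions comparable.
#'
#' @param x An `ifa_dataset` or a single `ifa_view`.
#' @return Object of the same class with transformed values.
#' @export
inverse_normal_transform <- function(x) {
  if (inherits(x, "ifa_dataset")) {
    x$views <- lapply(x$views, inverse_normal_transform)
    return(x)
  }
  stopifnot(inherits(x, "ifa_view"))
  vals <- x$values
  present <- x$mask[x$sample_ids]
  sub <- vals[present, , drop = FALSE]
  for (j in seq_len(ncol(sub))) {
    obs <- !is.na(sub[, j])
    n <- sum(obs)
    if (n == 0) next
    v <- sub[obs, j]
    if (length(unique(v)) <= 1) {
      sub[obs, j] <- 0
    } else {
      sub[obs, j] <- qnorm(avg_rank(v) / (n + 1))
    }
  }
  vals[present, ] <- sub
  view_matrix(vals, x$view_name, mask = x$mask)
}

#' Centered log-ratio transform of cluster composition
#'
#' Per sample, computes the proportion of cells in each cluster (after adding
#' a pseudocount of `pseudocount` cells to every cluster to guard against
#' empty clusters) and applies the CLR transform
#' `log p_i - mean_j log p_j`. Rows sum to zero.
#'
#' @param cells An `ifa_cells`.
#' @param pseudocount Cells added to every (sample, cluster) count
#'   (default 0.5).
#' @return Tibble: `sample_id`, one column per cluster, CLR values.
#' @export
clr_composition <- function(cells, pseudocount = 0.5) {
  tab <- table(cells$cell_meta$sample_id, cells$cell_meta$cluster)
  m <- matrix(as.numeric(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab)) +
    pseudocount
  p <- m / rowSums(m)
  clr <- log(p) - rowMeans(log(p))
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(clr)),
                   tibble::as_tibble(clr))
}

#' Harmonize a synthetic (or compatible) cohort into a model-ready dataset
#'
#' Applies the full per-view recipe: pseudobulk aggregation with prevalence
#' filtering and quantile normalization for each cluster view, the cytokine
#' OOR/validity rules, the neutrophil count pipeline, proteomics filtering
#' and downshift imputation, clinical log transform, sample alignment across
#' views, and the feature-wise inverse-normal transform. The clinical view is
#' returned separately (`$clinical`) rather than as a factor view: with only
#' a handful of markers it cannot support the factor counts the model is run
#' at, and it serves as the prediction benchmark.
#'
#' @param cohort An `ifa_cohort` (see [generate_cohort()], [read_cohort()]).
#' @param gene_criteria Prevalence criteria for cluster-view genes; the
#'   default suits the synthetic cohort's scale. Use
#'   [munich_gene_criteria()] / [groningen_gene_criteria()] for
#'   cohort-scale data.
#' @param seed Seed for the proteomics imputation draws (defaults to the
#'   cohort's own seed when generated by this package).
#' @return An `ifa_dataset` ready for [fit_gfa()], with the processed
#'   clinical view attached as `$clinical` and the cell-level prevalence
#'   table as `$prevalence`.
#' @export
preprocess_cohort <- function(cohort, gene_criteria = filter_criteria(c(20, 50)),
                              seed = NULL) {
  stopifnot(inherits(cohort, "ifa_cohort"))
  seed <- seed %||% (if (!is.null(cohort$config)) cohort$config$seed else 1L)
  prevalence <- compute_prevalence(cohort$cells)
  pb <- pseudobulk(cohort$cells)
  decisions <- filter_genes(prevalence, gene_criteria)
  cluster_views <- lapply(pb, function(v) {
    keep_genes <- decisions$gene[decisions$kept & decisions$cluster == v$view_name]
    keep <- feature_gene(v$feature_ids) %in% keep_genes
    sub <- view_matrix(v$values[, keep, drop = FALSE], v$view_name, mask = v$mask)
    normalize_pseudobulk(sub)
  })
  views <- c(cluster_views,
             list(cytokines = preprocess_cytokines(cohort$views$cytokines),
                  proteomics = preprocess_proteomics(cohort$views$proteomics,
                                                     seed = derive_seed(seed, 7L)),
                  neutrophils = preprocess_neutrophils(cohort$views$neutrophils)))
  dataset <- align_samples(views, cohort$meta)
  dataset <- inverse_normal_transform(dataset)
  if (!is.null(cohort$views$clinical)) {
    clin <- preprocess_clinical(cohort$views$clinical)
    clin <- inverse_normal_transform(clr_align_view_(clin, dataset$meta$sample_id))
    dataset$clinical <- clin
  }
  dataset$prevalence <- prevalence
  dataset
}

# align one extra view onto an existing sample universe
clr_align_view_ <- function(view, universe) {
  vals <- matrix(NA_real_, length(universe), ncol(view$values),
                 dimnames = list(universe, view$feature_ids))
  present <- intersect(universe, view$sample_ids)
  vals[present, ] <- view$values[present, , drop = FALSE]
  view_matrix(vals, view$view_name,
              mask = setNames(universe %in% view$sample_ids, universe))
}
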