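# Prior-guided ligand-receptor-target analysis: targets are factor-defined,
# ligands are gated by regulatory potential and by receptor reliability in
# the target cluster, and each surviving pair is scored by the Spearman
# correlation of ligand and target levels across samples, optionally with a
# one-timepoint lag.

#' Receptors reliably measured per cluster
#'
#' A receptor counts as reliably measured in a cluster when its expression
#' prevalence satisfies at least one of the criteria pairs (strict
#' inequalities), by default `(pct > 30 & n > 600) | (pct > 10 & n > 1200)`.
#'
#' @param prevalence Output of [compute_prevalence()].
#' @param receptors Character vector of receptor gene symbols (from the
#'   prior network's edge list).
#' @param criteria An `ifa_criteria`; default [receptor_criteria()].
#' @return Tibble `cluster`, `gene` of reliable (cluster, receptor) pairs.
#' @export
reliable_receptors <- function(prevalence, receptors, criteria = receptor_criteria()) {
  sub <- prevalence[prevalence$gene %in% receptors, , drop = FALSE]
  keep <- criteria_keep(sub$pct_cells_expressing, sub$n_cells_expressing, criteria)
  tibble::as_tibble(sub[keep, c("cluster", "gene")])
}

#' Select factor-defined target features
#'
#' The top `ceiling(fraction * total)` features by absolute weight on the
#' factor, restricted to the requested weight sign.
#'
#' @param fit An `ifa_gfa`.
#' @param factor Factor index or name.
#' @param top_fraction Fraction of all features defining "top" (default 0.01).
#' @param sign `"positive"` or `"negative"`.
#' @return Tibble as [rank_features()], restricted to the sign.
#' @export
select_targets <- function(fit, factor, top_fraction = 0.01,
                           sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  top <- rank_features(fit, factor, fraction = top_fraction)
  if (sign == "positive") top[top$weight > 0, ] else top[top$weight < 0, ]
}

#' Candidate ligand-target pairs by regulatory potential
#'
#' The threshold is the `potential_quantile` quantile of all entries of the
#' regulatory-potential matrix (zeros included); a (ligand, target feature)
#' pair is kept when its potential is at or above the threshold.
#'
#' @param network An `ifa_network` (or any list with a `potential` matrix and
#'   `lr_edges` tibble).
#' @param targets Target feature tibble from [select_targets()] (needs
#'   `feature` and `gene` columns).
#' @param potential_quantile Quantile defining the threshold (default 0.97).
#' @return Tibble `ligand`, `target_feature`, `target_gene`, `potential`,
#'   with the threshold as attribute `threshold`.
#' @export
candidate_pairs <- function(network, targets, potential_quantile = 0.97) {
  pot <- network$potential
  threshold <- quantile(pot, potential_quantile, names = FALSE)
  hits <- purrr::map_dfr(seq_len(nrow(targets)), function(i) {
    g <- targets$gene[i]
    if (!g %in% colnames(pot)) return(NULL)
    lig <- rownames(pot)[pot[, g] >= threshold]
    if (!length(lig)) return(NULL)
    tibble::tibble(ligand = lig, target_feature = targets$feature[i],
                   target_gene = g, potential = pot[lig, g])
  })
  attr(hits, "threshold") <- threshold
  hits
}

# locate the feature (view::gene) carrying a ligand's measured level:
# cytokine view first, then cluster views
ligand_features <- function(dataset, ligand) {
  feats <- unlist(lapply(dataset$views, function(v) v$feature_ids), use.names = FALSE)
  feats[feature_gene(feats) == ligand]
}

#' Correlate candidate ligand-target pairs across samples
#'
#' For every candidate pair, computes the Spearman correlation (average
#' ranks) between the ligand's measured level and the target feature across
#' samples present in both views. With `lag = 1`, each ACS patient's ligand
#' level at timepoint i is paired with the target level at timepoint i+1
#' (TP1 to TP2, TP2 to TP3, TP3 to TP4), capturing delayed responses.
#'
#' Pairs are kept when `|rho| >= min_abs_rho`, ligand and target views
#' differ, and — when the target lies in a cell-type cluster view — at least
#' one receptor of the ligand (per the prior network's edge list) is reliably
#' measured in the target cluster. Pairs with fewer than `min_pairs` usable
#' observations are dropped with a message.
#'
#' @param dataset An `ifa_dataset` (harmonized; the same one the model was
#'   fitted to).
#' @param pairs Candidate pairs from [candidate_pairs()].
#' @param reliable Reliable (cluster, receptor) tibble from
#'   [reliable_receptors()].
#' @param network The `ifa_network` providing `lr_edges`.
#' @param min_abs_rho Minimum absolute Spearman correlation (default 0.4).
#' @param lag 0 (same-timepoint) or 1 (ligand leads by one timepoint).
#' @param min_pairs Minimum usable observations per correlation (default 5).
#' @param acs_timepoints Timepoints defining the lag mapping, in order.
#' @param cluster_views Names of the views that are cell-type clusters (the
#'   receptor gate applies to targets in these). Defaults to the clusters in
#'   the dataset's prevalence table, else those in `reliable`.
#' @return Tibble `ligand`, `ligand_feature`, `target_feature`,
#'   `target_view`, `spearman_rho`, `n_pairs`, `potential`, `lagged`.
#' @export
correlate_pairs <- function(dataset, pairs, reliable, network,
                            min_abs_rho = 0.4, lag = 0, min_pairs = 5,
                            acs_timepoints = c("TP1", "TP2", "TP3", "TP4"),
                            cluster_views = NULL) {
  stopifnot(lag %in% c(0, 1))
  cluster_views <- cluster_views %||%
    unique(c(dataset$prevalence$cluster, reliable$cluster))
  meta <- dataset$meta
  views <- dataset$views
  feat_index <- purrr::map_dfr(views, function(v) {
    tibble::tibble(feature = v$feature_ids, view = v$view_name)
  })
  get_values <- function(feature) {
    vn <- feat_index$view[match(feature, feat_index$feature)]
    v <- views[[vn]]
    vals <- v$values[, feature]
    vals[!v$mask[v$sample_ids]] <- NA
    list(view = vn, values = vals)
  }
  lag_map <- NULL
  if (lag == 1) {
    acs <- meta[meta$timepoint %in% acs_timepoints, , drop = FALSE]
    steps <- purrr::map_dfr(seq_len(length(acs_timepoints) - 1), function(i) {
      lig <- acs[acs$timepoint == acs_timepoints[i], c("patient_id", "sample_id")]
      tgt <- acs[acs$timepoint == acs_timepoints[i + 1], c("patient_id", "sample_id")]
      dplyr::inner_join(lig, tgt, by = "patient_id", suffix = c("_ligand", "_target"))
    })
    lag_map <- steps
  }
  out <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    lg <- pairs$ligand[i]
    tf <- pairs$target_feature[i]
    tgt <- get_values(tf)
    lig_feats <- ligand_features(dataset, lg)
    purrr::map_dfr(lig_feats, function(lf) {
      lig <- get_values(lf)
      if (lig$view == tgt$view) return(NULL)
      # receptor gate for cluster-view targets
      if (tgt$view %in% cluster_views) {
        rec <- network$lr_edges$receptor[network$lr_edges$ligand == lg]
        ok <- any(reliable$gene %in% rec & reliable$cluster == tgt$view)
        if (!ok) return(NULL)
      }
      if (lag == 0) {
        x <- lig$values; y <- tgt$values
        use <- !is.na(x) & !is.na(y)
        xv <- x[use]; yv <- y[use]
      } else {
        xv <- lig$values[lag_map$sample_id_ligand]
        yv <- tgt$values[lag_map$sample_id_target]
        use <- !is.na(xv) & !is.na(yv)
        xv <- xv[use]; yv <- yv[use]
      }
      if (sum(use) < min_pairs) {
        message(sprintf("pair %s -> %s: only %d usable observations; dropped",
                        lf, tf, sum(use)))
        return(NULL)
      }
      rho <- cor(xv, yv, method = "spearman")
      tibble::tibble(ligand = lg, ligand_feature = lf, target_feature = tf,
                     target_view = tgt$view, spearman_rho = rho,
                     n_pairs = length(xv), potential = pairs$potential[i],
                     lagged = lag == 1)
    })
  })
  if (!nrow(out)) return(out)
  out[abs(out$spearman_rho) >= min_abs_rho, , drop = FALSE]
}
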