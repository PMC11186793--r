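# Ligand-target scoring: threshold logic is forced by the printed criteria;
# the Spearman statistic is checked against rank-then-Pearson brute force;
# planted pairs must surface through the full gated pipeline.

test_that("receptor reliability applies the printed OR-of-ANDs thresholds", {
  prev <- tibble::tibble(cluster = "c0",
                         gene = c("r1", "r2", "r3", "r4", "r5"),
                         n_cells_expressing = c(700L, 1300L, 1000L, 601L, 1200L),
                         n_cells_total = 5000L,
                         pct_cells_expressing = c(35, 12, 25, 30, 10))
  rel <- reliable_receptors(prev, prev$gene)
  # 35/700 passes pair 1; 12/1300 passes pair 2; 25/1000 fails both;
  # 30/601 fails (strict pct); 10/1200 fails (strict both)
  expect_setequal(rel$gene, c("r1", "r2"))
})

test_that("target selection composes ranking and sign filtering", {
  fit <- cached_small_fit()$fit
  top <- rank_features(fit, 1, fraction = 0.05)
  pos <- select_targets(fit, 1, top_fraction = 0.05, sign = "positive")
  expect_equal(pos$feature, top$feature[top$weight > 0])
  neg <- select_targets(fit, 1, top_fraction = 0.05, sign = "negative")
  expect_equal(sort(c(pos$feature, neg$feature)), sort(top$feature))
  # all weights of one sign leave the other empty
  fit2 <- fit
  fit2$W <- lapply(fit2$W, function(w) { w[, 2] <- -abs(w[, 2]); w })
  expect_equal(nrow(select_targets(fit2, 2, 1, "positive")), 0L)
  # fraction 1 with positive sign returns every positive-weight feature
  all_pos <- select_targets(fit, 1, top_fraction = 1, sign = "positive")
  n_pos <- sum(unlist(lapply(fit$W, function(w) w[, 1] > 0)))
  expect_equal(nrow(all_pos), n_pos)
})

test_that("the potential threshold retains the top quantile exactly", {
  set.seed(1)
  pot <- matrix(runif(100), 10, 10,
                dimnames = list(paste0("L", 1:10), paste0("g", 1:10)))
  net <- list(potential = pot, lr_edges = tibble::tibble(ligand = character(),
                                                         receptor = character()))
  targets <- tibble::tibble(feature = paste0("v::g", 1:10), gene = paste0("g", 1:10))
  hits <- candidate_pairs(net, targets, potential_quantile = 0.97)
  # 100 i.i.d. entries at the 0.97 quantile: exactly 3 at or above
  expect_equal(nrow(hits), 3L)
  expect_true(all(hits$potential >= attr(hits, "threshold")))
  # quantile 0 keeps every pair
  expect_equal(nrow(candidate_pairs(net, targets, 0)), 100L)
})

test_that("Spearman matches brute-force rank-then-Pearson with ties", {
  set.seed(2)
  for (i in 1:100) {
    x <- sample(round(rnorm(12), 1))   # rounding induces ties
    y <- sample(round(rnorm(12), 1))
    expect_equal(cor(x, y, method = "spearman"),
                 cor(rank(x), rank(y), method = "pearson"))
  }
})

test_that("monotone pairs are kept with the expected sign", {
  cfg <- tiny_config(seed = 30, missing_view_rate = 0)
  sim <- generate_cohort(cfg)
  ds <- preprocess_cohort(sim$cohort)
  # construct a two-feature scenario by hand: ligand in cytokines, target in
  # a cluster view, perfectly monotone
  lig_feat <- ds$views$cytokines$feature_ids[1]
  tgt_feat <- ds$views[[1]]$feature_ids[1]
  n <- nrow(ds$meta)
  ds$views$cytokines$values[, lig_feat] <- seq_len(n)
  ds$views[[1]]$values[, tgt_feat] <- seq_len(n)^2
  pairs <- tibble::tibble(ligand = immunofactors:::feature_gene(lig_feat),
                          target_feature = tgt_feat,
                          target_gene = immunofactors:::feature_gene(tgt_feat),
                          potential = 1)
  rel <- tibble::tibble(cluster = ds$views[[1]]$view_name,
                        gene = sim$cohort$network$lr_edges$receptor[
                          sim$cohort$network$lr_edges$ligand == pairs$ligand][1])
  net <- list(lr_edges = sim$cohort$network$lr_edges)
  res <- correlate_pairs(ds, pairs, rel, net)
  expect_equal(nrow(res), 1L)
  expect_equal(res$spearman_rho, 1)
  # anti-monotone target: rho -1, still kept by |rho|
  ds$views[[1]]$values[, tgt_feat] <- rev(seq_len(n))
  res2 <- correlate_pairs(ds, pairs, rel, net)
  expect_equal(res2$spearman_rho, -1)
  # receptor gate: no reliable receptor in the target cluster drops the pair
  res3 <- correlate_pairs(ds, pairs, rel[0, ], net)
  expect_equal(nrow(res3), 0L)
})

test_that("the lag mapping pairs TP1->TP2, TP2->TP3, TP3->TP4 per patient", {
  cfg <- tiny_config(seed = 31, missing_view_rate = 0, protein_missing_rate = 0)
  sim <- generate_cohort(cfg)
  ds <- preprocess_cohort(sim$cohort)
  meta <- ds$meta
  lig_feat <- ds$views$cytokines$feature_ids[1]
  tgt_feat <- ds$views$proteomics$feature_ids[1]
  # plant a perfect lagged relation: target at TP(i+1) equals ligand at TP(i)
  acs <- meta[meta$group == "sterile_ACS", ]
  lig_vals <- setNames(seq_len(nrow(meta)), meta$sample_id)
  ds$views$cytokines$values[, lig_feat] <- lig_vals
  tgt_vals <- rnorm(nrow(meta))
  names(tgt_vals) <- meta$sample_id
  tps <- c("TP1", "TP2", "TP3", "TP4")
  for (p in unique(acs$patient_id)) {
    for (i in 1:3) {
      sid_l <- acs$sample_id[acs$patient_id == p & acs$timepoint == tps[i]]
      sid_t <- acs$sample_id[acs$patient_id == p & acs$timepoint == tps[i + 1]]
      tgt_vals[sid_t] <- lig_vals[sid_l]
    }
  }
  ds$views$proteomics$values[, tgt_feat] <- tgt_vals
  pairs <- tibble::tibble(ligand = immunofactors:::feature_gene(lig_feat),
                          target_feature = tgt_feat,
                          target_gene = immunofactors:::feature_gene(tgt_feat),
                          potential = 1)
  net <- list(lr_edges = sim$cohort$network$lr_edges)
  res <- correlate_pairs(ds, pairs, tibble::tibble(cluster = character(),
                                                   gene = character()),
                         net, lag = 1)
  expect_equal(res$spearman_rho, 1)
  # exactly 3 lagged pairs per ACS patient enter the correlation
  expect_equal(res$n_pairs, 3L * dplyr::n_distinct(acs$patient_id))
  expect_true(res$lagged)
})

test_that("lag 0 with one sample per patient-timepoint is the plain correlation", {
  ds <- cached_small_fit()$dataset
  lig_feat <- ds$views$cytokines$feature_ids[2]
  tgt_feat <- ds$views$proteomics$feature_ids[2]
  pairs <- tibble::tibble(ligand = immunofactors:::feature_gene(lig_feat),
                          target_feature = tgt_feat,
                          target_gene = immunofactors:::feature_gene(tgt_feat),
                          potential = 1)
  net <- list(lr_edges = tibble::tibble(ligand = character(), receptor = character()))
  res <- correlate_pairs(ds, pairs, tibble::tibble(cluster = character(),
                                                   gene = character()),
                         net, min_abs_rho = 0)
  v1 <- ds$views$cytokines; v2 <- ds$views$proteomics
  x <- v1$values[, lig_feat]; x[!v1$mask] <- NA
  y <- v2$values[, tgt_feat]; y[!v2$mask] <- NA
  use <- !is.na(x) & !is.na(y)
  expect_equal(res$spearman_rho, cor(x[use], y[use], method = "spearman"))
  expect_equal(res$n_pairs, sum(use))
})

test_that("pairs with too few observations are dropped with a message", {
  ds <- cached_small_fit()$dataset
  lig_feat <- ds$views$cytokines$feature_ids[1]
  tgt_feat <- ds$views$proteomics$feature_ids[1]
  # blank out the ligand almost everywhere
  ds$views$cytokines$mask[] <- FALSE
  ds$views$cytokines$mask[1:3] <- TRUE
  pairs <- tibble::tibble(ligand = immunofactors:::feature_gene(lig_feat),
                          target_feature = tgt_feat,
                          target_gene = immunofactors:::feature_gene(tgt_feat),
                          potential = 1)
  net <- list(lr_edges = tibble::tibble(ligand = character(), receptor = character()))
  expect_message(
    res <- correlate_pairs(ds, pairs, tibble::tibble(cluster = character(),
                                                     gene = character()), net),
    "usable observations")
  expect_equal(nrow(res), 0L)
})

test_that("planted ligand-target pairs survive the full gated pipeline", {
  hits <- 0L
  n_seeds <- 5L
  for (seed in seq_len(n_seeds)) {
    sim <- if (seed == 1) cached_default_sim(1)$sim else
      generate_cohort(cohort_config(seed = seed))
    ds <- if (seed == 1) cached_default_sim(1)$dataset else
      preprocess_cohort(sim$cohort)
    net <- sim$cohort$network
    planted <- sim$truth$planted_pairs
    targets <- tibble::tibble(feature = planted$target_feature,
                              gene = planted$target)
    cand <- candidate_pairs(net, targets, 0.97)
    rel <- reliable_receptors(ds$prevalence, unique(net$lr_edges$receptor))
    res <- correlate_pairs(ds, cand, rel, net, min_abs_rho = 0.4)
    found <- sum(paste(planted$ligand, planted$target_feature) %in%
                   paste(res$ligand, res$target_feature))
    hits <- hits + (found >= 2)   # at least 2 of the 3 planted pairs
  }
  expect_gte(hits, n_seeds - 1L)
})

test_that("decoy pairs rarely pass the correlation threshold under independence", {
  set.seed(4)
  n <- 40
  fp <- mean(replicate(400, {
    abs(cor(rnorm(n), rnorm(n), method = "spearman")) >= 0.4
  }))
  expect_lt(fp, 0.1)
})
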