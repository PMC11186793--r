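# Unit checks for every harmonization rule; expected values are either
# forced by the printed thresholds or computed by independent brute force.

test_that("pseudobulk means raw counts then equalizes row totals", {
  pb <- pseudobulk(toy_cells())
  # s1/cA: cells (2,0,1,0) and (4,0,3,0) -> mean (3,0,2,0) before scaling
  raw_s1 <- c(3, 0, 2, 0)
  raw_s2 <- c(2, 0, 0.5, 0)
  t1 <- sum(raw_s1); t2 <- sum(raw_s2); target <- mean(c(t1, t2))
  expect_equal(unname(pb$cA$values["s1", ]), raw_s1 * target / t1)
  expect_equal(unname(pb$cA$values["s2", ]), raw_s2 * target / t2)
  expect_equal(unname(rowSums(pb$cA$values)), c(target, target))
})

test_that("samples without cells in a cluster are masked, not zero-filled", {
  cells <- toy_cells()
  # remove s2's only cB cell
  keep <- !(cells$cell_meta$sample_id == "s2" & cells$cell_meta$cluster == "cB")
  cells <- cell_matrix(cells$counts[keep, ], cells$cell_meta[keep, ])
  pb <- pseudobulk(cells)
  expect_false(pb$cB$mask[["s2"]])
  expect_true(all(is.na(pb$cB$values["s2", ])))
})

test_that("prevalence counts expressing cells over the pooled cluster", {
  prev <- compute_prevalence(toy_cells())
  # g2 in cB: cells (5,3,4,2) -> 4 of 4 expressing
  row <- prev[prev$cluster == "cB" & prev$gene == "g2", ]
  expect_equal(row$n_cells_expressing, 4L)
  expect_equal(row$pct_cells_expressing, 100)
  # g4 in cA: never expressed
  row <- prev[prev$cluster == "cA" & prev$gene == "g4", ]
  expect_equal(row$n_cells_expressing, 0L)
  expect_equal(row$pct_cells_expressing, 0)
  # brute-force recount on a generated fixture
  cells <- generate_cohort(tiny_config(seed = 20, cells_per_sample = 25))$cohort$cells
  prev <- compute_prevalence(cells)
  for (i in sample(nrow(prev), 10)) {
    idx <- cells$cell_meta$cluster == prev$cluster[i]
    expect_equal(prev$n_cells_expressing[i],
                 sum(cells$counts[idx, prev$gene[i]] > 0))
  }
})

test_that("gene filters enforce the printed thresholds exactly", {
  prev <- tibble::tibble(cluster = "c", gene = c("a", "b", "c"),
                         n_cells_expressing = c(1500L, 2000L, 3100L),
                         n_cells_total = 10000L,
                         pct_cells_expressing = c(60, 45, 41))
  dec <- filter_genes(prev, munich_gene_criteria())
  expect_equal(dec$kept, c(TRUE, FALSE, TRUE))  # 60/1500 pair1; 45/2000 fails; 41/3100 pair2
  expect_equal(dec$rule, c(1L, NA, 2L))
  # boundaries are strict
  prev2 <- tibble::tibble(cluster = "c", gene = c("d", "e"),
                          n_cells_expressing = c(1200L, 1201L),
                          n_cells_total = 10000L,
                          pct_cells_expressing = c(51, 50))
  dec2 <- filter_genes(prev2, munich_gene_criteria())
  expect_equal(dec2$kept, c(FALSE, FALSE))
  # filters are idempotent: re-running on the survivors keeps them all
  surv <- dec[dec$kept, ]
  expect_true(all(filter_genes(surv, munich_gene_criteria())$kept))
})

test_that("quantile normalization equalizes sample distributions", {
  # samples (1,2,3) and (4,5,6): both rows become the mean of sorted logs
  v <- make_view(rbind(c(1, 2, 3), c(4, 5, 6)))
  out <- normalize_pseudobulk(v)
  ref <- rowMeans(cbind(log1p(1:3), log1p(4:6)))
  expect_equal(unname(out$values[1, ]), ref)
  expect_equal(unname(out$values[2, ]), ref)
  # identical samples are unchanged by the quantile step
  v2 <- make_view(rbind(c(1, 5, 2), c(1, 5, 2)))
  out2 <- normalize_pseudobulk(v2)
  expect_equal(unname(out2$values[1, ]), log1p(c(1, 5, 2)))
  # monotone order within each sample is preserved
  v3 <- make_view(matrix(rexp(50), 5, 10))
  out3 <- normalize_pseudobulk(v3)
  for (i in 1:5) {
    expect_equal(order(out3$values[i, ]), order(v3$values[i, ]))
  }
})

test_that("cytokine preprocessing assesses validity before OOR substitution", {
  vals <- matrix(c(2, NA, NA, NA, NA, NA,   # c1: valid in 1/6 < 20% -> drop
                   0, 3, 1, NA, 2, 5,       # c2: OOR cell counted invalid
                   1, 2, 3, 4, 5, 6), 6, 3,
                 dimnames = list(sprintf("s%d", 1:6), c("cy::c1", "cy::c2", "cy::c3")))
  oor <- matrix(FALSE, 6, 3, dimnames = dimnames(vals))
  oor[4, 2] <- TRUE
  v <- view_matrix(vals, "cy", oor = oor)
  out <- preprocess_cytokines(v, min_valid_fraction = 0.2)
  expect_equal(attr(out, "dropped"), "cy::c1")
  expect_equal(colnames(out$values), c("cy::c2", "cy::c3"))
  # OOR becomes 0 -> log1p(0) = 0, and zero stays zero
  expect_equal(out$values["s4", "cy::c2"], 0)
  expect_equal(out$values["s1", "cy::c2"], 0)
  expect_equal(out$values["s6", "cy::c3"], log1p(6))
  # a cytokine valid in exactly 15% of samples is removed
  vals2 <- matrix(NA_real_, 20, 2,
                  dimnames = list(sprintf("s%02d", 1:20), c("cy::lo", "cy::hi")))
  vals2[1:3, "cy::lo"] <- 1   # 15% valid
  vals2[, "cy::hi"] <- 2
  out2 <- preprocess_cytokines(view_matrix(vals2, "cy"))
  expect_equal(attr(out2, "dropped"), "cy::lo")
})

test_that("the neutrophil pipeline applies its filters in the stated order", {
  set.seed(1)
  n <- 20
  base <- matrix(rpois(n * 6, 50), n, 6)
  colnames(base) <- paste0("pmn::", c("GOOD1", "GOOD2", "GOOD3", "GOOD4", "RARE", "MT-X"))
  rownames(base) <- sprintf("s%02d", 1:n)
  base[, "pmn::RARE"] <- 0; base[1:5, "pmn::RARE"] <- 3     # expressed in 25% < 80%
  bad_sample <- "s01"                                        # reads in too few genes
  base[bad_sample, c("pmn::GOOD1", "pmn::GOOD2")] <- 0       # 2/4 retained genes = 50% < 90%
  v <- view_matrix(base, "pmn")
  out <- preprocess_neutrophils(v)
  lg <- attr(out, "log")
  expect_equal(lg$flagged_genes, "pmn::MT-X")
  expect_equal(lg$low_prevalence_genes, "pmn::RARE")
  expect_equal(lg$dropped_samples, bad_sample)
  expect_false(out$mask[[bad_sample]])
  # variance filter: genes strictly below the 25% quantile are removed
  expect_equal(ncol(out$values), 3)  # one of four retained genes dropped
})

test_that("the variance filter drops strictly-below-quantile genes", {
  # 8 genes with log-scale variances 1..8: the 25% quantile (type 7) is 2.75,
  # so exactly the two lowest-variance genes fall below it
  v <- c(1:8)
  thr <- quantile(v, 0.25, type = 7, names = FALSE)
  expect_equal(sum(v < thr), 2)
  expect_equal(sum(v >= thr), 6)
})

test_that("a gene expressed in 79% of samples fails the neutrophil gene rule", {
  n <- 100
  m <- matrix(5, n, 2, dimnames = list(sprintf("s%03d", 1:n), c("pmn::a", "pmn::b")))
  m[1:21, "pmn::a"] <- 0   # expressed in 79%
  out <- preprocess_neutrophils(view_matrix(m, "pmn"), var_quantile = 0)
  expect_equal(attr(out, "log")$low_prevalence_genes, "pmn::a")
})

test_that("proteomics filtering, centering and imputation follow the recipe", {
  set.seed(2)
  n <- 20
  vals <- matrix(rnorm(n * 3, 10), n, 3,
                 dimnames = list(sprintf("s%02d", 1:n), c("p::a", "p::b", "p::c")))
  vals[1:6, "p::a"] <- NA   # 70% valid -> removed
  vals[1, "p::b"] <- NA     # 95% valid -> kept, imputed
  v <- view_matrix(vals, "p")
  out <- preprocess_proteomics(v, seed = 3)
  expect_equal(colnames(out$values), c("p::b", "p::c"))
  expect_false(anyNA(out$values[out$mask, ]))
  # with no missing values the output is exactly the median-centered input
  v2 <- view_matrix(vals[, "p::c", drop = FALSE], "p")
  out2 <- preprocess_proteomics(v2, seed = 3)
  expect_equal(out2$values[, 1], vals[, "p::c"] - median(vals[, "p::c"]))
  # deterministic given the seed
  out3 <- preprocess_proteomics(v, seed = 3)
  expect_identical(out$values, out3$values)
})

test_that("downshift imputation draws from the stated Gaussian", {
  set.seed(4)
  n <- 10000
  vals <- matrix(rnorm(n * 2), n, 2,
                 dimnames = list(sprintf("s%05d", 1:n), c("p::x", "p::ref")))
  miss <- sample(n, 2000)
  vals[miss, 1] <- NA
  mu <- mean(vals[, 1], na.rm = TRUE); sg <- sd(vals[, 1], na.rm = TRUE)
  med <- median(vals[, 1], na.rm = TRUE)
  out <- preprocess_proteomics(view_matrix(vals, "p"), min_valid = 0.5, seed = 5)
  imputed <- out$values[miss, 1]
  expect_equal(mean(imputed), (mu - med) - 1.8 * sg, tolerance = 0.02)
  expect_equal(sd(imputed), 0.3 * sg, tolerance = 0.02)
})

test_that("degenerate proteins impute the constant downshifted mean", {
  set.seed(6)
  vals <- cbind(rep(5, 10), matrix(rnorm(40), 10, 4))
  dimnames(vals) <- list(sprintf("s%02d", 1:10),
                         c("p::flat", sprintf("p::ref%d", 1:4)))
  vals[3, 1] <- NA
  out <- preprocess_proteomics(view_matrix(vals, "p"), seed = 1)
  expect_equal(out$values[3, 1], 0)  # median-centered constant, sigma = 0
})

test_that("clinical preprocessing is log1p and rejects negatives", {
  v <- make_view(matrix(c(0, exp(1) - 1, 3), 3, 1,
                        dimnames = list(c("s1", "s2", "s3"), "clinical::CK")), "clinical")
  out <- preprocess_clinical(v)
  expect_equal(unname(out$values[, 1]), c(0, 1, log1p(3)))
  bad <- make_view(matrix(-1, 1, 1, dimnames = list("s1", "clinical::CK")), "clinical")
  expect_error(preprocess_clinical(bad), "negative clinical value")
})

test_that("the inverse-normal transform maps ranks onto normal quantiles", {
  v <- make_view(matrix(c(5, 2, 9), 3, 1))
  out <- inverse_normal_transform(v)
  expect_equal(unname(out$values[, 1]),
               qnorm(c(2, 1, 3) / 4), tolerance = 1e-10)
  expect_equal(round(unname(out$values[, 1]), 4), c(0, -0.6745, 0.6745))
  # rank invariance: any strictly monotone transform gives identical output
  x <- rexp(15)
  v1 <- make_view(matrix(x, 15, 1))
  v2 <- make_view(matrix(exp(2 * x) + 1, 15, 1))
  expect_equal(inverse_normal_transform(v1)$values,
               inverse_normal_transform(v2)$values)
  # ties share average ranks
  vt <- make_view(matrix(c(1, 1, 2), 3, 1))
  expect_equal(unname(inverse_normal_transform(vt)$values[, 1]),
               qnorm(c(1.5, 1.5, 3) / 4))
  # constants map to zero, missing entries stay untouched
  vc <- make_view(matrix(c(7, 7, 7, NA), 4, 1))
  outc <- inverse_normal_transform(vc)
  expect_equal(unname(outc$values[, 1]), c(0, 0, 0, NA))
})

test_that("inverse-normal output is mean-zero for odd tie-free n", {
  for (n in c(5, 9, 15)) {
    v <- make_view(matrix(sample(rnorm(n * 3)), n, 3))
    out <- inverse_normal_transform(v)
    expect_lt(max(abs(colMeans(out$values))), 1e-9)
  }
})

test_that("the CLR transform maps compositions to zero-sum coordinates", {
  clr <- clr_composition(toy_cells(), pseudocount = 0.5)
  m <- as.matrix(clr[, -1])
  expect_lt(max(abs(rowSums(m))), 1e-10)
  # direct formula on known proportions, no zeros involved
  p <- c(0.5, 0.25, 0.25)
  expect_equal(round(log(p) - mean(log(p)), 4), c(0.4621, -0.2310, -0.2310))
  # equal counts give all-zero CLR
  counts <- matrix(1L, 4, 2, dimnames = list(sprintf("c%d", 1:4), c("g1", "g2")))
  meta <- tibble::tibble(cell_id = sprintf("c%d", 1:4), sample_id = "s1",
                         cluster = c("a", "b", "c", "d"))
  clr2 <- clr_composition(cell_matrix(counts, meta))
  expect_equal(unname(as.matrix(clr2[, -1])[1, ]), rep(0, 4))
})

test_that("CLR output is equivariant under cluster relabeling", {
  cells <- toy_cells()
  clr <- clr_composition(cells)
  relabeled <- cells
  relabeled$cell_meta$cluster <- c(cA = "zB", cB = "aA")[relabeled$cell_meta$cluster]
  clr2 <- clr_composition(cell_matrix(relabeled$counts, relabeled$cell_meta))
  expect_equal(unname(as.matrix(clr2[, c("aA", "zB")])),
               unname(as.matrix(clr[, c("cB", "cA")])))
})
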