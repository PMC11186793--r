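# Pathway enrichment on factor weights across all views: a pathway's gene set
# is extended to every feature whose gene symbol it contains, and the set's
# weights are compared to the background by a Wilcoxon rank-sum test.

#' Read a GMT pathway file
#'
#' Standard tab-delimited GMT: pathway id, description, then gene symbols.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (gene sets).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  stop_if_duplicated(names(sets), "pathway ids")
  sets[lengths(sets) > 0]
}

#' Write gene sets to GMT
#'
#' @param sets Named list of gene sets.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Extend pathway annotation to multi-view features
#'
#' A feature (`view::gene`) belongs to a pathway iff its gene symbol is in
#' the pathway's gene set — so one gene measured in several views contributes
#' several features. Coverage is the fraction of the pathway's genes present
#' anywhere in the feature universe.
#'
#' @param pathways Named list of gene sets (see [read_gmt()]).
#' @param features Character vector of `view::gene` feature ids.
#' @return An `ifa_pathways` object: named list with per-pathway `features`
#'   and `coverage`.
#' @export
extend_annotation <- function(pathways, features) {
  genes <- feature_gene(features)
  present <- unique(genes)
  ext <- lapply(pathways, function(set) {
    list(features = features[genes %in% set],
         coverage = mean(set %in% present))
  })
  structure(ext, class = "ifa_pathways")
}

#' Filter extended pathways by coverage
#'
#' Pathways whose coverage (fraction of member genes present in the feature
#' universe) is below `min_coverage` are removed; `less than` is strict, so a
#' pathway at exactly the threshold is retained. A stricter display threshold
#' (e.g. 0.5) can be applied the same way for reporting.
#'
#' @param extended An `ifa_pathways` from [extend_annotation()].
#' @param min_coverage Minimum coverage retained (default 0.2).
#' @return The filtered `ifa_pathways`.
#' @export
filter_by_coverage <- function(extended, min_coverage = 0.2) {
  keep <- vapply(extended, function(p) p$coverage >= min_coverage, logical(1))
  structure(extended[keep], class = "ifa_pathways")
}

# two-sided Wilcoxon rank-sum; exact enumeration when both groups are small
# and tie-free, normal approximation with tie correction otherwise
rank_sum_test <- function(set_scores, bg_scores) {
  exact <- length(set_scores) <= 10 && length(bg_scores) <= 10 &&
    !any(duplicated(c(set_scores, bg_scores)))
  ht <- suppressWarnings(wilcox.test(set_scores, bg_scores, exact = exact,
                                     correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Rank-sum enrichment of pathways on factor weights
#'
#' For each pathway, compares the scores of its features against all other
#' features by a two-sided Wilcoxon rank-sum test, where the score is the
#' signed weight for `direction = "positive"` (restricted to
#' positive-weight features), the negated weight for `"negative"`
#' (negative-weight features only), and the absolute weight for `"all"`.
#' P-values are Benjamini-Hochberg adjusted over the tested pathways within
#' the direction.
#'
#' @param weights Named numeric vector of feature weights on one factor
#'   (names are `view::gene` ids); take a column of `fit$W` stacked over
#'   views, or use [rank_features()] with `fraction = 1`.
#' @param extended An `ifa_pathways`, already coverage-filtered.
#' @param direction One of `"positive"`, `"negative"`, `"all"`.
#' @return Tibble `pathway`, `direction`, `n_set`, `coverage`, `statistic`,
#'   `p_value`, `adj_p`, sorted by `p_value`. Pathways with no features after
#'   extension (or none of the requested sign) are skipped with a message.
#' @export
enrich <- function(weights, extended, direction = c("all", "positive", "negative")) {
  direction <- match.arg(direction)
  feats <- names(weights)
  if (is.null(feats)) abort("`weights` must be named by feature id")
  keep <- switch(direction,
                 positive = weights > 0,
                 negative = weights < 0,
                 all = rep(TRUE, length(weights)))
  scores <- switch(direction,
                   positive = weights[keep],
                   negative = -weights[keep],
                   all = abs(weights))
  rows <- purrr::map_dfr(names(extended), function(nm) {
    set_feats <- intersect(extended[[nm]]$features, names(scores))
    if (!length(set_feats)) {
      message(sprintf("pathway '%s': no features after extension/sign restriction; skipped", nm))
      return(NULL)
    }
    bg <- setdiff(names(scores), set_feats)
    ht <- rank_sum_test(unname(scores[set_feats]), unname(scores[bg]))
    tibble::tibble(pathway = nm, direction = direction,
                   n_set = length(set_feats),
                   coverage = extended[[nm]]$coverage,
                   statistic = ht$statistic, p_value = ht$p_value)
  })
  if (!nrow(rows)) return(dplyr::mutate(rows, adj_p = numeric(0)))
  rows$adj_p <- adjust_bh(rows$p_value)
  dplyr::arrange(rows, .data$p_value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order.
#' @export
adjust_bh <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  p.adjust(p_values, method = "BH")
}
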