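# Internal helpers shared across modules.

# feature ids follow the "view::gene" convention used throughout the field's
# multi-view models; the gene symbol is everything after the first "::".
feature_view <- function(ids) sub("::.*$", "", ids)

feature_gene <- function(ids) sub("^[^:]*::", "", ids)

make_feature_ids <- function(view, genes) paste0(view, "::", genes)

stop_if_duplicated <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  if (length(dup)) {
    abort(sprintf("duplicate %s: %s", what, paste(head(dup, 5), collapse = ", ")))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  as.integer(x)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x >= 1) {
    abort(sprintf("`%s` must be a fraction in [0, 1)", name))
  }
  as.numeric(x)
}

# average ranks, as used by the inverse-normal transform and Spearman checks
avg_rank <- function(x) rank(x, ties.method = "average", na.last = "keep")

# deterministic child seeds below 2^31 derived from one user seed
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629) + 1L
}
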