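# Transfer of a fitted factor model to an external cohort: feature matching,
# right-inverse projection of samples onto the source factors, and
# per-timepoint trajectory summaries.

#' Match model features to a target cohort
#'
#' Intersects the model's features with the target dataset's by exact
#' `view::gene` id within a whitelist of views (the well-aligned cell types
#' plus any bulk views shared between cohorts). Unmatched features are
#' dropped from the weight matrix; a per-view report of matched and
#' unmatched counts is attached.
#'
#' @param fit An `ifa_gfa` fitted on the source cohort.
#' @param target_dataset An `ifa_dataset` preprocessed with the source
#'   recipe. The projector refuses raw inputs downstream, so run the view
#'   recipes and [inverse_normal_transform()] first.
#' @param view_whitelist Views to match (default: all views shared by model
#'   and target).
#' @param cluster_map Optional tibble (`source_name`, `target_name`) renaming
#'   target views onto the source annotation before matching.
#' @return A `projection_input`: `W_matched` (K x D), `Y_target`
#'   (sample x D), `report` (tibble `view`, `n_model`, `n_matched`).
#' @export
match_features <- function(fit, target_dataset, view_whitelist = NULL,
                           cluster_map = NULL) {
  target_views <- target_dataset$views
  if (!is.null(cluster_map)) {
    stopifnot(all(c("source_name", "target_name") %in% names(cluster_map)))
    renames <- setNames(cluster_map$source_name, cluster_map$target_name)
    idx <- names(target_views) %in% names(renames)
    names(target_views)[idx] <- renames[names(target_views)[idx]]
    target_views[idx] <- purrr::map2(target_views[idx], names(target_views)[idx],
      function(v, nm) {
        colnames(v$values) <- make_feature_ids(nm, feature_gene(v$feature_ids))
        view_matrix(v$values, nm, mask = v$mask)
      })
  }
  whitelist <- view_whitelist %||% intersect(names(fit$W), names(target_views))
  Wk <- list(); Yk <- list(); report <- list()
  for (vn in whitelist) {
    model_feats <- rownames(fit$W[[vn]])
    tgt <- target_views[[vn]]
    matched <- if (is.null(tgt)) character() else intersect(model_feats, tgt$feature_ids)
    report[[vn]] <- tibble::tibble(view = vn, n_model = length(model_feats),
                                   n_matched = length(matched))
    if (length(matched)) {
      Wk[[vn]] <- t(fit$W[[vn]][matched, , drop = FALSE])
      Yk[[vn]] <- tgt$values[, matched, drop = FALSE]
    }
  }
  if (!length(Wk)) abort("no features matched in any whitelisted view")
  W_matched <- do.call(cbind, Wk)
  Y_target <- do.call(cbind, Yk)
  structure(list(W_matched = W_matched, Y_target = Y_target,
                 report = dplyr::bind_rows(report)),
            class = "projection_input")
}

#' Project samples onto existing factors via the right inverse
#'
#' Computes `Z = Y W' (W W')^{-1}`, the right-inverse projection of target
#' samples onto the factors defined by a K x D weight matrix restricted to
#' matched features. If `Y = Z0 W` exactly, the projection returns `Z0`.
#'
#' @param input A `projection_input` from [match_features()], or a sample x D
#'   matrix `Y` when `W` is given.
#' @param W Optional K x D weight matrix (when `input` is a plain matrix).
#' @param max_condition Condition-number guard on `W W'` (default 1e10).
#' @return Sample x K matrix of projected factor scores.
#' @export
project_factors <- function(input, W = NULL, max_condition = 1e10) {
  if (inherits(input, "projection_input")) {
    Y <- input$Y_target
    W <- input$W_matched
  } else {
    Y <- as.matrix(input)
    if (is.null(W)) abort("`W` is required when `input` is a matrix")
  }
  if (ncol(Y) != ncol(W)) abort("feature dimension of Y and W differ")
  if (anyNA(Y)) {
    abort("Y contains missing values; complete rows are required for projection")
  }
  G <- tcrossprod(W)
  cond <- kappa(G, exact = TRUE)
  if (!is.finite(cond) || cond > max_condition) {
    abort(sprintf(paste0("W W' is ill-conditioned (condition number %.3g); ",
                         "review the feature matching"), cond))
  }
  Z <- Y %*% t(W) %*% solve(G)
  colnames(Z) <- rownames(W)
  Z
}

#' Summarize a factor trajectory over timepoints
#'
#' Per (group, timepoint): mean and standard error of the factor scores,
#' optionally sign-aligned to a reference cohort by correlating per-timepoint
#' means and flipping when the correlation is negative.
#'
#' @param Z Sample x K score matrix with sample ids as rownames.
#' @param meta Sample metadata covering the rows of `Z`.
#' @param factor Factor index or column name.
#' @param reference Optional reference summary (the source cohort's output of
#'   this function) used for sign alignment on shared timepoints.
#' @return Tibble `group`, `timepoint`, `n`, `mean`, `sem` (NA when a cell
#'   has a single sample) with attribute `flipped`.
#' @export
summarize_trajectory <- function(Z, meta, factor, reference = NULL) {
  k <- if (is.character(factor)) factor else colnames(Z)[factor] %||% factor
  scores <- tibble::tibble(sample_id = rownames(Z),
                           score = Z[, k])
  df <- dplyr::inner_join(scores, meta, by = "sample_id")
  flipped <- FALSE
  if (!is.null(reference)) {
    ref_means <- reference |>
      dplyr::group_by(.data$timepoint) |>
      dplyr::summarise(ref = mean(.data$mean), .groups = "drop")
    own <- df |>
      dplyr::group_by(.data$timepoint) |>
      dplyr::summarise(own = mean(.data$score), .groups = "drop") |>
      dplyr::inner_join(ref_means, by = "timepoint")
    if (nrow(own) >= 2 && cor(own$own, own$ref) < 0) {
      df$score <- -df$score
      flipped <- TRUE
    }
  }
  out <- df |>
    dplyr::group_by(.data$group, .data$timepoint) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$score),
                     sem = ifelse(dplyr::n() > 1, sd(.data$score) / sqrt(dplyr::n()), NA_real_),
                     .groups = "drop")
  attr(out, "flipped") <- flipped
  out
}
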