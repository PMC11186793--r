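# broom-style tidiers and ggplot2 methods for the fitted objects.

#' Tidy a fitted group factor model
#'
#' One row per (view, feature, factor) weight, or per (sample, factor) score
#' with `what = "scores"`.
#'
#' @param x An `ifa_gfa`.
#' @param what `"weights"` (default) or `"scores"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ifa_gfa <- function(x, what = c("weights", "scores"), ...) {
  what <- match.arg(what)
  if (what == "scores") {
    return(tibble::as_tibble(x$Z, rownames = "sample_id") |>
             tidyr::pivot_longer(-"sample_id", names_to = "factor",
                                 values_to = "score"))
  }
  purrr::map_dfr(names(x$W), function(vn) {
    tibble::as_tibble(x$W[[vn]], rownames = "feature") |>
      tidyr::pivot_longer(-"feature", names_to = "factor", values_to = "weight") |>
      dplyr::mutate(view = vn, gene = feature_gene(.data$feature), .before = 1)
  })
}

#' Glance at a fitted group factor model
#'
#' @param x An `ifa_gfa`.
#' @param ... Unused.
#' @return One-row tibble: factors, samples, views, iterations, final ELBO,
#'   convergence flag.
#' @export
glance.ifa_gfa <- function(x, ...) {
  tibble::tibble(K = x$K, n_samples = nrow(x$Z), n_views = length(x$W),
                 n_iter = x$n_iter, elbo = x$trace$elbo[x$n_iter],
                 converged = x$converged)
}

#' Tidy a variance decomposition
#' @param x An `ifa_variance`.
#' @param ... Unused.
#' @export
tidy.ifa_variance <- function(x, ...) x$by_factor

#' @rdname tidy.ifa_variance
#' @export
glance.ifa_variance <- function(x, ...) {
  tidyr::pivot_wider(x$totals, names_from = "view", values_from = "r2_total")
}

#' Tidy a penalized or plain logistic fit
#' @param x An `ifa_lasso` or `ifa_logistic`.
#' @param ... Unused.
#' @export
tidy.ifa_lasso <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.ifa_lasso
#' @export
glance.ifa_lasso <- function(x, ...) {
  i <- match(x$lambda_min, x$lambda_path)
  tibble::tibble(lambda_min = x$lambda_min,
                 cv_deviance_min = x$cv_deviance$cvm[i],
                 n_nonzero = sum(x$coefficients[-1] != 0))
}

#' @rdname tidy.ifa_lasso
#' @export
tidy.ifa_logistic <- function(x, ...) {
  s <- summary(x$glm)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
                 statistic = s[, 3], p_value = s[, 4])
}

#' Tidy an ROC result
#' @param x An `ifa_roc`.
#' @param ... Unused.
#' @export
tidy.ifa_roc <- function(x, ...) x$curve

#' @rdname tidy.ifa_roc
#' @export
glance.ifa_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' broom-style generics
#'
#' Generic `tidy()` / `glance()` verbs for this package's fitted objects.
#'
#' @param x A fitted object.
#' @param ... Passed to methods.
#' @name tidy
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Variance-decomposition heatmap
#'
#' The field's standard overview: per (factor, view) fraction of explained
#' variance as a shaded grid, with the per-view totals in the subtitle.
#'
#' @param object An `ifa_variance`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ifa_variance
#' @export
autoplot.ifa_variance <- function(object, ...) {
  df <- object$by_factor
  df$factor <- factor(df$factor, levels = rev(unique(df$factor)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$view, y = .data$factor,
                                   fill = pmax(.data$r2, 0))) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10",
                                 name = "variance\nexplained") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Factor trajectory plot
#'
#' Mean factor score with standard-error ribbons per group over timepoints,
#' from a [summarize_trajectory()] table.
#'
#' @param summary Output of [summarize_trajectory()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$timepoint, y = .data$mean,
                                        group = .data$group, color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::labs(x = "timepoint", y = "factor score (mean ± SEM)") +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param object An `ifa_roc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ifa_roc
#' @export
autoplot.ifa_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(linetype = 2, color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
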