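# Outcome labeling from ejection-fraction change, ROC evaluation, and
# factor-/feature-based outcome classifiers (cross-validated lasso logistic
# regression and a reduced-feature logistic model).

#' Outcome rule from ejection-fraction change
#'
#' The change in left-ventricular ejection fraction over the hospital stay
#' (delta EF) defines outcome: positive change is a good outcome, negative a
#' poor one. Cohorts differ in how a stable (zero) change is classed, so the
#' rule must declare it explicitly: the Munich convention counts stable as
#' good, the Groningen convention as poor.
#'
#' @param stable_is `"good"` or `"poor"`.
#' @return An `outcome_rule`.
#' @export
outcome_rule <- function(stable_is = c("good", "poor")) {
  structure(list(stable_is = match.arg(stable_is)), class = "outcome_rule")
}

#' @rdname outcome_rule
#' @export
munich_rule <- function() outcome_rule("good")

#' @rdname outcome_rule
#' @export
groningen_rule <- function() outcome_rule("poor")

#' Label sample outcomes
#'
#' @param meta Sample metadata with a `delta_EF` column.
#' @param rule An [outcome_rule()].
#' @return `meta` with an `outcome` column in `{good, poor, unknown}`
#'   (`unknown` where `delta_EF` is absent).
#' @export
label_outcome <- function(meta, rule) {
  stopifnot(inherits(rule, "outcome_rule"))
  out <- dplyr::case_when(
    is.na(meta$delta_EF) ~ "unknown",
    meta$delta_EF > 0 ~ "good",
    meta$delta_EF < 0 ~ "poor",
    TRUE ~ rule$stable_is)
  dplyr::mutate(meta, outcome = out)
}

#' Min-max scaling to the unit interval
#'
#' `(x - min) / (max - min)`; constant input maps to 0.5 with a warning.
#' Because the scaling is strictly monotone it leaves any subsequent ROC
#' analysis unchanged.
#'
#' @param values Numeric vector.
#' @return Scaled vector in `[0, 1]`.
#' @export
minmax_scale <- function(values) {
  rng <- range(values, na.rm = TRUE)
  if (diff(rng) == 0) {
    warn("constant input to minmax_scale; returning 0.5")
    return(rep(0.5, length(values)))
  }
  (values - rng[1]) / diff(rng)
}

#' ROC curve and AUC
#'
#' AUC computed by the rank statistic
#' `P(score_pos > score_neg) + 0.5 P(tie)` (the normalized Mann-Whitney U);
#' the curve enumerates all distinct thresholds.
#'
#' @param scores Numeric classifier scores, higher = more positive.
#' @param labels Binary labels (logical, 0/1, or the positive level given by
#'   `positive`).
#' @param positive Value of `labels` treated as the positive class when
#'   `labels` is not logical/numeric.
#' @return An `ifa_roc`: list with `auc` and `curve`
#'   (tibble `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    positive <- positive %||% sort(unique(labels))[1]
    y <- labels == positive
  } else {
    y <- as.logical(labels)
  }
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- avg_rank(scores)
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- purrr::map_dfr(thr, function(t) {
    tibble::tibble(threshold = t,
                   fpr = sum(scores[!y] >= t) / n0,
                   tpr = sum(scores[y] >= t) / n1)
  })
  structure(list(auc = auc, curve = curve, n_pos = n1, n_neg = n0),
            class = "ifa_roc")
}

#' @export
print.ifa_roc <- function(x, ...) {
  cat(sprintf("<ifa_roc> AUC = %.3f (%d positive vs %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

# deterministic stratified fold assignment
make_folds <- function(y, n_folds, seed, stratified = TRUE) {
  foldid <- integer(length(y))
  withr::with_seed(seed, {
    if (stratified) {
      for (cl in unique(y)) {
        idx <- which(y == cl)
        foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
    } else {
      foldid <- sample(rep_len(seq_len(n_folds), length(y)))
    }
  })
  foldid
}

#' Cross-validated lasso logistic regression
#'
#' L1-penalized logistic regression over a 100-value log-spaced lambda path
#' from the smallest lambda zeroing all coefficients down to 1e-4 of it, with
#' deterministic (by default class-stratified) fold assignment.
#' `lambda_min` minimizes the mean cross-validated binomial deviance; the
#' returned coefficients are the path fit at `lambda_min` on all data, on
#' the original feature scale.
#'
#' @param X Sample x feature numeric matrix.
#' @param y Binary outcome (two levels).
#' @param n_folds Number of CV folds (default 8).
#' @param seed Integer seed controlling fold assignment.
#' @param stratified Stratify folds by class (default TRUE); set FALSE for
#'   plain random folds.
#' @param type_measure `"deviance"` (default) or `"class"`.
#' @return An `ifa_lasso`: `coefficients` (named, incl. `(Intercept)`),
#'   `lambda_path`, `lambda_min`, `cv_deviance` tibble, `foldid`, underlying
#'   `glmnet` objects.
#' @export
fit_lasso_logistic <- function(X, y, n_folds = 8, seed = 1L, stratified = TRUE,
                               type_measure = c("deviance", "class")) {
  type_measure <- match.arg(type_measure)
  X <- as.matrix(X)
  yf <- as.factor(y)
  if (nlevels(yf) != 2) abort("`y` must have exactly two classes")
  if (nrow(X) < n_folds) abort("need at least as many samples as folds")
  foldid <- make_folds(as.integer(yf), n_folds, seed)
  cv <- glmnet::cv.glmnet(X, yf, family = "binomial", alpha = 1,
                          foldid = foldid, nlambda = 100,
                          lambda.min.ratio = 1e-4,
                          type.measure = type_measure, standardize = TRUE)
  co <- as.matrix(coef(cv, s = "lambda.min"))[, 1]
  structure(list(coefficients = co, lambda_path = cv$lambda,
                 lambda_min = cv$lambda.min,
                 cv_deviance = tibble::tibble(lambda = cv$lambda, cvm = cv$cvm,
                                              cvsd = cv$cvsd),
                 foldid = foldid, glmnet_cv = cv, levels = levels(yf),
                 seed = seed),
            class = "ifa_lasso")
}

#' @export
print.ifa_lasso <- function(x, ...) {
  nz <- sum(x$coefficients[-1] != 0)
  cat(sprintf("<ifa_lasso> lambda_min = %.4g, %d/%d non-zero coefficients\n",
              x$lambda_min, nz, length(x$coefficients) - 1))
  invisible(x)
}

#' Predict with a lasso or logistic model
#'
#' @param object Fitted `ifa_lasso` or `ifa_logistic`.
#' @param newdata Sample x feature matrix with the training columns.
#' @param ... Unused.
#' @return Numeric vector of predicted probabilities of the second class
#'   level.
#' @export
predict.ifa_lasso <- function(object, newdata, ...) {
  drop(predict(object$glmnet_cv, newx = as.matrix(newdata), s = "lambda.min",
               type = "response"))
}

#' Unpenalized logistic regression
#'
#' Maximum likelihood via iteratively reweighted least squares (tolerance
#' 1e-8). Perfect separation — detected by fitted probabilities collapsing
#' to 0/1 or diverging coefficients — is an error rather than a silently
#' unstable fit.
#'
#' @param X Sample x feature matrix (or data frame).
#' @param y Binary outcome.
#' @return An `ifa_logistic` with `coefficients` and the underlying `glm`.
#' @export
fit_logistic <- function(X, y) {
  df <- as.data.frame(X)
  yf <- as.factor(y)
  if (nlevels(yf) != 2) abort("`y` must have exactly two classes")
  df$.y <- as.integer(yf) - 1L
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep_warned || !fit$converged || any(abs(coef(fit)) > 1e8, na.rm = TRUE)) {
    abort("perfect separation detected; the logistic MLE does not exist")
  }
  structure(list(coefficients = coef(fit), glm = fit, levels = levels(yf)),
            class = "ifa_logistic")
}

#' @export
#' @rdname fit_logistic
#' @param object Fitted `ifa_logistic`.
#' @param newdata Data with the training feature columns.
#' @param ... Unused.
predict.ifa_logistic <- function(object, newdata, ...) {
  unname(predict(object$glm, newdata = as.data.frame(newdata), type = "response"))
}

#' Intersection of two rankings' top-n features
#'
#' @param rankA,rankB Ranked feature tibbles (from [rank_features()]) or
#'   named weight vectors; ranking is by absolute weight.
#' @param n Depth of each list (default 280).
#' @return Character vector of features in both top-n lists.
#' @export
select_top_intersection <- function(rankA, rankB, n = 280) {
  top_of <- function(r) {
    if (is.numeric(r) && !is.null(names(r))) {
      names(r)[order(-abs(r))][seq_len(min(n, length(r)))]
    } else {
      r$feature[order(-abs(r$weight))][seq_len(min(n, nrow(r)))]
    }
  }
  intersect(top_of(rankA), top_of(rankB))
}
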