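# Gaussian group factor model with automatic relevance determination (ARD),
# fitted by expectation-maximization with per-view missing-sample masks.
#
# Model, per view m and sample n:
#   y_mn = W_m z_n + eps_mn,  eps_mn ~ N(0, tau_m^{-1} I),  z_n ~ N(0, I_K),
#   column k of W_m ~ N(0, alpha_mk^{-1} I_Dm)   (ARD prior).
# The E-step computes the exact Gaussian posterior of z_n given the views
# present for that sample; the M-step updates W, tau and alpha in closed
# form. The trace records the evidence lower bound, which is non-decreasing.

new_gfa_fit <- function(Z, W, tau, alpha, trace, K, n_iter, converged) {
  structure(list(Z = Z, W = W, tau = tau, alpha = alpha, trace = trace,
                 K = K, n_iter = n_iter, converged = converged),
            class = "ifa_gfa")
}

#' @export
print.ifa_gfa <- function(x, ...) {
  cat(sprintf("<ifa_gfa> K = %d factors, %d samples, %d views; %d iterations (%s)\n",
              x$K, nrow(x$Z), length(x$W), x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Fit the group factor model
#'
#' @param dataset An `ifa_dataset` whose views have been inverse-normal
#'   transformed (see [preprocess_cohort()] / [inverse_normal_transform()]).
#' @param K Number of factors. Must not exceed the sample count or any view's
#'   feature count; superfluous factors are shrunk by the ARD prior rather
#'   than removed.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative change of the evidence lower bound below which the fit
#'   stops.
#' @param seed Unused: initialization is deterministic (singular vectors of
#'   the concatenated per-view-scaled data), so the fit is reproducible
#'   without a seed. Accepted for interface stability.
#' @return An `ifa_gfa` fit: `Z` (sample x K posterior factor scores), `W`
#'   (per view, feature x K weights), `tau` (per-view noise precision),
#'   `alpha` (view x factor ARD precision), `trace` (ELBO per iteration).
#'   Factors are ordered by decreasing total explained sum of squares and
#'   signed so each factor's largest-magnitude weight is positive.
#' @export
fit_gfa <- function(dataset, K = 20, max_iter = 50000, tol = 1e-6, seed = NULL) {
  stopifnot(inherits(dataset, "ifa_dataset"))
  views <- dataset$views
  N <- nrow(dataset$meta)
  M <- length(views)
  view_names <- names(views)
  Y <- lapply(views, function(v) v$values[v$mask[v$sample_ids], , drop = FALSE])
  rows <- lapply(views, function(v) which(v$mask[v$sample_ids]))
  D <- vapply(Y, ncol, integer(1))
  for (m in seq_len(M)) {
    if (any(!is.finite(Y[[m]]))) {
      abort(sprintf("view '%s' contains non-finite values; run the view recipes first",
                    view_names[m]))
    }
  }
  if (K > N || any(K > D)) {
    abort(sprintf("K = %d exceeds the sample count (%d) or a view's feature count (min %d)",
                  K, N, min(D)))
  }

  # deterministic initialization: SVD of the concatenated per-view-scaled
  # data, absent rows as zero (the prior mean)
  X <- matrix(0, N, sum(D))
  off <- 0
  for (m in seq_len(M)) {
    X[rows[[m]], off + seq_len(D[m])] <- Y[[m]] / sqrt(D[m])
    off <- off + D[m]
  }
  sv <- svd(X, nu = K, nv = 0)
  U <- sv$u
  flip <- apply(U, 2, function(u) sign(u[which.max(abs(u))]))
  Z0 <- sweep(U, 2, flip, `*`) * sqrt(N)

  W <- vector("list", M); names(W) <- view_names
  for (m in seq_len(M)) {
    Zm <- Z0[rows[[m]], , drop = FALSE]
    W[[m]] <- t(solve(crossprod(Zm) + diag(K), crossprod(Zm, Y[[m]])))
  }
  tau <- setNames(rep(1, M), view_names)
  alpha <- matrix(1, M, K, dimnames = list(view_names, NULL))
  alpha_max <- 1e6
  YtY <- vapply(Y, function(y) sum(y^2), numeric(1))
  Nm <- vapply(rows, length, numeric(1))

  # per-sample view-presence patterns
  P <- matrix(FALSE, N, M)
  for (m in seq_len(M)) P[rows[[m]], m] <- TRUE
  pat_key <- apply(P, 1, function(p) paste(as.integer(p), collapse = ""))
  pat_groups <- split(seq_len(N), pat_key)

  elbo_trace <- numeric(0)
  elbo_prev <- -Inf
  converged <- FALSE
  mu <- matrix(0, N, K)
  const_ln2pi <- log(2 * pi)

  for (iter in seq_len(max_iter)) {
    CW <- lapply(seq_len(M), function(m) tau[m] * crossprod(W[[m]]))
    B <- matrix(0, N, K)
    for (m in seq_len(M)) {
      B[rows[[m]], ] <- B[rows[[m]], ] + tau[m] * (Y[[m]] %*% W[[m]])
    }
    Sigma <- list(); logdetS <- numeric(length(pat_groups)); trS <- numeric(length(pat_groups))
    names(logdetS) <- names(pat_groups)
    for (g in seq_along(pat_groups)) {
      key <- names(pat_groups)[g]
      in_p <- which(strsplit(key, "")[[1]] == "1")
      Lam <- diag(K)
      for (m in in_p) Lam <- Lam + CW[[m]]
      R <- chol(Lam)
      Sg <- chol2inv(R)
      Sigma[[key]] <- Sg
      logdetS[key] <- -2 * sum(log(diag(R)))
      idx <- pat_groups[[g]]
      mu[idx, ] <- B[idx, , drop = FALSE] %*% Sg
    }

    # sufficient statistics per view
    S <- vector("list", M); A <- vector("list", M)
    for (m in seq_len(M)) {
      Mm <- mu[rows[[m]], , drop = FALSE]
      Sm <- crossprod(Mm)
      for (key in names(pat_groups)) {
        # a pattern either contains view m for all its samples or for none
        if (substr(key, m, m) == "1") Sm <- Sm + length(pat_groups[[key]]) * Sigma[[key]]
      }
      S[[m]] <- Sm
      A[[m]] <- crossprod(Y[[m]], Mm)
    }

    # ELBO at (q_t, theta_{t-1}); non-decreasing across iterations
    elbo <- 0
    for (m in seq_len(M)) {
      resid <- YtY[m] - 2 * sum(A[[m]] * W[[m]]) + sum((W[[m]] %*% S[[m]]) * W[[m]])
      elbo <- elbo + Nm[m] * D[m] / 2 * (log(tau[m]) - const_ln2pi) - tau[m] / 2 * resid
      wss <- colSums(W[[m]]^2)
      elbo <- elbo + sum(D[m] / 2 * (log(alpha[m, ]) - const_ln2pi) - alpha[m, ] / 2 * wss)
    }
    ez2 <- sum(mu^2)
    for (key in names(pat_groups)) {
      cnt <- length(pat_groups[[key]])
      ez2 <- ez2 + cnt * sum(diag(Sigma[[key]]))
      elbo <- elbo + cnt * (K / 2 * (1 + const_ln2pi) + logdetS[key] / 2)
    }
    elbo <- elbo - N * K / 2 * const_ln2pi - ez2 / 2
    elbo_trace[iter] <- elbo
    if (is.finite(elbo_prev) &&
        abs(elbo - elbo_prev) < tol * abs(elbo)) {
      converged <- TRUE
      break
    }
    elbo_prev <- elbo

    # M-step
    for (m in seq_len(M)) {
      W[[m]] <- t(solve(S[[m]] + diag(alpha[m, ] / tau[m], K), t(A[[m]])))
      resid <- YtY[m] - 2 * sum(A[[m]] * W[[m]]) + sum((W[[m]] %*% S[[m]]) * W[[m]])
      tau[m] <- Nm[m] * D[m] / max(resid, 1e-12)
      alpha[m, ] <- pmin(alpha_max, D[m] / pmax(colSums(W[[m]]^2), 1e-12))
    }
  }

  if (!converged) {
    # refresh the posterior scores so Z matches the final parameters
    CW <- lapply(seq_len(M), function(m) tau[m] * crossprod(W[[m]]))
    B <- matrix(0, N, K)
    for (m in seq_len(M)) {
      B[rows[[m]], ] <- B[rows[[m]], ] + tau[m] * (Y[[m]] %*% W[[m]])
    }
    for (key in names(pat_groups)) {
      in_p <- which(strsplit(key, "")[[1]] == "1")
      Lam <- diag(K)
      for (m in in_p) Lam <- Lam + CW[[m]]
      idx <- pat_groups[[key]]
      Sg <- chol2inv(chol(Lam))
      Sigma[[key]] <- Sg
      mu[idx, ] <- B[idx, , drop = FALSE] %*% Sg
    }
    S <- vector("list", M); A <- vector("list", M)
    for (m in seq_len(M)) {
      Mm <- mu[rows[[m]], , drop = FALSE]
      Sm <- crossprod(Mm)
      for (key in names(pat_groups)) {
        if (substr(key, m, m) == "1") Sm <- Sm + length(pat_groups[[key]]) * Sigma[[key]]
      }
      S[[m]] <- Sm
      A[[m]] <- crossprod(Y[[m]], Mm)
    }
  }

  # order factors by total explained sum of squares; sign so the pooled
  # largest-|weight| feature is positive
  expl <- numeric(K)
  for (m in seq_len(M)) {
    wss <- colSums(W[[m]]^2)
    expl <- expl + 2 * colSums(A[[m]] * W[[m]]) - diag(S[[m]]) * wss
  }
  ord <- order(expl, decreasing = TRUE)
  mu <- mu[, ord, drop = FALSE]
  W <- lapply(W, function(w) w[, ord, drop = FALSE])
  alpha <- alpha[, ord, drop = FALSE]
  all_w <- do.call(rbind, W)
  for (k in seq_len(K)) {
    j <- which.max(abs(all_w[, k]))
    if (all_w[j, k] < 0) {
      mu[, k] <- -mu[, k]
      W <- lapply(W, function(w) { w[, k] <- -w[, k]; w })
      all_w[, k] <- -all_w[, k]
    }
  }
  dimnames(mu) <- list(dataset$meta$sample_id, paste0("F", seq_len(K)))
  W <- lapply(W, function(w) { colnames(w) <- paste0("F", seq_len(K)); w })
  for (m in seq_len(M)) rownames(W[[m]]) <- colnames(Y[[m]])
  colnames(alpha) <- paste0("F", seq_len(K))

  new_gfa_fit(Z = mu, W = W, tau = tau, alpha = alpha,
              trace = tibble::tibble(iter = seq_along(elbo_trace), elbo = elbo_trace),
              K = K, n_iter = length(elbo_trace), converged = converged)
}

#' Variance decomposition of a fitted factor model
#'
#' Per (factor, view): `1 - sum((y - z_k w_k')^2) / sum(y^2)` over the view's
#' present entries, i.e. the fraction of the view's (uncentered) sum of
#' squares explained by that factor alone; per view additionally the total
#' fraction using the full reconstruction. Uncentered denominators are
#' appropriate because inputs are inverse-normal transformed (mean ~ 0).
#'
#' @param fit An `ifa_gfa`.
#' @param dataset The dataset the model was fitted to.
#' @return An `ifa_variance` object: `by_factor` tibble
#'   (`factor`, `view`, `r2`) and `totals` tibble (`view`, `r2_total`).
#' @export
variance_explained <- function(fit, dataset) {
  views <- dataset$views
  by_factor <- purrr::map_dfr(names(views), function(vn) {
    v <- views[[vn]]
    present <- v$mask[v$sample_ids]
    Ym <- v$values[present, , drop = FALSE]
    Zm <- fit$Z[rownames(Ym), , drop = FALSE]
    Wm <- fit$W[[vn]]
    ss <- sum(Ym^2)
    r2 <- vapply(seq_len(fit$K), function(k) {
      1 - sum((Ym - tcrossprod(Zm[, k], Wm[, k]))^2) / ss
    }, numeric(1))
    tibble::tibble(factor = colnames(fit$Z), view = vn, r2 = r2)
  })
  totals <- purrr::map_dfr(names(views), function(vn) {
    v <- views[[vn]]
    present <- v$mask[v$sample_ids]
    Ym <- v$values[present, , drop = FALSE]
    Zm <- fit$Z[rownames(Ym), , drop = FALSE]
    recon <- Zm %*% t(fit$W[[vn]])
    tibble::tibble(view = vn, r2_total = 1 - sum((Ym - recon)^2) / sum(Ym^2))
  })
  structure(list(by_factor = by_factor, totals = totals), class = "ifa_variance")
}

#' @export
print.ifa_variance <- function(x, ...) {
  cat("<ifa_variance> fraction of view variance explained\n")
  wide <- tidyr::pivot_wider(x$by_factor, names_from = "factor", values_from = "r2")
  print(as.data.frame(wide), digits = 3)
  invisible(x)
}

#' Rank features by factor weight
#'
#' Features from all views are pooled and ranked by the magnitude of their
#' weight on one factor; the top `ceiling(fraction * total)` are returned
#' with signed weights. Per-view counts (absolute and relative to the view's
#' feature number) are attached as the `view_counts` attribute.
#'
#' @param fit An `ifa_gfa`.
#' @param factor Factor index or name (e.g. `"F2"`).
#' @param fraction Fraction of all features to return, in (0, 1].
#' @return Tibble `feature`, `view`, `gene`, `weight`, `rank`.
#' @export
rank_features <- function(fit, factor, fraction = 0.01) {
  if (!(is.numeric(fraction) && fraction > 0 && fraction <= 1)) {
    abort("`fraction` must be in (0, 1]")
  }
  k <- if (is.character(factor)) match(factor, colnames(fit$Z)) else as.integer(factor)
  w <- unlist(lapply(fit$W, function(wm) wm[, k]))
  feats <- unlist(lapply(fit$W, rownames))
  names(w) <- feats
  n_top <- ceiling(fraction * length(w))
  ord <- order(-abs(w))
  top <- ord[seq_len(n_top)]
  out <- tibble::tibble(feature = feats[top], view = feature_view(feats[top]),
                        gene = feature_gene(feats[top]), weight = unname(w[top]),
                        rank = seq_len(n_top))
  counts <- out |>
    dplyr::count(.data$view, name = "n_top") |>
    dplyr::left_join(tibble::tibble(view = names(fit$W),
                                    n_view = vapply(fit$W, nrow, integer(1))),
                     by = "view") |>
    dplyr::mutate(relative = .data$n_top / .data$n_view)
  attr(out, "view_counts") <- counts
  out
}

#' Per-feature effect of a two-group contrast
#'
#' Ordinary least-squares slope of each feature on a 0/1 group indicator —
#' identically the difference of group means — with its standard error, as
#' used to score treatment effects in perturbation experiments.
#'
#' @param values Sample x feature numeric matrix (or data frame).
#' @param labels Two-level factor/character vector along the samples; the
#'   slope is `mean(level2) - mean(level1)` with levels in sort order.
#' @return Tibble `feature`, `estimate`, `se`.
#' @export
group_effect_size <- function(values, labels) {
  values <- as.matrix(values)
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2) abort("`labels` must have exactly two levels")
  g1 <- values[labels == lev[2], , drop = FALSE]
  g0 <- values[labels == lev[1], , drop = FALSE]
  if (nrow(g0) < 2 || nrow(g1) < 2) abort("each group needs at least 2 samples")
  est <- colMeans(g1) - colMeans(g0)
  ss <- colSums(sweep(g0, 2, colMeans(g0))^2) + colSums(sweep(g1, 2, colMeans(g1))^2)
  s2 <- ss / (nrow(g0) + nrow(g1) - 2)
  se <- sqrt(s2 * (1 / nrow(g0) + 1 / nrow(g1)))
  tibble::tibble(feature = colnames(values) %||% as.character(seq_along(est)),
                 estimate = unname(est), se = unname(se))
}
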