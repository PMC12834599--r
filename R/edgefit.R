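#' Edgewise ordinary least squares across all edges
#'
#' Fits the marginal model independently at every edge by OLS:
#' \eqn{\hat\beta = (X'X)^{-1} X' y_e} for each column \eqn{y_e} of `Y`,
#' solved once for all edges via the shared Gram matrix.
#'
#' @param Y numeric matrix, subjects x edges (Fisher-Z connectivity).
#' @param X numeric design matrix, subjects x p (or a `"design_matrix"`).
#' @return list: `beta` (p x edges), `residuals` (subjects x edges),
#'   `XtX_inv` (p x p).
#' @export
fit_marginal <- function(Y, X) {
  if (inherits(X, "design_matrix")) X <- X$X
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop_nla("nla_bad_design", "rows of Y must align with X")
  if (nrow(X) <= ncol(X)) {
    stop_nla("nla_bad_design", "need more subjects than design columns")
  }
  C <- chol2inv(chol(crossprod(X)))
  beta <- C %*% crossprod(X, Y)
  list(beta = beta, residuals = Y - X %*% beta, XtX_inv = C)
}

#' Cluster-robust (Huber-White sandwich) standard errors
#'
#' Corrects the OLS standard errors for non-exchangeability of residuals
#' within clusters (e.g. acquisition site, family):
#' \deqn{V = (X'X)^{-1} \Big[\sum_g X_g' e_g e_g' X_g\Big] (X'X)^{-1}}
#' summed over clusters \eqn{g}. `small_sample = "CR0"` is the plain
#' estimator; `"CR1"` scales \eqn{V} by \eqn{G/(G-1)\cdot(n-1)/(n-p)}.
#' With singleton clusters CR0 reduces to the heteroskedasticity-robust
#' HC0 estimator.
#'
#' @param X design matrix (subjects x p) or `"design_matrix"`.
#' @param residuals subjects x edges residual matrix from [fit_marginal()].
#' @param cluster_ids one cluster label per subject.
#' @param small_sample `"CR0"` (default) or `"CR1"`.
#' @param coef_index coefficients to compute SEs for (default all).
#' @return matrix `length(coef_index)` x edges of standard errors.
#' @export
cluster_robust_se <- function(X, residuals, cluster_ids,
                              small_sample = c("CR0", "CR1"),
                              coef_index = NULL) {
  small_sample <- match.arg(small_sample)
  if (inherits(X, "design_matrix")) {
    if (is.null(cluster_ids)) cluster_ids <- X$cluster_ids
    X <- X$X
  }
  residuals <- as.matrix(residuals)
  n <- nrow(X); p <- ncol(X)
  stopifnot(nrow(residuals) == n, length(cluster_ids) == n)
  g <- factor(cluster_ids)
  G <- nlevels(g)
  if (G < 2L) stop_nla("nla_single_cluster",
                       "cluster-robust variance needs at least two clusters")
  if (is.null(coef_index)) coef_index <- seq_len(p)
  C <- chol2inv(chol(crossprod(X)))
  fac <- if (small_sample == "CR1") G / (G - 1) * (n - 1) / (n - p) else 1
  se <- matrix(NA_real_, length(coef_index), ncol(residuals))
  for (k in seq_along(coef_index)) {
    j <- coef_index[k]
    w <- as.numeric(X %*% C[, j])
    S <- rowsum(w * residuals, g)          # G x edges cluster scores
    se[k, ] <- sqrt(fac * colSums(S^2))
  }
  rownames(se) <- colnames(X)[coef_index]
  se
}

#' Wild cluster bootstrap null distribution of edgewise t-values
#'
#' Generates the null distribution of the cluster-robust t-statistic for
#' the predictor of interest by the restricted (null-imposed) wild
#' cluster bootstrap with Rademacher weights: the model is refit with the
#' interest column removed, and each bootstrap outcome is the restricted
#' fit plus the restricted residuals flipped by a random sign \eqn{v_g \in
#' \{-1,+1\}} drawn once per cluster. The full model is then refit and the
#' cluster-robust t-value of the interest coefficient recorded. Crucially,
#' the same cluster signs are shared by every edge within a replicate, so
#' the null preserves the dependence between edges that downstream
#' step-down (maxT) corrections rely on.
#'
#' The refits are carried out in closed form (the bootstrap t for all
#' replicates and edges reduces to products of per-cluster score matrices
#' with the Rademacher sign matrix), which is algebraically identical to
#' refitting on each bootstrap outcome.
#'
#' @inheritParams fit_marginal
#' @param design a `"design_matrix"` from [build_design()], or a plain
#'   matrix together with `interest_index` and `cluster_ids`.
#' @param interest_index column of the coefficient under test.
#' @param cluster_ids per-subject cluster labels.
#' @param B number of bootstrap replicates (the headline analyses use
#'   2,000).
#' @param seed RNG seed for the Rademacher draws.
#' @param small_sample as in [cluster_robust_se()].
#' @param weights optional B x G matrix of +/-1 sign weights overriding
#'   the Rademacher draws (columns in `sort(unique(cluster_ids))` order);
#'   intended for tests.
#' @return list of class `"wild_null"`: `null_t` (B x edges), `B`, `seed`.
#' @export
wild_bootstrap_null <- function(Y, design, interest_index = NULL,
                                cluster_ids = NULL, B = 2000, seed = 1,
                                small_sample = c("CR0", "CR1"),
                                weights = NULL) {
  small_sample <- match.arg(small_sample)
  if (inherits(design, "design_matrix")) {
    X <- design$X
    interest_index <- interest_index %||% design$interest_index
    cluster_ids <- cluster_ids %||% design$cluster_ids
  } else {
    X <- as.matrix(design)
    if (is.null(interest_index) || is.null(cluster_ids)) {
      stop_nla("nla_bad_design",
               "interest_index and cluster_ids required with a plain matrix")
    }
  }
  if (B < 1) stop_nla("nla_bad_arg", "B must be at least 1")
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); E <- ncol(Y)
  j <- interest_index
  g <- factor(cluster_ids)
  G <- nlevels(g)
  if (G < 2L) stop_nla("nla_single_cluster", "need at least two clusters")

  Xr <- X[, -j, drop = FALSE]
  if (qr(Xr)$rank < ncol(Xr)) {
    stop_nla("nla_rank_deficient", "restricted (null) model is rank deficient")
  }
  Cr <- chol2inv(chol(crossprod(Xr)))
  Er <- Y - Xr %*% (Cr %*% crossprod(Xr, Y))   # restricted residuals

  C <- chol2inv(chol(crossprod(X)))
  w0 <- as.numeric(X %*% C[, j])
  S0 <- rowsum(w0 * Er, g)                      # G x E cluster scores
  # per-cluster cross products X_g' E_g, laid out G x (p*E) with p fastest
  Tarr <- array(NA_real_, c(G, p, E))
  for (l in seq_len(p)) Tarr[, l, ] <- rowsum(X[, l] * Er, g)
  Tmat <- matrix(Tarr, G, p * E)
  Q <- matrix(NA_real_, G, p)
  for (l in seq_len(p)) Q[, l] <- rowsum(X[, l] * w0, g)
  QC <- Q %*% C

  if (is.null(weights)) {
    V <- with_seed(seed, matrix(sample(c(-1, 1), B * G, replace = TRUE), B, G))
  } else {
    V <- as.matrix(weights)
    if (ncol(V) != G || nrow(V) != B) {
      stop_nla("nla_bad_arg", "weights must be B x n_clusters")
    }
  }
  fac <- if (small_sample == "CR1") G / (G - 1) * (n - 1) / (n - p) else 1

  Num <- V %*% S0                               # bootstrap beta* for coef j
  VT <- V %*% Tmat                              # B x (p*E)
  null_t <- matrix(NA_real_, B, E)
  for (b in seq_len(B)) {
    H <- matrix(VT[b, ], p, E)                  # X'(v o e) for replicate b
    U <- V[b, ] * S0 - QC %*% H                 # G x E refit cluster scores
    null_t[b, ] <- Num[b, ] / sqrt(fac * colSums(U^2))
  }
  structure(list(null_t = null_t, B = B, seed = seed,
                 small_sample = small_sample),
            class = "wild_null")
}

#' Bootstrap two-sided edgewise p-values
#'
#' \eqn{p_e = \#\{b : |t^*_{be}| \ge |t_e|\} / B}: the fraction of
#' bootstrap null t-values at least as extreme as the observed one, with
#' ties counting against rejection. `method = "plus_one"` uses the
#' \eqn{(k+1)/(B+1)} estimator, which never returns exactly zero.
#'
#' @param t observed per-edge t-values.
#' @param null_t B x edges matrix of null t-values (or a `"wild_null"`).
#' @param method `"plain"` (default, as-printed) or `"plus_one"`.
#' @return per-edge p-values.
#' @export
edgewise_pvalues <- function(t, null_t, method = c("plain", "plus_one")) {
  method <- match.arg(method)
  if (inherits(null_t, "wild_null")) null_t <- null_t$null_t
  null_t <- as.matrix(null_t)
  stopifnot(length(t) == ncol(null_t))
  B <- nrow(null_t)
  k <- colSums(abs(null_t) >= rep(abs(t), each = B))
  if (method == "plain") k / B else (k + 1) / (B + 1)
}

#' Fit the edgewise marginal model with bootstrap inference
#'
#' One-call wrapper: OLS at every edge, cluster-robust SE and t for the
#' predictor of interest, wild cluster bootstrap null t-values, and
#' edgewise bootstrap p-values.
#'
#' @inheritParams wild_bootstrap_null
#' @param p_method p-value convention, see [edgewise_pvalues()].
#' @return list of class `"edgewise_fit"`: `beta`, `se`, `t`, `p` (per
#'   edge, interest coefficient), `null_t` (B x edges), `B`,
#'   `coef_names`, `interest_index`, `cluster_by`, `n_subjects`.
#' @export
fit_edgewise <- function(Y, design, B = 2000, seed = 1,
                         small_sample = c("CR0", "CR1"),
                         p_method = c("plain", "plus_one")) {
  small_sample <- match.arg(small_sample)
  p_method <- match.arg(p_method)
  stopifnot(inherits(design, "design_matrix"))
  Y <- as.matrix(Y)
  fit <- fit_marginal(Y, design$X)
  j <- design$interest_index
  se <- cluster_robust_se(design$X, fit$residuals, design$cluster_ids,
                          small_sample = small_sample, coef_index = j)
  beta <- fit$beta[j, ]
  tval <- beta / se[1L, ]
  nul <- wild_bootstrap_null(Y, design, B = B, seed = seed,
                             small_sample = small_sample)
  structure(list(
    beta = beta, se = se[1L, ], t = tval,
    p = edgewise_pvalues(tval, nul, method = p_method),
    null_t = nul$null_t, B = B, seed = seed,
    coef_names = design$coef_names, interest_index = j,
    cluster_by = design$cluster_by, small_sample = small_sample,
    n_subjects = nrow(Y)
  ), class = "edgewise_fit")
}

#' @export
print.edgewise_fit <- function(x, ...) {
  cat(sprintf(
    "edgewise_fit: %d edges, %d subjects, interest = %s, clusters by %s, B = %d\n",
    length(x$t), x$n_subjects, x$coef_names[x$interest_index], x$cluster_by, x$B))
  cat(sprintf("t range [%.3f, %.3f]; %d edges with bootstrap p < 0.05\n",
              min(x$t), max(x$t), sum(x$p < 0.05)))
  invisible(x)
}
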