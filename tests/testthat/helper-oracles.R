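# Independent oracles used across tests. These are deliberately naive
# (loops, enumeration) and never share code with the implementation.

# Cluster-robust covariance by explicit per-cluster summation.
oracle_cluster_vcov <- function(X, e, cluster, type = "CR0") {
  X <- as.matrix(X)
  A <- solve(t(X) %*% X)
  S <- matrix(0, ncol(X), ncol(X))
  for (g in unique(cluster)) {
    Xg <- X[cluster == g, , drop = FALSE]
    eg <- e[cluster == g]
    sg <- t(Xg) %*% eg
    S <- S + sg %*% t(sg)
  }
  V <- A %*% S %*% A
  if (type == "CR1") {
    G <- length(unique(cluster)); n <- nrow(X); p <- ncol(X)
    V <- V * G / (G - 1) * (n - 1) / (n - p)
  }
  V
}

# Westfall-Young step-down by direct enumeration over ranks.
oracle_wy <- function(obs, null, two_sided = TRUE) {
  if (two_sided) { obs <- abs(obs); null <- abs(null) }
  m <- length(obs)
  ord <- order(obs, decreasing = TRUE)
  q <- numeric(m)
  for (r in seq_len(m)) {
    cnt <- 0
    for (b in seq_len(nrow(null))) {
      mx <- max(null[b, ord[r:m]])
      if (mx >= obs[ord[r]]) cnt <- cnt + 1
    }
    q[r] <- cnt / nrow(null)
  }
  for (r in seq_len(m)[-1]) q[r] <- max(q[r], q[r - 1])
  out <- numeric(m)
  out[ord] <- pmin(q, 1)
  out
}

# Hand-built parcellation object for geometry-free tests.
make_parcellation <- function(networks, xyz = NULL, hemisphere = NULL,
                              merge_spec = NULL) {
  n <- length(networks)
  if (is.null(xyz)) xyz <- matrix(NA_real_, n, 3)
  if (is.null(hemisphere)) hemisphere <- rep("left", n)
  if (is.null(merge_spec)) {
    merge_spec <- stats::setNames(unique(networks), unique(networks))
  }
  structure(list(
    parcels = data.frame(parcel_id = seq_len(n), hemisphere = hemisphere,
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         is_cortical = !is.na(xyz[, 1]) | hemisphere != "subcortical",
                         network = networks, stringsAsFactors = FALSE),
    merge_spec = merge_spec
  ), class = "parcellation")
}

# Wild cluster bootstrap by literal refitting, one replicate at a time.
oracle_wild_bootstrap <- function(Y, X, j, cluster, V) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  levs <- sort(unique(cluster))
  Xr <- X[, -j, drop = FALSE]
  br <- solve(t(Xr) %*% Xr) %*% t(Xr) %*% Y
  Er <- Y - Xr %*% br
  out <- matrix(NA_real_, nrow(V), ncol(Y))
  for (b in seq_len(nrow(V))) {
    v <- V[b, match(cluster, levs)]
    Ystar <- Xr %*% br + v * Er
    bb <- solve(t(X) %*% X) %*% t(X) %*% Ystar
    res <- Ystar - X %*% bb
    for (e in seq_len(ncol(Y))) {
      Vc <- oracle_cluster_vcov(X, res[, e], cluster)
      out[b, e] <- bb[j, e] / sqrt(Vc[j, j])
    }
  }
  out
}
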