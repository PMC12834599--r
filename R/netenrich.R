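#' Apply a raw-to-merged network mapping
#'
#' Network-level inference is biased toward network pairs with many
#' edges, so small related networks are combined before testing (e.g. the
#' five motor-related systems into one SM network; salience + parietal
#' memory into SAL/PMN; lateral + medial visual into VIS — see
#' [default_merge_spec()]). Every raw label must be mapped; an identity
#' mapping leaves the assignment unchanged.
#'
#' @param x character vector of raw network labels, or a
#'   `"parcellation"` whose `parcels$network` column is to be merged.
#' @param merge_spec named character vector raw -> merged.
#' @return merged labels (same shape as `x`), or a `"parcellation"` with
#'   merged labels and an identity `merge_spec`.
#' @export
merge_networks <- function(x, merge_spec = default_merge_spec()) {
  if (inherits(x, "parcellation")) {
    merged <- merge_networks(x$parcels$network, merge_spec)
    x$parcels$network <- merged
    x$merge_spec <- stats::setNames(unique(merged), unique(merged))
    return(x)
  }
  x <- as.character(x)
  unmapped <- setdiff(unique(x), names(merge_spec))
  if (length(unmapped) > 0) {
    stop_nla("nla_unmapped_label",
             paste0("raw network label(s) not in merge_spec: ",
                    paste(unmapped, collapse = ", ")))
  }
  unname(merge_spec[x])
}

#' Welch's two-sample t-statistic
#'
#' \deqn{t = (\bar a - \bar b) / \sqrt{s_a^2/n_a + s_b^2/n_b}}
#' with sample variances; valid under unequal variances. This is the
#' enrichment statistic of the network-level analysis: positive values
#' indicate enrichment of the first group relative to the second,
#' negative values depletion.
#'
#' @param values_a,values_b numeric vectors with at least 2 finite values
#'   each.
#' @return the Welch statistic (a single number).
#' @export
welch_t <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop_nla("nla_bad_arg", "both groups need at least 2 values")
  }
  va <- stats::var(values_a); vb <- stats::var(values_b)
  den <- sqrt(va / length(values_a) + vb / length(values_b))
  if (den == 0) stop_nla("nla_zero_variance", "zero pooled variance")
  (mean(values_a) - mean(values_b)) / den
}

# Vectorized Welch statistics of edge groups against the whole connectome.
# x: edge values; groups: factor over edges; reference "overlap" compares
# each group with all edges (including its own), "disjoint" with the rest.
group_welch <- function(x, groups, reference = c("overlap", "disjoint")) {
  reference <- match.arg(reference)
  n <- tabulate(groups)
  gi <- as.integer(groups)   # level order, matching tabulate() and levels()
  s1 <- rowsum(x, gi, reorder = TRUE)[, 1L]
  s2 <- rowsum(x^2, gi, reorder = TRUE)[, 1L]
  m <- s1 / n
  v <- pmax((s2 - n * m^2) / (n - 1), 0)  # guard tiny negative round-off
  E <- length(x)
  if (reference == "overlap") {
    mb <- mean(x); vb <- stats::var(x); nb <- rep(E, length(n))
  } else {
    nb <- E - n
    mb <- (sum(x) - s1) / nb
    vb <- (sum(x^2) - s2 - nb * mb^2) / (nb - 1)
  }
  num <- m - mb
  den <- sqrt(v / n + vb / nb)
  w <- num / den
  w[den == 0 & num == 0] <- 0   # all values equal: no enrichment by convention
  w[n < 2L] <- NA_real_
  list(welch = w, n = n, mean = m, levels = levels(groups))
}

# Same but for a B x E matrix of null edge values: returns B x K matrix.
group_welch_matrix <- function(M, groups, reference = c("overlap", "disjoint")) {
  reference <- match.arg(reference)
  n <- tabulate(groups)
  K <- nlevels(groups)
  E <- ncol(M)
  Ind <- matrix(0, E, K)
  Ind[cbind(seq_len(E), as.integer(groups))] <- 1
  S1 <- M %*% Ind
  S2 <- (M * M) %*% Ind
  Mn <- sweep(S1, 2L, n, "/")
  Vr <- pmax(sweep(S2 - sweep(Mn^2, 2L, n, "*"), 2L, n - 1, "/"), 0)
  if (reference == "overlap") {
    mb <- rowMeans(M)
    vb <- (rowSums(M * M) - E * mb^2) / (E - 1)
    num <- Mn - mb
    den <- sqrt(sweep(Vr, 2L, n, "/") + vb / E)
  } else {
    nb <- E - n
    Sb1 <- rowSums(M) - S1
    Sb2 <- rowSums(M * M) - S2
    Mb <- sweep(Sb1, 2L, nb, "/")
    Vb <- pmax(sweep(Sb2 - sweep(Mb^2, 2L, nb, "*"), 2L, nb - 1, "/"), 0)
    num <- Mn - Mb
    den <- sqrt(sweep(Vr, 2L, n, "/") + sweep(Vb, 2L, nb, "/"))
  }
  W <- num / den
  W[den == 0 & num == 0] <- 0
  W[, n < 2L] <- NA_real_
  colnames(W) <- levels(groups)
  W
}

# Edge groups for network pairs: factor of "A|B" per edge. Groups with
# fewer than 2 edges are kept in the factor but yield NA statistics.
pair_edge_groups <- function(parcellation) {
  factor(edge_block_labels(parcellation))
}

# Incident-edge membership for whole networks: logical E x K matrix
# (an edge can touch two networks, so this is not a partition).
incident_membership <- function(parcellation, within_only = FALSE) {
  lab <- merged_labels(parcellation)
  nets <- sort(unique(lab))
  pr <- edge_pairs(nrow(parcellation$parcels))
  a <- lab[pr[, "i"]]; b <- lab[pr[, "j"]]
  mem <- vapply(nets, function(k) {
    if (within_only) a == k & b == k else a == k | b == k
  }, logical(nrow(pr)))
  colnames(mem) <- nets
  mem
}

#' Network-pair enrichment statistics
#'
#' For every unordered pair of merged networks (within-network pairs
#' included), compares the edgewise t-values of the pair's edges with the
#' t-values over the whole connectome using Welch's t. Positive
#' statistics indicate enrichment (a larger change in connectivity than
#' the connectome at large), negative statistics depletion. Pairs with
#' fewer than 2 edges are returned with `NA` and are excluded from any
#' downstream correction family.
#'
#' @param t_edges per-edge t-values in canonical edge order.
#' @param parcellation a `"parcellation"`; its `merge_spec` defines the
#'   merged networks.
#' @param reference `"overlap"` compares each pair against all edges
#'   (as-printed behaviour); `"disjoint"` against the complement.
#' @return data.frame: `pair`, `net_a`, `net_b`, `n_edges`, `mean_t`,
#'   `welch_t`.
#' @export
pair_enrichment <- function(t_edges, parcellation,
                            reference = c("overlap", "disjoint")) {
  reference <- match.arg(reference)
  if (any(!is.finite(t_edges))) stop_nla("nla_bad_arg", "t_edges must be finite")
  groups <- pair_edge_groups(parcellation)
  stopifnot(length(t_edges) == length(groups))
  gw <- group_welch(t_edges, groups, reference)
  parts <- strsplit(gw$levels, "|", fixed = TRUE)
  data.frame(
    pair = gw$levels,
    net_a = vapply(parts, `[`, "", 1L),
    net_b = vapply(parts, `[`, "", 2L),
    n_edges = gw$n,
    mean_t = gw$mean,
    welch_t = gw$welch,
    stringsAsFactors = FALSE
  )
}

#' Whole-network enrichment statistics
#'
#' Compares the absolute edgewise t-values of all edges belonging to a
#' network (by default every edge incident to one of its parcels) with
#' the absolute t-values over the whole connectome using Welch's t.
#' Positive statistics indicate enrichment of connectivity differences in
#' that network.
#'
#' @inheritParams pair_enrichment
#' @param edges `"incident"` (default): edges with at least one endpoint
#'   in the network; `"within"`: both endpoints.
#' @return data.frame: `network`, `n_edges`, `mean_abs_t`, `welch_t`.
#' @export
whole_network_enrichment <- function(t_edges, parcellation,
                                     edges = c("incident", "within"),
                                     reference = c("overlap", "disjoint")) {
  edges <- match.arg(edges)
  reference <- match.arg(reference)
  if (any(!is.finite(t_edges))) stop_nla("nla_bad_arg", "t_edges must be finite")
  mem <- incident_membership(parcellation, within_only = edges == "within")
  stopifnot(length(t_edges) == nrow(mem))
  at <- abs(t_edges)
  all_mean <- mean(at); all_var <- stats::var(at); E <- length(at)
  out <- lapply(colnames(mem), function(k) {
    sel <- at[mem[, k]]
    n <- length(sel)
    if (n < 2L || n == E && reference == "disjoint") {
      return(data.frame(network = k, n_edges = n, mean_abs_t = mean(sel),
                        welch_t = NA_real_, stringsAsFactors = FALSE))
    }
    if (reference == "overlap") {
      num <- mean(sel) - all_mean
      den <- sqrt(stats::var(sel) / n + all_var / E)
    } else {
      rest <- at[!mem[, k]]
      num <- mean(sel) - mean(rest)
      den <- sqrt(stats::var(sel) / n + stats::var(rest) / length(rest))
    }
    w <- if (den == 0 && num == 0) 0 else num / den
    data.frame(network = k, n_edges = n, mean_abs_t = mean(sel),
               welch_t = w, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Westfall-Young step-down adjusted p-values
#'
#' Resampling-based family-wise error control using successive maxima of
#' the null statistics (step-down maxT). Hypotheses are ordered by
#' decreasing observed statistic (in absolute value for two-sided
#' families); the adjusted p of the hypothesis at rank \eqn{r} is the
#' fraction of null replicates whose maximum over hypotheses ranked
#' \eqn{\ge r} reaches the observed value, with monotonicity enforced down
#' the ordering. Ties in the observed statistics are broken by hypothesis
#' index.
#'
#' @param observed_stats vector of m observed statistics.
#' @param null_stats B x m matrix of null statistics, columns aligned
#'   with `observed_stats`.
#' @param alternative `"two.sided"` (compare |statistics|) or
#'   `"greater"` (signed, enrichment only).
#' @param method `"plain"` counts k/B (as-printed); `"plus_one"` uses
#'   (k+1)/(B+1).
#' @return vector of m adjusted p-values (`p_fwer >= raw p` always).
#' @export
westfall_young_adjust <- function(observed_stats, null_stats,
                                  alternative = c("two.sided", "greater"),
                                  method = c("plain", "plus_one")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  null_stats <- as.matrix(null_stats)
  m <- length(observed_stats)
  if (ncol(null_stats) != m) {
    stop_nla("nla_bad_arg", "null_stats columns must align with observed_stats")
  }
  B <- nrow(null_stats)
  if (B < 1) stop_nla("nla_bad_arg", "need at least one null replicate")
  score <- if (alternative == "two.sided") abs(observed_stats) else observed_stats
  nscore <- if (alternative == "two.sided") abs(null_stats) else null_stats
  ord <- order(score, decreasing = TRUE)     # ties broken by index
  M <- nscore[, ord, drop = FALSE]
  if (m > 1L) {
    for (s in (m - 1L):1L) M[, s] <- pmax(M[, s], M[, s + 1L])
  }
  q <- numeric(m)
  for (r in seq_len(m)) {
    k <- sum(M[, r] >= score[ord[r]])
    q[r] <- if (method == "plain") k / B else (k + 1) / (B + 1)
  }
  q <- cummax(q)
  adj <- numeric(m)
  adj[ord] <- pmin(q, 1)
  adj
}

#' Network Level Analysis with bootstrap FWER control
#'
#' Runs the full network-level inference on an edgewise fit: Welch
#' enrichment statistics for every network pair (two-sided) and for every
#' whole network (one-sided, on |t|), with null distributions obtained by
#' recomputing the same statistics on each wild-bootstrap replicate's
#' null t-vector, and Westfall-Young step-down FWER correction applied
#' separately to the two families. The shared cluster signs across edges
#' within each bootstrap replicate (see [wild_bootstrap_null()]) make the
#' null Welch statistics carry the true between-pair dependence.
#'
#' @param fit an `"edgewise_fit"` carrying `null_t` (see
#'   [fit_edgewise()]).
#' @param parcellation a `"parcellation"` defining the merged networks.
#' @param alpha FWER level for significance flags (default 0.05).
#' @param whole_edges edge set for whole-network tests, see
#'   [whole_network_enrichment()].
#' @param reference connectome comparison group, see [pair_enrichment()].
#' @param p_method p-value counting convention.
#' @return list of class `"nla_result"`: `pairs` and `networks`
#'   data.frames with `welch_t`, `p_raw`, `p_fwer`, `significant`, plus
#'   `alpha` and `B`.
#' @export
run_nla <- function(fit, parcellation, alpha = 0.05,
                    whole_edges = c("incident", "within"),
                    reference = c("overlap", "disjoint"),
                    p_method = c("plain", "plus_one")) {
  whole_edges <- match.arg(whole_edges)
  reference <- match.arg(reference)
  p_method <- match.arg(p_method)
  if (is.null(fit$null_t)) stop_nla("nla_bad_arg", "fit carries no null_t")
  t_obs <- fit$t
  null_t <- fit$null_t
  B <- nrow(null_t)

  ## --- network pairs (two-sided) ---
  pairs <- pair_enrichment(t_obs, parcellation, reference)
  groups <- pair_edge_groups(parcellation)
  null_pairs <- group_welch_matrix(null_t, groups, reference)
  ok <- !is.na(pairs$welch_t) & colSums(is.na(null_pairs)) == 0
  pairs$p_raw <- NA_real_
  pairs$p_fwer <- NA_real_
  if (any(ok)) {
    obs <- pairs$welch_t[ok]
    nl <- null_pairs[, ok, drop = FALSE]
    k <- colSums(abs(nl) >= rep(abs(obs), each = B))
    pairs$p_raw[ok] <- if (p_method == "plain") k / B else (k + 1) / (B + 1)
    pairs$p_fwer[ok] <- westfall_young_adjust(obs, nl, "two.sided", p_method)
  }
  pairs$significant <- !is.na(pairs$p_fwer) & pairs$p_fwer < alpha

  ## --- whole networks (one-sided on |t|) ---
  nets <- whole_network_enrichment(t_obs, parcellation, whole_edges, reference)
  mem <- incident_membership(parcellation, within_only = whole_edges == "within")
  null_nets <- abs_group_welch_matrix(null_t, mem, reference)
  okn <- !is.na(nets$welch_t) & colSums(is.na(null_nets)) == 0
  nets$p_raw <- NA_real_
  nets$p_fwer <- NA_real_
  if (any(okn)) {
    obsn <- nets$welch_t[okn]
    nln <- null_nets[, okn, drop = FALSE]
    kn <- colSums(nln >= rep(obsn, each = B))
    nets$p_raw[okn] <- if (p_method == "plain") kn / B else (kn + 1) / (B + 1)
    nets$p_fwer[okn] <- westfall_young_adjust(obsn, nln, "greater", p_method)
  }
  nets$significant <- !is.na(nets$p_fwer) & nets$p_fwer < alpha

  structure(list(pairs = pairs, networks = nets, alpha = alpha, B = B,
                 whole_edges = whole_edges, reference = reference),
            class = "nla_result")
}

# Welch statistics of |edge values| for (possibly overlapping) network
# memberships, per null replicate: returns B x K.
abs_group_welch_matrix <- function(M, mem, reference = c("overlap", "disjoint")) {
  reference <- match.arg(reference)
  A <- abs(M)
  E <- ncol(A)
  n <- colSums(mem)
  S1 <- A %*% mem
  S2 <- (A * A) %*% mem
  Mn <- sweep(S1, 2L, n, "/")
  Vr <- pmax(sweep(S2 - sweep(Mn^2, 2L, n, "*"), 2L, n - 1, "/"), 0)
  if (reference == "overlap") {
    mb <- rowMeans(A)
    vb <- (rowSums(A * A) - E * mb^2) / (E - 1)
    W <- (Mn - mb) / sqrt(sweep(Vr, 2L, n, "/") + vb / E)
  } else {
    nb <- E - n
    Mb <- sweep(rowSums(A) - S1, 2L, nb, "/")
    Vb <- pmax(sweep(rowSums(A * A) - S2 - sweep(Mb^2, 2L, nb, "*"),
                     2L, nb - 1, "/"), 0)
    W <- (Mn - Mb) / sqrt(sweep(Vr, 2L, n, "/") + sweep(Vb, 2L, nb, "/"))
  }
  W[is.nan(W)] <- 0   # 0/0: all values equal, no enrichment by convention
  W[, n < 2L | n > E - (reference == "disjoint")] <- NA_real_
  colnames(W) <- colnames(mem)
  W
}

#' @export
print.nla_result <- function(x, ...) {
  cat(sprintf("nla_result: %d network pairs, %d whole networks, B = %d, alpha = %g\n",
              nrow(x$pairs), nrow(x$networks), x$B, x$alpha))
  sig <- x$pairs[x$pairs$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    cat("significant pairs (FWER):\n")
    print(sig[, c("pair", "n_edges", "welch_t", "p_fwer")], row.names = FALSE)
  } else {
    cat("no significant pairs at FWER alpha\n")
  }
  invisible(x)
}
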