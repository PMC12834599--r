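#' RMS magnitude map from edgewise statistics
#'
#' Summarizes edgewise change per parcel as the root-mean-square of the
#' t-values (or any edge statistic) over the parcel's row of the
#' connectivity matrix, i.e. its `n_parcels - 1` incident edges. The map
#' is computed on the full parcel set; cortex-only views are obtained by
#' masking afterwards.
#'
#' @param t_edges per-edge values in canonical edge order.
#' @param n_parcels number of parcels.
#' @return numeric vector of length `n_parcels`.
#' @export
rms_magnitude_map <- function(t_edges, n_parcels) {
  if (any(!is.finite(t_edges))) stop_nla("nla_bad_arg", "t_edges must be finite")
  stopifnot(length(t_edges) == n_edges(n_parcels))
  pr <- edge_pairs(n_parcels)
  s <- t_edges^2
  tot <- as.numeric(rowsum(c(s, s), c(pr[, "i"], pr[, "j"])))
  sqrt(tot / (n_parcels - 1))
}

#' Seed-based map from edgewise statistics
#'
#' Extracts the edge statistics between one seed parcel and every other
#' parcel (the seed's row of the matrix). The entry at the seed itself is
#' `NA`.
#'
#' @inheritParams rms_magnitude_map
#' @param seed_parcel parcel index in 1..n_parcels.
#' @return numeric vector of length `n_parcels` with `NA` at the seed.
#' @export
seed_map <- function(t_edges, seed_parcel, n_parcels) {
  stopifnot(length(t_edges) == n_edges(n_parcels))
  if (length(seed_parcel) != 1L || seed_parcel < 1 || seed_parcel > n_parcels) {
    stop_nla("nla_bad_arg", "invalid seed parcel id")
  }
  out <- rep(NA_real_, n_parcels)
  others <- setdiff(seq_len(n_parcels), seed_parcel)
  out[others] <- t_edges[edge_index(rep(seed_parcel, n_parcels - 1L),
                                   others, n_parcels)]
  out
}

#' Pearson correlation of two parcel maps
#'
#' @param map_a,map_b numeric vectors over parcels.
#' @param subset logical or integer subset of parcels to correlate over
#'   (e.g. the cortical parcels); default all.
#' @return Pearson r.
#' @export
map_correlation <- function(map_a, map_b, subset = NULL) {
  if (!is.null(subset)) {
    map_a <- map_a[subset]; map_b <- map_b[subset]
  }
  if (length(map_a) < 3L) stop_nla("nla_bad_arg", "need at least 3 parcels")
  if (any(!is.finite(map_a)) || any(!is.finite(map_b))) {
    stop_nla("nla_bad_arg", "maps must be finite on the subset")
  }
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0) {
    stop_nla("nla_constant_map", "correlation undefined for a constant map")
  }
  stats::cor(map_a, map_b)
}

#' Row-wise correlation of two edge statistic vectors
#'
#' For each parcel, the Pearson correlation between its incident-edge
#' values in two edgewise analyses (e.g. a stimulant FC matrix row vs the
#' corresponding sleep FC matrix row). Parcels whose row is constant in
#' either input are masked with `NA` rather than failing.
#'
#' @param t_edges_a,t_edges_b per-edge values on the same edge index.
#' @inheritParams rms_magnitude_map
#' @return numeric vector of length `n_parcels`.
#' @export
rowwise_fc_correlation_map <- function(t_edges_a, t_edges_b, n_parcels) {
  stopifnot(length(t_edges_a) == n_edges(n_parcels),
            length(t_edges_b) == n_edges(n_parcels))
  out <- rep(NA_real_, n_parcels)
  for (i in seq_len(n_parcels)) {
    idx <- incident_edges(i, n_parcels)
    a <- t_edges_a[idx]; b <- t_edges_b[idx]
    if (stats::sd(a) > 0 && stats::sd(b) > 0) out[i] <- stats::cor(a, b)
  }
  out
}

#' Write / read a parcel map as TSV
#'
#' Two columns: `parcel_id`, `value`.
#'
#' @param map numeric vector over parcels.
#' @param path file path.
#' @param parcel_id parcel ids (default sequential).
#' @export
write_parcel_map <- function(map, path, parcel_id = seq_along(map)) {
  utils::write.table(data.frame(parcel_id = parcel_id, value = map),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parcel_map
#' @export
read_parcel_map <- function(path) {
  df <- utils::read.delim(path)
  stats::setNames(df$value, df$parcel_id)
}
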