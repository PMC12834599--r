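#' Fisher-Z functional connectivity from a parcel time series
#'
#' Computes pairwise Pearson correlations between all parcel time series
#' over the retained frames and applies the Fisher Z transform
#' (`atanh`). The result is one value per unordered parcel pair in the
#' canonical edge order of [edge_index()].
#'
#' @param series numeric matrix, parcels x frames.
#' @param mask optional logical vector over frames (TRUE = retained),
#'   e.g. from [censor_frames()]; default retains all frames.
#' @return list of class `"connectivity_vector"`: `z` (numeric, length
#'   `n_edges(n_parcels)`), `n_frames_used`, `n_parcels`.
#' @export
fisher_fc <- function(series, mask = NULL) {
  series <- as.matrix(series)
  n_parcels <- nrow(series)
  if (n_parcels < 2L) stop_nla("nla_bad_series", "need at least two parcels")
  if (is.null(mask)) mask <- rep(TRUE, ncol(series))
  stopifnot(is.logical(mask), length(mask) == ncol(series))
  kept <- series[, mask, drop = FALSE]
  if (ncol(kept) < 3L) stop_nla("nla_bad_series", "fewer than 3 retained frames")
  sds <- apply(kept, 1L, stats::sd)
  if (any(sds == 0)) {
    stop_nla("nla_constant_series",
             paste0("constant time series for parcel(s): ",
                    paste(which(sds == 0), collapse = ", ")))
  }
  r <- stats::cor(t(kept))
  # upper.tri() vectorizes column-major ((1,2),(1,3),(2,3),...); index the
  # correlation matrix explicitly to honour the canonical edge order.
  pr <- edge_pairs(n_parcels)
  rmat_idx <- (pr[, "j"] - 1L) * n_parcels + pr[, "i"]
  z_lin <- r[rmat_idx]
  if (any(abs(z_lin) >= 1)) {
    bad <- which(abs(z_lin) >= 1)[1L]
    stop_nla("nla_collinear_parcels",
             sprintf("|r| = 1 for parcel pair (%d, %d); collinear series",
                     pr[bad, "i"], pr[bad, "j"]))
  }
  structure(list(
    z = atanh(z_lin),
    n_frames_used = ncol(kept),
    n_parcels = n_parcels
  ), class = "connectivity_vector")
}
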