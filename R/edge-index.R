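#' Canonical edge indexing for a parcellated connectome
#'
#' The edgewise analyses operate on the vectorized upper triangle of the
#' parcel-by-parcel connectivity matrix. Edges are the unordered parcel
#' pairs \eqn{(i, j)} with \eqn{i < j}, stored in lexicographic order:
#' (1,2), (1,3), ..., (1,n), (2,3), ... . All functions in the package use
#' this one ordering, so a subject's connectome is a plain numeric vector
#' of length \eqn{n(n-1)/2}.
#'
#' @param n_parcels number of parcels (nodes); at least 2.
#' @return `n_edges()`: the number of distinct edges, \eqn{n(n-1)/2}.
#' @examples
#' n_edges(394)  # 77421
#' edge_index(1, 2, n_parcels = 4)
#' edge_pairs(4)
#' @export
n_edges <- function(n_parcels) {
  stopifnot(length(n_parcels) == 1L, n_parcels >= 2)
  n_parcels * (n_parcels - 1) / 2
}

#' @rdname n_edges
#' @param i,j parcel indices in 1..n_parcels, `i != j` (vectorized).
#' @return `edge_index()`: the 1-based linear edge index of each pair.
#' @export
edge_index <- function(i, j, n_parcels) {
  if (any(i == j)) stop_nla("nla_bad_edge", "self-edges (i == j) have no index")
  if (any(i < 1 | j < 1 | i > n_parcels | j > n_parcels)) {
    stop_nla("nla_bad_edge", "parcel index out of range")
  }
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  # 0-based: k0 = (lo-1)*n - (lo-1)*lo/2 + (hi - lo - 1)
  as.numeric((lo - 1) * n_parcels - (lo - 1) * lo / 2 + (hi - lo - 1) + 1)
}

#' @rdname n_edges
#' @return `edge_pairs()`: a two-column integer matrix (`i`, `j`) whose row
#'   `k` is the parcel pair of edge `k`, the inverse of `edge_index()`.
#' @export
edge_pairs <- function(n_parcels) {
  stopifnot(n_parcels >= 2)
  i <- rep.int(seq_len(n_parcels - 1L), times = (n_parcels - 1L):1L)
  j <- sequence((n_parcels - 1L):1L) + i
  cbind(i = i, j = j)
}

#' @rdname n_edges
#' @param parcel parcel index whose incident edges are requested.
#' @return `incident_edges()`: the `n_parcels - 1` linear indices of the
#'   edges touching `parcel` (its row of the connectivity matrix).
#' @export
incident_edges <- function(parcel, n_parcels) {
  stopifnot(length(parcel) == 1L, parcel >= 1, parcel <= n_parcels)
  others <- setdiff(seq_len(n_parcels), parcel)
  edge_index(rep(parcel, n_parcels - 1L), others, n_parcels)
}
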