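#' Generate a synthetic spherical parcellation with network labels
#'
#' Builds a parcellation that mimics the geometry the analysis assumes:
#' cortical parcels living on a unit sphere per hemisphere (as after
#' spherical surface registration), split between left and right
#' hemispheres with mirrored coordinates, plus subcortical parcels that
#' carry no surface coordinates. Cortical centroids are placed on a
#' Fibonacci lattice (quasi-uniform), and networks are assigned as
#' contiguous spherical caps (Voronoi cells of random seed directions), so
#' network membership is spatially autocorrelated — the regime rotational
#' null models are designed for.
#'
#' With the default `n_networks = 16` the raw cortical labels are named
#' after canonical resting-state systems (premotor, somatomotor hand /
#' mouth / foot, somato-cognitive action, auditory, salience, parietal
#' memory, lateral/medial visual, default mode, dorsal/ventral attention,
#' frontoparietal, context association, action mode); otherwise generic
#' labels `net01..netK` are used. Subcortical parcels cycle through five
#' subcortical systems (hippocampus, amygdala, basal ganglia, thalamus,
#' cerebellum).
#'
#' @param n_cortical number of cortical parcels (default 333), split as
#'   evenly as possible across hemispheres.
#' @param n_subcortical number of subcortical parcels (default 61).
#' @param n_networks number of raw cortical networks (default 16).
#' @param seed RNG seed for network seed directions.
#' @return list of class `"parcellation"` with elements
#'   \describe{
#'     \item{parcels}{data.frame: `parcel_id`, `hemisphere` (`left`,
#'       `right`, `subcortical`), `x`, `y`, `z` (unit-norm centroid, NA for
#'       subcortical), `is_cortical`, `network` (raw label).}
#'     \item{merge_spec}{named character vector mapping raw labels to the
#'       merged labels used for network-level inference (see
#'       [merge_networks()]).}
#'   }
#' @examples
#' p <- gen_parcellation(333, 61, seed = 1)
#' nrow(p$parcels)           # 394
#' n_edges(nrow(p$parcels))  # 77421
#' @export
gen_parcellation <- function(n_cortical = 333, n_subcortical = 61,
                             n_networks = 16, seed = 1) {
  if (n_cortical < 2) stop_nla("nla_bad_arg", "n_cortical must be at least 2")
  if (n_subcortical < 0) stop_nla("nla_bad_arg", "n_subcortical must be non-negative")
  if (n_networks < 2) stop_nla("nla_bad_arg", "n_networks must be at least 2")
  n_left <- ceiling(n_cortical / 2)
  n_right <- n_cortical - n_left

  left <- fibonacci_sphere(n_left)
  right <- fibonacci_sphere(max(n_right, 1L))[seq_len(n_right), , drop = FALSE]
  right[, 1] <- -right[, 1]  # mirror through the sagittal plane

  labels <- if (n_networks == 16L) canonical_cortical_labels() else
    sprintf("net%02d", seq_len(n_networks))

  seeds_dir <- with_seed(seed, {
    m <- matrix(stats::rnorm(3 * n_networks), n_networks, 3)
    m / sqrt(rowSums(m^2))
  })
  assign_cap <- function(xyz, dirs) max.col(xyz %*% t(dirs))
  net_left <- labels[assign_cap(left, seeds_dir)]
  seeds_right <- seeds_dir
  seeds_right[, 1] <- -seeds_right[, 1]
  net_right <- labels[assign_cap(right, seeds_right)]

  sub_labels <- canonical_subcortical_labels()
  net_sub <- if (n_subcortical > 0) {
    sub_labels[((seq_len(n_subcortical) - 1L) %% length(sub_labels)) + 1L]
  } else character(0)

  parcels <- data.frame(
    parcel_id = seq_len(n_cortical + n_subcortical),
    hemisphere = c(rep("left", n_left), rep("right", n_right),
                   rep("subcortical", n_subcortical)),
    x = c(left[, 1], right[, 1], rep(NA_real_, n_subcortical)),
    y = c(left[, 2], right[, 2], rep(NA_real_, n_subcortical)),
    z = c(left[, 3], right[, 3], rep(NA_real_, n_subcortical)),
    is_cortical = c(rep(TRUE, n_cortical), rep(FALSE, n_subcortical)),
    network = c(net_left, net_right, net_sub),
    stringsAsFactors = FALSE
  )
  structure(list(parcels = parcels, merge_spec = default_merge_spec()),
            class = "parcellation")
}

# Quasi-uniform points on the unit sphere (golden-angle spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

canonical_cortical_labels <- function() {
  c("premotor", "somatomotor_hand", "somatomotor_mouth", "somatomotor_foot",
    "somatocognitive_action", "auditory", "salience", "parietal_memory",
    "visual_lateral", "visual_medial", "default_mode", "dorsal_attention",
    "ventral_attention", "frontoparietal", "context_association",
    "action_mode")
}

canonical_subcortical_labels <- function() {
  c("hippocampus", "amygdala", "basal_ganglia", "thalamus", "cerebellum")
}

#' Default raw-to-merged network mapping
#'
#' Small related networks are combined before network-level inference,
#' which would otherwise be biased toward large network pairs: the five
#' motor-related systems become one sensorimotor (SM) network, salience
#' and parietal memory become SAL/PMN, and lateral/medial visual become
#' VIS. Other labels map to their usual abbreviations.
#'
#' @return named character vector, raw label -> merged label.
#' @export
default_merge_spec <- function() {
  c(premotor = "SM", somatomotor_hand = "SM", somatomotor_mouth = "SM",
    somatomotor_foot = "SM", somatocognitive_action = "SM",
    auditory = "AUD", salience = "SAL/PMN", parietal_memory = "SAL/PMN",
    visual_lateral = "VIS", visual_medial = "VIS",
    default_mode = "DMN", dorsal_attention = "DAN",
    ventral_attention = "VAN", frontoparietal = "FPN",
    context_association = "CAN", action_mode = "AMN",
    hippocampus = "HC", amygdala = "AMYG", basal_ganglia = "BG",
    thalamus = "THAL", cerebellum = "CERB")
}

#' @export
print.parcellation <- function(x, ...) {
  p <- x$parcels
  cat(sprintf("parcellation: %d parcels (%d cortical, %d subcortical), %d edges\n",
              nrow(p), sum(p$is_cortical), sum(!p$is_cortical),
              n_edges(nrow(p))))
  cat(sprintf("raw networks: %s\n", paste(sort(unique(p$network)), collapse = ", ")))
  invisible(x)
}

#' Write / read a parcel table
#'
#' Plain TSV with columns `parcel_id`, `hemisphere`, `x`, `y`, `z`,
#' `is_cortical`, `network`.
#'
#' @param parcellation a `"parcellation"` object.
#' @param path output file path.
#' @export
write_parcel_table <- function(parcellation, path) {
  utils::write.table(parcellation$parcels, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parcel_table
#' @param merge_spec merge mapping to attach (default [default_merge_spec()]).
#' @export
read_parcel_table <- function(path, merge_spec = default_merge_spec()) {
  parcels <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(list(parcels = parcels, merge_spec = merge_spec),
            class = "parcellation")
}
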