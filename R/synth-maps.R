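#' Generate a synthetic parcel-level reference map
#'
#' Produces a cortical parcel map loading on a set of target networks
#' (value 1 inside, 0 outside) plus spatially smooth noise, standing in
#' for external reference maps (e.g. neurotransmitter or arousal
#' templates) in spin-test recovery experiments. The noise is a sum of
#' random spherical Gaussian bumps evaluated at the parcel centroids, so
#' it carries spatial autocorrelation like real cortical maps; it is
#' rescaled to have standard deviation `noise_sd` across cortical parcels.
#' Subcortical parcels get `NA` (the rotational null is cortex-only).
#'
#' @inheritParams gen_fc_data
#' @param target_networks character vector of merged network labels the
#'   map loads on.
#' @param noise_sd SD of the smooth noise component (0 = noiseless
#'   network indicator).
#' @param n_bumps,concentration number and angular concentration of the
#'   random bumps forming the noise field.
#' @return numeric vector over parcels (NA for subcortical), in the order
#'   of `parcellation$parcels`.
#' @export
gen_reference_map <- function(parcellation, target_networks = "SM",
                              noise_sd = 0.3, seed = 1,
                              n_bumps = 12, concentration = 10) {
  lab <- merged_labels(parcellation)
  known <- unique(c(lab, unname(parcellation$merge_spec)))
  if (!all(target_networks %in% known)) {
    stop_nla("nla_bad_block", "target_networks contains unknown merged labels")
  }
  p <- parcellation$parcels
  cortical <- p$is_cortical
  vals <- ifelse(lab %in% target_networks, 1, 0)
  vals[!cortical] <- NA_real_
  if (noise_sd > 0) {
    noise <- with_seed(seed, {
      u <- matrix(stats::rnorm(3 * n_bumps), n_bumps, 3)
      u <- u / sqrt(rowSums(u^2))
      amp <- stats::rnorm(n_bumps)
      xyz <- as.matrix(p[cortical, c("x", "y", "z")])
      # each hemisphere is its own sphere: evaluate one isotropic field
      # at left-equivalent coordinates, giving a bilaterally symmetric
      # map whose per-hemisphere law is rotation-invariant (the regime
      # the mirrored-rotation spin test is built for)
      right <- p$hemisphere[cortical] == "right"
      xyz[right, 1] <- -xyz[right, 1]
      field <- exp(concentration * (xyz %*% t(u) - 1)) %*% amp
      as.numeric(field)
    })
    sdn <- stats::sd(noise)
    if (sdn > 0) noise <- noise / sdn * noise_sd
    vals[cortical] <- vals[cortical] + noise
  }
  vals
}
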