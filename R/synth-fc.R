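#' Ground-truth effect specification for synthetic connectomes
#'
#' Describes where covariate effects are planted in edge space and the
#' variance components of the generative model. Effects are specified per
#' network *block*: an unordered pair of merged network labels written
#' `"A|B"` (within-network blocks are `"A|A"`). The default mirrors the
#' sign pattern the package's recovery tests target: stimulant effects of
#' -0.030 (Fisher-Z units) on within-SM edges and +0.030 on SM-SAL/PMN
#' edges, and a sleep effect of -0.011 per unit of the 1-5 sleep score on
#' within-SM edges. Because those blocks cover roughly two percent of all
#' edges, the planted magnitude is, by construction, close to the 98th
#' percentile of |beta| across edges.
#'
#' @param stim named numeric: stimulant effect per block (Fisher-Z units).
#' @param sleep named numeric: effect per unit sleep score per block.
#' @param interaction named numeric: stimulant-by-sleep effect per block.
#' @param site_sd,family_sd SDs of site- and family-level random
#'   intercepts (per edge); both default 0.04.
#' @param noise_sd residual edge noise SD; default 0.17.
#' @param baseline_within,baseline_between mean Fisher-Z connectivity for
#'   within- and between-network edges.
#' @return list of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(stim = c("SM|SM" = -0.030, "SAL/PMN|SM" = 0.030),
                            sleep = c("SM|SM" = -0.011),
                            interaction = numeric(0),
                            site_sd = 0.04, family_sd = 0.04,
                            noise_sd = 0.17,
                            baseline_within = 0.30, baseline_between = 0.05) {
  if (site_sd < 0 || family_sd < 0 || noise_sd < 0) {
    stop_nla("nla_bad_arg", "variance components must be non-negative")
  }
  norm_blocks <- function(x) {
    if (length(x) == 0) return(stats::setNames(numeric(0), character(0)))
    nm <- strsplit(names(x), "|", fixed = TRUE)
    if (any(lengths(nm) != 2L)) {
      stop_nla("nla_bad_arg", "block names must be 'A|B' pairs of merged labels")
    }
    names(x) <- vapply(nm, function(p) paste(sort(p), collapse = "|"), "")
    x
  }
  structure(list(
    stim = norm_blocks(stim), sleep = norm_blocks(sleep),
    interaction = norm_blocks(interaction),
    site_sd = site_sd, family_sd = family_sd, noise_sd = noise_sd,
    baseline_within = baseline_within, baseline_between = baseline_between
  ), class = "synthetic_truth")
}

# Merged network label per parcel, in parcel order.
merged_labels <- function(parcellation) {
  merged <- merge_networks(parcellation$parcels$network,
                           parcellation$merge_spec)
  merged
}

# "A|B" block label per edge (canonical edge order), labels sorted.
edge_block_labels <- function(parcellation) {
  lab <- merged_labels(parcellation)
  pr <- edge_pairs(nrow(parcellation$parcels))
  a <- lab[pr[, "i"]]
  b <- lab[pr[, "j"]]
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# Per-edge effect vector from a named block specification.
block_effect_vector <- function(blocks, edge_labels, parcellation) {
  beta <- numeric(length(edge_labels))
  if (length(blocks) == 0) return(beta)
  # valid labels are the merge spec's codomain: a block naming a merged
  # network with no parcels simply covers zero edges
  known <- unique(c(merged_labels(parcellation),
                    unname(parcellation$merge_spec)))
  for (bl in names(blocks)) {
    parts <- strsplit(bl, "|", fixed = TRUE)[[1L]]
    if (!all(parts %in% known)) {
      stop_nla("nla_bad_block",
               sprintf("block '%s' references unknown merged network label", bl))
    }
    beta[edge_labels == bl] <- blocks[[bl]]
  }
  beta
}

# Expected (noise-free, cluster-effect-free) Fisher-Z per subject x edge.
expected_fc <- function(design, parcellation, truth) {
  el <- edge_block_labels(parcellation)
  lab <- merged_labels(parcellation)
  pr <- edge_pairs(nrow(parcellation$parcels))
  within <- lab[pr[, "i"]] == lab[pr[, "j"]]
  base <- ifelse(within, truth$baseline_within, truth$baseline_between)
  bs <- block_effect_vector(truth$stim, el, parcellation)
  bl <- block_effect_vector(truth$sleep, el, parcellation)
  bi <- block_effect_vector(truth$interaction, el, parcellation)
  ones <- rep(1, nrow(design))
  outer(ones, base) +
    outer(as.numeric(design$stimulant), bs) +
    outer(as.numeric(design$sleep), bl) +
    outer(as.numeric(design$stimulant * design$sleep), bi)
}

#' Generate synthetic subject-by-edge connectivity data
#'
#' Simulates Fisher-Z connectivity vectors under the marginal-model data
#' generating process the analysis assumes: for subject \eqn{i} and edge
#' \eqn{e},
#' \deqn{z_{ie} = \mu_e + \beta^{stim}_e stim_i + \beta^{sleep}_e sleep_i
#'   + \beta^{int}_e stim_i sleep_i + a_{site(i),e} + b_{fam(i),e} +
#'   \epsilon_{ie}}
#' where \eqn{\mu_e} is a within/between-network baseline, the block
#' effects come from `truth`, and \eqn{a}, \eqn{b}, \eqn{\epsilon} are
#' independent centered Gaussians with SDs `site_sd`, `family_sd`,
#' `noise_sd`. The site and family intercepts are drawn per (cluster,
#' edge), so edge residuals are correlated within clusters — the
#' non-exchangeability the cluster-robust machinery must absorb.
#'
#' @param design a `"cohort_design"` (see [gen_cohort()]).
#' @param parcellation a `"parcellation"` (see [gen_parcellation()]).
#' @param truth a `"synthetic_truth"` (see [synthetic_truth()]).
#' @param seed RNG seed.
#' @return list of class `"fc_data"`: `z` (subjects x edges matrix of
#'   Fisher-Z values), `truth`, and per-edge truth vectors `beta_stim`,
#'   `beta_sleep`, `beta_interaction`, plus `edge_blocks` (the `"A|B"`
#'   label of every edge) for recovery tests.
#' @export
gen_fc_data <- function(design, parcellation, truth = synthetic_truth(),
                        seed = 1) {
  stopifnot(inherits(design, "cohort_design") || is.data.frame(design))
  el <- edge_block_labels(parcellation)
  mu <- expected_fc(design, parcellation, truth)
  n <- nrow(design)
  E <- ncol(mu)
  z <- with_seed(seed, {
    sites <- sort(unique(design$site_id))
    fams <- sort(unique(design$family_id))
    a <- matrix(stats::rnorm(length(sites) * E, sd = truth$site_sd),
                length(sites), E)
    b <- matrix(stats::rnorm(length(fams) * E, sd = truth$family_sd),
                length(fams), E)
    mu + a[match(design$site_id, sites), , drop = FALSE] +
      b[match(design$family_id, fams), , drop = FALSE] +
      matrix(stats::rnorm(n * E, sd = truth$noise_sd), n, E)
  })
  structure(list(
    z = z,
    truth = truth,
    beta_stim = block_effect_vector(truth$stim, el, parcellation),
    beta_sleep = block_effect_vector(truth$sleep, el, parcellation),
    beta_interaction = block_effect_vector(truth$interaction, el, parcellation),
    edge_blocks = el,
    n_parcels = nrow(parcellation$parcels)
  ), class = "fc_data")
}

#' @export
print.fc_data <- function(x, ...) {
  cat(sprintf("fc_data: %d subjects x %d edges (%d parcels); %d edges carry a stimulant effect\n",
              nrow(x$z), ncol(x$z), x$n_parcels, sum(x$beta_stim != 0)))
  invisible(x)
}
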