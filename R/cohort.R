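#' Generate a synthetic clustered cohort
#'
#' Draws a subjects-by-covariates table with the clustering structure of a
#' multi-site family study: subjects are nested in families, families are
#' nested in sites (a family never straddles sites). Predictors of
#' interest are a binary stimulant indicator (default prevalence 5.8%, the
#' day-of-scan prevalence in the cohort the defaults emulate) and an
#' ordinal sleep-duration score on a monotonically increasing 1-5 scale.
#' Nuisance covariates are age in months, sex, mean in-scanner head motion
#' (FD, mm) and a socioeconomic z-score.
#'
#' @param n_subjects number of subjects.
#' @param n_sites number of acquisition sites (default 21).
#' @param mean_family_size expected subjects per family (>= 1).
#' @param prevalence_stim probability of stimulant = 1 (default 0.058).
#' @param sleep_probs probabilities of sleep scores 1..5; must sum to 1.
#' @param seed RNG seed.
#' @return data.frame of class `"cohort_design"`: `subject_id`, `site_id`,
#'   `family_id` (globally unique, nested in site), `stimulant` (0/1),
#'   `sleep` (1..5), `age_months`, `sex` (0/1), `fd_mean`, `ses`.
#' @export
gen_cohort <- function(n_subjects, n_sites = 21, mean_family_size = 1.15,
                       prevalence_stim = 0.058,
                       sleep_probs = c(0.08, 0.18, 0.30, 0.28, 0.16),
                       seed = 1) {
  if (n_sites > n_subjects) stop_nla("nla_bad_arg", "n_sites exceeds n_subjects")
  if (n_sites < 1 || n_subjects < 1) stop_nla("nla_bad_arg", "counts must be positive")
  if (prevalence_stim < 0 || prevalence_stim > 1) {
    stop_nla("nla_bad_arg", "prevalence_stim must be in [0, 1]")
  }
  if (length(sleep_probs) != 5L || any(sleep_probs < 0) ||
      abs(sum(sleep_probs) - 1) > 1e-8) {
    stop_nla("nla_bad_arg", "sleep_probs must be 5 non-negative values summing to 1")
  }
  stopifnot(mean_family_size >= 1)
  with_seed(seed, {
    # uneven site sizes, every site non-empty
    w <- stats::rgamma(n_sites, shape = 5)
    site <- c(seq_len(n_sites),
              sample(n_sites, n_subjects - n_sites, replace = TRUE,
                     prob = w / sum(w)))
    site <- sort(site)
    # partition each site's subjects into families of size 1 + Poisson
    family <- integer(n_subjects)
    next_fam <- 1L
    for (s in seq_len(n_sites)) {
      idx <- which(site == s)
      k <- 0L
      while (k < length(idx)) {
        fs <- 1L + stats::rpois(1L, mean_family_size - 1)
        fs <- min(fs, length(idx) - k)
        family[idx[k + seq_len(fs)]] <- next_fam
        next_fam <- next_fam + 1L
        k <- k + fs
      }
    }
    out <- data.frame(
      subject_id = seq_len(n_subjects),
      site_id = site,
      family_id = family,
      stimulant = stats::rbinom(n_subjects, 1L, prevalence_stim),
      sleep = sample.int(5L, n_subjects, replace = TRUE, prob = sleep_probs),
      age_months = round(stats::rnorm(n_subjects, mean = 119, sd = 7.5)),
      sex = stats::rbinom(n_subjects, 1L, 0.5),
      fd_mean = exp(stats::rnorm(n_subjects, mean = log(0.12), sd = 0.35)),
      ses = stats::rnorm(n_subjects),
      stringsAsFactors = FALSE
    )
    class(out) <- c("cohort_design", "data.frame")
    out
  })
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    "cohort_design: %d subjects, %d sites, %d families, %d stimulant takers (%.1f%%)\n",
    nrow(x), length(unique(x$site_id)), length(unique(x$family_id)),
    sum(x$stimulant), 100 * mean(x$stimulant)))
  invisible(x)
}
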