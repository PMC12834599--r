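#' Generate synthetic parcel time series with motion traces
#'
#' Draws, for each subject, a parcels-by-frames Gaussian series whose
#' population correlation matrix equals the inverse Fisher-Z transform of
#' the subject's target connectivity (baseline + planted effects + that
#' subject's site/family intercepts), so that [fisher_fc()] recovers the
#' target in expectation. A framewise-displacement trace is attached with
#' Bernoulli(`fd_spike_rate`) motion spikes above 0.2 mm; clean frames sit
#' well below the censoring threshold.
#'
#' If a subject's target correlation matrix is not positive definite the
#' generator signals an error of class `"nla_not_posdef"`; increasing
#' `shrinkage` (convex combination with the identity) is the remedy.
#'
#' @inheritParams gen_fc_data
#' @param n_frames frames per subject (default 720, i.e. 9.6 min at TR
#'   0.8 s, so subjects survive default censoring).
#' @param tr repetition time in seconds (default 0.8).
#' @param fd_spike_rate per-frame probability of a motion spike.
#' @param shrinkage amount `l` in `(1-l) R + l I` applied to each target
#'   correlation matrix before factorization.
#' @return list of class `"timeseries_set"`: `series` (list of parcels x
#'   frames matrices), `fd` (list of per-frame FD traces), `tr`,
#'   `subject_id`.
#' @export
gen_timeseries <- function(design, parcellation, truth = synthetic_truth(),
                           n_frames = 720, tr = 0.8, fd_spike_rate = 0.03,
                           seed = 1, shrinkage = 0) {
  if (n_frames < 1) stop_nla("nla_bad_arg", "n_frames must be at least 1")
  if (tr <= 0) stop_nla("nla_bad_arg", "tr must be positive")
  stopifnot(fd_spike_rate >= 0, fd_spike_rate <= 1, shrinkage >= 0, shrinkage < 1)
  n_parcels <- nrow(parcellation$parcels)
  # target z per subject including cluster intercepts, no edge noise
  truth0 <- truth
  truth0$noise_sd <- 0
  targets <- gen_fc_data(design, parcellation, truth0, seed = seed)$z
  pr <- edge_pairs(n_parcels)
  with_seed(seed + 1L, {
    series <- vector("list", nrow(design))
    fd <- vector("list", nrow(design))
    for (s in seq_len(nrow(design))) {
      R <- diag(n_parcels)
      R[pr] <- tanh(targets[s, ])
      R[pr[, c(2, 1)]] <- tanh(targets[s, ])
      if (shrinkage > 0) R <- (1 - shrinkage) * R + shrinkage * diag(n_parcels)
      L <- tryCatch(chol(R), error = function(e) NULL)
      if (is.null(L)) {
        stop_nla("nla_not_posdef",
                 sprintf(paste0("target correlation matrix for subject %d is not ",
                                "positive definite; increase `shrinkage`"), s))
      }
      series[[s]] <- t(L) %*% matrix(stats::rnorm(n_parcels * n_frames),
                                     n_parcels, n_frames)
      spikes <- stats::rbinom(n_frames, 1L, fd_spike_rate) == 1L
      f <- stats::runif(n_frames, 0.02, 0.15)
      f[spikes] <- 0.2 + stats::rexp(sum(spikes), rate = 1 / 0.15)
      f[1L] <- 0
      fd[[s]] <- f
    }
    structure(list(series = series, fd = fd, tr = tr,
                   subject_id = design$subject_id),
              class = "timeseries_set")
  })
}
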