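#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Defaults match the
#' reference analysis settings: FD censoring at 0.2 mm, 600-frame
#' minimum, 2,000 bootstrap iterations, 2,000 rotations, FWER alpha 0.05,
#' site-level clustering. Every stochastic stage derives its seed from
#' the single `seed` field, so a rerun with the same configuration is
#' reproducible.
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"ingest"`
#'   (read connectivity + cohort tables from `connectivity_csv` /
#'   `cohort_csv`).
#' @param n_subjects,n_cortical,n_subcortical,n_networks synthetic cohort
#'   and parcellation sizes (simulate mode).
#' @param n_sites,prevalence_stim cohort structure passed to
#'   [gen_cohort()] in simulate mode.
#' @param from_timeseries if TRUE, simulate BOLD-like time series and run
#'   motion censoring + Fisher-Z connectivity; otherwise simulate
#'   connectivity directly.
#' @param n_frames,tr,fd_spike_rate time-series settings.
#' @param fd_threshold,min_frames censoring settings.
#' @param truth a [synthetic_truth()] specification.
#' @param interest,covariates,cluster_by model settings.
#' @param B bootstrap replicates; `n_rotations` spin rotations.
#' @param alpha FWER level.
#' @param spin_target networks the synthetic reference map loads on.
#' @param power_n_nets within-network edge counts for the power table.
#' @param seed master seed.
#' @param connectivity_csv,cohort_csv,parcel_tsv input paths (ingest
#'   mode; `parcel_tsv` optional in simulate mode).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest"),
                            n_subjects = 300, n_cortical = 60,
                            n_subcortical = 0, n_networks = 16,
                            n_sites = 21, prevalence_stim = 0.058,
                            from_timeseries = FALSE,
                            n_frames = 720, tr = 0.8, fd_spike_rate = 0.03,
                            fd_threshold = 0.2, min_frames = 600,
                            truth = synthetic_truth(),
                            interest = "stimulant",
                            covariates = c("age_months", "sex", "fd_mean"),
                            cluster_by = "site",
                            B = 2000, n_rotations = 2000, alpha = 0.05,
                            spin_target = "SM",
                            power_n_nets = c(DAN = 496, VAN = 253, FPN = 276),
                            seed = 1,
                            connectivity_csv = NULL, cohort_csv = NULL,
                            parcel_tsv = NULL) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, n_subjects = n_subjects, n_cortical = n_cortical,
              n_subcortical = n_subcortical, n_networks = n_networks,
              n_sites = n_sites, prevalence_stim = prevalence_stim,
              from_timeseries = from_timeseries, n_frames = n_frames,
              tr = tr, fd_spike_rate = fd_spike_rate,
              fd_threshold = fd_threshold, min_frames = min_frames,
              truth = truth, interest = interest, covariates = covariates,
              cluster_by = cluster_by, B = B, n_rotations = n_rotations,
              alpha = alpha, spin_target = spin_target,
              power_n_nets = power_n_nets, seed = seed,
              connectivity_csv = connectivity_csv, cohort_csv = cohort_csv,
              parcel_tsv = parcel_tsv)
  if (mode == "ingest" &&
      (is.null(connectivity_csv) || is.null(cohort_csv) || is.null(parcel_tsv))) {
    stop_nla("nla_bad_config",
             "ingest mode needs connectivity_csv, cohort_csv and parcel_tsv")
  }
  stopifnot(cfg$fd_threshold > 0, cfg$B >= 1, cfg$n_rotations >= 1,
            cfg$alpha > 0, cfg$alpha < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full connectome analysis pipeline
#'
#' Executes the stages simulate/ingest -> connectivity -> edgewise fit ->
#' network-level analysis -> brain maps -> spin test -> power table,
#' writing every artifact plus a machine-readable provenance record into
#' `out_dir`. Any stage failure aborts with a stage-tagged error and an
#' `INCOMPLETE` marker file in the run directory.
#'
#' @param config a `"pipeline_config"`.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with the in-memory results: `parcellation`,
#'   `cohort`, `fit`, `nla`, `maps`, `spin`, `power`, `exclusions`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(out_dir, "INCOMPLETE")
  file.create(marker)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_nla("nla_stage_failure",
               sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }
  written <- character(0)
  emit <- function(path) written <<- c(written, path)

  ## ---- simulate / ingest ----
  res <- stage("simulate", {
    if (config$mode == "simulate") {
      parc <- gen_parcellation(config$n_cortical, config$n_subcortical,
                               config$n_networks, seed = config$seed)
      cohort <- gen_cohort(config$n_subjects, n_sites = config$n_sites,
                           prevalence_stim = config$prevalence_stim,
                           seed = config$seed + 1L)
      list(parc = parc, cohort = cohort)
    } else {
      parc <- read_parcel_table(config$parcel_tsv)
      cohort <- utils::read.csv(config$cohort_csv)
      class(cohort) <- c("cohort_design", "data.frame")
      list(parc = parc, cohort = cohort)
    }
  })
  parc <- res$parc; cohort <- res$cohort
  write_parcel_table(parc, file.path(out_dir, "parcels.tsv"))
  emit(file.path(out_dir, "parcels.tsv"))
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  emit(file.path(out_dir, "cohort.csv"))

  ## ---- connectivity ----
  exclusions <- data.frame(subject_id = integer(0), n_retained = integer(0))
  Z <- stage("connectivity", {
    if (config$mode == "ingest") {
      as.matrix(utils::read.csv(config$connectivity_csv, row.names = 1L))
    } else if (config$from_timeseries) {
      ts <- gen_timeseries(cohort, parc, config$truth,
                           n_frames = config$n_frames, tr = config$tr,
                           fd_spike_rate = config$fd_spike_rate,
                           seed = config$seed + 2L)
      rows <- vector("list", length(ts$series))
      keep <- logical(length(ts$series))
      for (s in seq_along(ts$series)) {
        cen <- censor_frames(ts$fd[[s]], config$fd_threshold, config$min_frames)
        if (cen$excluded) {
          exclusions <- rbind(exclusions,
                              data.frame(subject_id = ts$subject_id[s],
                                         n_retained = cen$n_retained))
          next
        }
        keep[s] <- TRUE
        rows[[s]] <- fisher_fc(ts$series[[s]], cen$mask)$z
      }
      cohort <- cohort[keep, , drop = FALSE]
      do.call(rbind, rows[keep])
    } else {
      gen_fc_data(cohort, parc, config$truth, seed = config$seed + 2L)$z
    }
  })
  conn_path <- file.path(out_dir, "connectivity.csv")
  utils::write.csv(data.frame(subject_id = cohort$subject_id, Z,
                              check.names = FALSE),
                   conn_path, row.names = FALSE)
  emit(conn_path)
  utils::write.csv(exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  emit(file.path(out_dir, "exclusions.csv"))

  ## ---- edgewise fit ----
  fit <- stage("fit", {
    design <- build_design(cohort, interest_term = config$interest,
                           covariates = config$covariates,
                           cluster_by = config$cluster_by)
    fit_edgewise(Z, design, B = config$B, seed = config$seed + 3L)
  })
  pr <- edge_pairs(nrow(parc$parcels))
  edge_stats <- data.frame(edge = seq_along(fit$t), i = pr[, "i"],
                           j = pr[, "j"], beta = fit$beta, se = fit$se,
                           t = fit$t, p = fit$p)
  utils::write.csv(edge_stats, file.path(out_dir, "edge_stats.csv"),
                   row.names = FALSE)
  emit(file.path(out_dir, "edge_stats.csv"))

  ## ---- network level analysis ----
  nla <- stage("nla", run_nla(fit, parc, alpha = config$alpha))
  utils::write.csv(nla$pairs, file.path(out_dir, "nla_pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(nla$networks, file.path(out_dir, "nla_networks.csv"),
                   row.names = FALSE)
  emit(file.path(out_dir, "nla_pairs.csv"))
  emit(file.path(out_dir, "nla_networks.csv"))

  ## ---- brain maps ----
  maps <- stage("maps", {
    n_parc <- nrow(parc$parcels)
    rms <- rms_magnitude_map(fit$t, n_parc)
    exemplar <- which.max(rms)
    list(rms = rms, exemplar = exemplar,
         seed = seed_map(fit$t, exemplar, n_parc))
  })
  write_parcel_map(maps$rms, file.path(out_dir, "rms_map.tsv"))
  write_parcel_map(maps$seed, file.path(out_dir, "seed_map.tsv"))
  emit(file.path(out_dir, "rms_map.tsv"))
  emit(file.path(out_dir, "seed_map.tsv"))

  ## ---- spin test ----
  spin <- stage("spin", {
    ref <- gen_reference_map(parc, target_networks = config$spin_target,
                             seed = config$seed + 4L)
    spin_test(maps$rms, ref, parc, N = config$n_rotations,
              seed = config$seed + 5L)
  })
  spin_json <- file.path(out_dir, "spin_result.json")
  jsonlite::write_json(list(r_obs = spin$r_obs, p_two_tailed = spin$p_two_tailed,
                            N = spin$N, mode = spin$mode),
                       spin_json, auto_unbox = TRUE, digits = NA)
  emit(spin_json)
  utils::write.csv(data.frame(r_null = spin$r_null),
                   file.path(out_dir, "spin_null.csv"), row.names = FALSE)
  emit(file.path(out_dir, "spin_null.csv"))

  ## ---- power ----
  power <- stage("power", {
    nul <- welch_null_synthetic(config$power_n_nets, B = config$B,
                                seed = config$seed + 6L)
    power_table(config$power_n_nets, nul)
  })
  utils::write.csv(power, file.path(out_dir, "power_table.csv"),
                   row.names = FALSE)
  emit(file.path(out_dir, "power_table.csv"))

  ## ---- provenance ----
  cfg_plain <- unclass(config)
  cfg_plain$truth <- unclass(cfg_plain$truth)
  prov <- list(
    package = "nlaconn",
    version = as.character(utils::packageVersion("nlaconn")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = cfg_plain,
    seeds = list(parcellation = config$seed, cohort = config$seed + 1L,
                 data = config$seed + 2L, bootstrap = config$seed + 3L,
                 reference_map = config$seed + 4L, spin = config$seed + 5L,
                 power_null = config$seed + 6L),
    outputs = as.list(tools::md5sum(written))
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.remove(marker)
  invisible(list(parcellation = parc, cohort = cohort, fit = fit, nla = nla,
                 maps = maps, spin = spin, power = power,
                 exclusions = exclusions))
}
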