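test_that("zero effects and zero variances reproduce the baseline exactly", {
  p <- gen_parcellation(20, 0, seed = 1)
  co <- gen_cohort(12, n_sites = 3, seed = 2)
  tr <- synthetic_truth(stim = numeric(0), sleep = numeric(0),
                        site_sd = 0, family_sd = 0, noise_sd = 0)
  fc <- gen_fc_data(co, p, tr, seed = 3)
  expect_equal(max(abs(sweep(fc$z, 2, fc$z[1, ]))), 0)
  lab <- nlaconn:::merged_labels(p)
  pr <- edge_pairs(20)
  within <- lab[pr[, "i"]] == lab[pr[, "j"]]
  expect_true(all(fc$z[1, within] == 0.30))
  expect_true(all(fc$z[1, !within] == 0.05))
})

test_that("a planted stimulant effect is recovered as a group mean difference", {
  p <- gen_parcellation(60, 0, seed = 1)
  co <- gen_cohort(2000, prevalence_stim = 0.3, seed = 4)
  tr <- synthetic_truth(stim = c("SM|SM" = -0.030), sleep = numeric(0),
                        site_sd = 0, family_sd = 0, noise_sd = 0.17)
  fc <- gen_fc_data(co, p, tr, seed = 5)
  sel <- fc$beta_stim != 0
  expect_true(any(sel))
  diff <- colMeans(fc$z[co$stimulant == 1, sel, drop = FALSE]) -
    colMeans(fc$z[co$stimulant == 0, sel, drop = FALSE])
  # Monte-Carlo moment check on the average planted edge
  n1 <- sum(co$stimulant); n0 <- sum(!co$stimulant)
  se <- 0.17 * sqrt(1 / n1 + 1 / n0) / sqrt(sum(sel))
  expect_lt(abs(mean(diff) - (-0.030)), 3 * se)
})

test_that("site intercepts induce positive intra-site correlation (ANOVA oracle)", {
  p <- gen_parcellation(12, 0, seed = 1)
  co <- gen_cohort(1200, n_sites = 20, seed = 6)
  tr <- synthetic_truth(stim = numeric(0), sleep = numeric(0),
                        site_sd = 0.08, family_sd = 0, noise_sd = 0.15)
  fc <- gen_fc_data(co, p, tr, seed = 7)
  # one-way ANOVA variance components on a handful of edges
  iccs <- vapply(1:10, function(e) {
    fit <- stats::aov(fc$z[, e] ~ factor(co$site_id))
    ms <- summary(fit)[[1]][["Mean Sq"]]
    nbar <- nrow(co) / 20
    vb <- (ms[1] - ms[2]) / nbar
    vb / (vb + ms[2])
  }, numeric(1))
  expect_gt(mean(iccs), 0.1)   # true ICC = 0.08^2/(0.08^2+0.15^2) ~ 0.22
})

test_that("fc generation is deterministic under a fixed seed", {
  p <- gen_parcellation(16, 4, seed = 1)
  co <- gen_cohort(30, n_sites = 4, seed = 1)
  expect_identical(gen_fc_data(co, p, seed = 11)$z,
                   gen_fc_data(co, p, seed = 11)$z)
})

test_that("unknown effect blocks are rejected", {
  p <- gen_parcellation(16, 0, seed = 1)
  co <- gen_cohort(10, n_sites = 2, seed = 1)
  tr <- synthetic_truth(stim = c("NOPE|SM" = 0.1))
  expect_error(gen_fc_data(co, p, tr, seed = 1), class = "nla_bad_block")
})

test_that("time series recover the target Fisher-Z at the 1/(n-3) rate", {
  p <- gen_parcellation(6, 0, seed = 1)
  co <- gen_cohort(2, n_sites = 2, seed = 2)
  tr <- synthetic_truth(stim = numeric(0), sleep = numeric(0),
                        site_sd = 0, family_sd = 0, noise_sd = 0,
                        baseline_within = 0.5, baseline_between = 0.5)
  n <- 10000
  ts <- gen_timeseries(co, p, tr, n_frames = n, fd_spike_rate = 0, seed = 3)
  cv <- fisher_fc(ts$series[[1]])
  expect_true(all(abs(cv$z - 0.5) < 3 / sqrt(n - 3)))
})

test_that("time series generation is deterministic and flags bad targets", {
  p <- gen_parcellation(6, 0, seed = 1)
  co <- gen_cohort(3, n_sites = 2, seed = 2)
  a <- gen_timeseries(co, p, n_frames = 50, seed = 9)
  b <- gen_timeseries(co, p, n_frames = 50, seed = 9)
  expect_identical(a$series, b$series)
  # an impossible correlation pattern: within-pair r = -0.9 while both
  # members correlate 0.9 with a third parcel
  p3 <- make_parcellation(c("A", "A", "B"))
  tr <- synthetic_truth(stim = numeric(0), sleep = numeric(0),
                        site_sd = 0, family_sd = 0, noise_sd = 0,
                        baseline_within = atanh(-0.9),
                        baseline_between = atanh(0.9))
  expect_error(gen_timeseries(co, p3, tr, n_frames = 20, seed = 1),
               class = "nla_not_posdef")
  # shrinkage is the advertised remedy
  expect_silent(gen_timeseries(co, p3, tr, n_frames = 20, seed = 1,
                               shrinkage = 0.6))
})

test_that("zero spike rate keeps every frame after censoring", {
  p <- gen_parcellation(6, 0, seed = 1)
  co <- gen_cohort(2, n_sites = 2, seed = 2)
  ts <- gen_timeseries(co, p, n_frames = 100, fd_spike_rate = 0, seed = 4)
  cen <- censor_frames(ts$fd[[1]], 0.2, min_frames = 100)
  expect_true(all(cen$mask))
  expect_false(cen$excluded)
})

test_that("reference maps are constant per network at zero noise and reproducible", {
  p <- gen_parcellation(40, 6, seed = 2)
  m0 <- gen_reference_map(p, target_networks = "SM", noise_sd = 0, seed = 1)
  lab <- nlaconn:::merged_labels(p)
  ct <- p$parcels$is_cortical
  expect_true(all(m0[ct & lab == "SM"] == 1))
  expect_true(all(m0[ct & lab != "SM"] == 0))
  expect_true(all(is.na(m0[!ct])))
  m1 <- gen_reference_map(p, "SM", noise_sd = 0.5, seed = 5)
  expect_identical(m1, gen_reference_map(p, "SM", noise_sd = 0.5, seed = 5))
  expect_error(gen_reference_map(p, "NOPE"), class = "nla_bad_block")
})

test_that("reference maps correlate with the RMS map of a matched effect", {
  p <- gen_parcellation(60, 0, seed = 1)
  tr <- synthetic_truth(stim = c("SM|SM" = -0.05), sleep = numeric(0),
                        site_sd = 0.02, family_sd = 0.02, noise_sd = 0.17)
  ref <- gen_reference_map(p, "SM", noise_sd = 0.2, seed = 21)
  cors <- vapply(1:5, function(k) {
    co <- gen_cohort(600, prevalence_stim = 0.3, seed = 30 + k)
    fc <- gen_fc_data(co, p, tr, seed = 40 + k)
    d <- build_design(co)
    f <- fit_marginal(fc$z, d$X)
    se <- cluster_robust_se(d$X, f$residuals, d$cluster_ids,
                            coef_index = d$interest_index)
    rms <- rms_magnitude_map(f$beta[d$interest_index, ] / se[1, ], 60)
    map_correlation(rms, ref, subset = p$parcels$is_cortical)
  }, numeric(1))
  expect_gt(mean(cors) / (sd(cors) / sqrt(5)), 3)
})
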