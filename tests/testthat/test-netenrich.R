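test_that("network merging is a label mapping with conserved counts", {
  raw <- c("premotor", "somatomotor_hand", "somatomotor_mouth",
           "somatomotor_foot", "somatocognitive_action", "auditory")
  merged <- merge_networks(raw)
  expect_equal(merged, c(rep("SM", 5), "AUD"))
  ident <- setNames(raw, raw)
  expect_equal(merge_networks(raw, ident), raw)
  expect_error(merge_networks(c("auditory", "mystery")),
               class = "nla_unmapped_label")
  p <- gen_parcellation(50, 10, seed = 1)
  m <- merge_networks(p)
  expect_equal(nrow(m$parcels), nrow(p$parcels))
  expect_equal(as.vector(table(nlaconn:::merged_labels(p))),
               as.vector(table(m$parcels$network)))
})

test_that("welch_t matches hand arithmetic and its symmetries", {
  # A = {1,2,3}: mean 2, var 1; B = {0,0,0,1}: mean .25, var .25
  # t = 1.75 / sqrt(1/3 + 0.25/4) = 2.78151795
  expect_equal(welch_t(c(1, 2, 3), c(0, 0, 0, 1)), 2.78151795,
               tolerance = 1e-7)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(welch_t(c(0, 0, 0, 1), c(1, 2, 3)), -2.78151795,
               tolerance = 1e-7)
  expect_error(welch_t(c(1, 1), c(1, 1)), class = "nla_zero_variance")
  expect_error(welch_t(1, c(1, 2)), class = "nla_bad_arg")
})

test_that("pair enrichment matches a brute-force oracle on a 3-network toy", {
  p <- make_parcellation(c("A", "A", "B", "B", "C", "C"))
  set.seed(1)
  t_edges <- round(rnorm(n_edges(6)), 2)
  res <- pair_enrichment(t_edges, p)
  expect_equal(nrow(res), 3 * 4 / 2)           # K(K+1)/2 pairs
  lab <- p$parcels$network
  pr <- edge_pairs(6)
  for (r in seq_len(nrow(res))) {
    sel <- (pmin(lab[pr[, 1]], lab[pr[, 2]]) == res$net_a[r]) &
           (pmax(lab[pr[, 1]], lab[pr[, 2]]) == res$net_b[r])
    expect_equal(res$n_edges[r], sum(sel))
    if (sum(sel) >= 2) {
      expect_equal(res$welch_t[r], welch_t(t_edges[sel], t_edges),
                   tolerance = 1e-12)
    } else {
      expect_true(is.na(res$welch_t[r]))
    }
  }
})

test_that("pair edge sets partition the connectome and means aggregate exactly", {
  p <- gen_parcellation(30, 6, seed = 3)
  set.seed(2)
  t_edges <- rnorm(n_edges(36))
  res <- pair_enrichment(t_edges, p)
  expect_equal(sum(res$n_edges), n_edges(36))
  expect_equal(sum(res$n_edges * res$mean_t) / sum(res$n_edges),
               mean(t_edges), tolerance = 1e-12)
})

test_that("equal t-values give zero enrichment everywhere", {
  p <- make_parcellation(c("A", "A", "B", "B"))
  res <- pair_enrichment(rep(1.7, 6), p)
  expect_true(all(res$welch_t[res$n_edges >= 2] == 0))
  nets <- whole_network_enrichment(rep(1.7, 6), p)
  expect_true(all(nets$welch_t == 0))
})

test_that("pair results are invariant to network relabeling", {
  p <- make_parcellation(c("A", "A", "B", "B", "C", "C"))
  q <- make_parcellation(c("Z", "Z", "Y", "Y", "X", "X"))
  set.seed(4)
  t_edges <- rnorm(15)
  a <- pair_enrichment(t_edges, p)
  b <- pair_enrichment(t_edges, q)
  relabel <- c(A = "Z", B = "Y", C = "X")
  key_a <- apply(cbind(relabel[a$net_a], relabel[a$net_b]), 1,
                 function(x) paste(sort(x), collapse = "|"))
  expect_equal(a$welch_t[order(key_a)], b$welch_t[order(b$pair)],
               tolerance = 1e-12)
})

test_that("whole-network enrichment flags inflated |t| and degenerate containment", {
  p <- make_parcellation(c("A", "A", "A", "B", "B", "B"))
  pr <- edge_pairs(6)
  inc_a <- pr[, 1] <= 3 | pr[, 2] <= 3
  set.seed(5)
  t_edges <- rnorm(15, sd = 0.5)
  t_edges[inc_a] <- t_edges[inc_a] + 3 * sign(t_edges[inc_a])
  res <- whole_network_enrichment(t_edges, p)
  expect_gt(res$welch_t[res$network == "A"], 0)
  # a network containing every parcel compares the connectome to itself
  pall <- make_parcellation(rep("ALL", 5))
  res0 <- whole_network_enrichment(rnorm(10), pall)
  expect_equal(res0$welch_t, 0)
  # within-only variant restricts to both-endpoint edges
  resw <- whole_network_enrichment(t_edges, p, edges = "within")
  expect_equal(resw$n_edges, c(3, 3))
})

test_that("Westfall-Young reduces to the simple bootstrap p for one hypothesis", {
  null <- matrix(c(0.5, 1.2, 2.0, 0.1, 3.3), 5, 1)
  obs <- 1.5
  expect_equal(westfall_young_adjust(obs, null),
               mean(abs(null) >= abs(obs)))
})

test_that("Westfall-Young matches exhaustive enumeration on tabulated toys", {
  # m = 2, B = 4 fixture checked against the rank-by-rank oracle
  null <- rbind(c(1.0, 0.5), c(2.5, 1.5), c(0.2, 3.0), c(1.1, 0.9))
  obs <- c(2.0, -1.2)
  expect_equal(westfall_young_adjust(obs, null), oracle_wy(obs, null))
  # larger random fixtures, both alternatives
  set.seed(6)
  for (rep in 1:5) {
    m <- sample(2:5, 1)
    null <- matrix(rnorm(7 * m), 7, m)
    obs <- rnorm(m)
    expect_equal(westfall_young_adjust(obs, null), oracle_wy(obs, null))
  }
})

test_that("adjusted p dominates raw p and is monotone in the ordering", {
  set.seed(7)
  null <- matrix(rnorm(200 * 6), 200, 6)
  obs <- rnorm(6, sd = 1.5)
  adj <- westfall_young_adjust(obs, null)
  raw <- colMeans(sweep(abs(null), 2, abs(obs), ">="))
  expect_true(all(adj >= raw - 1e-12))
  ord <- order(abs(obs), decreasing = TRUE)
  expect_true(all(diff(adj[ord]) >= -1e-12))
  expect_error(westfall_young_adjust(obs, null[, 1:3]), class = "nla_bad_arg")
})

test_that("run_nla ties the pieces together with coherent output", {
  p <- gen_parcellation(30, 0, seed = 2)
  co <- gen_cohort(150, n_sites = 8, prevalence_stim = 0.3, seed = 8)
  fc <- gen_fc_data(co, p, seed = 9)
  f <- fit_edgewise(fc$z, build_design(co), B = 200, seed = 10)
  res <- run_nla(f, p)
  expect_s3_class(res, "nla_result")
  ok <- !is.na(res$pairs$p_fwer)
  expect_true(all(res$pairs$p_fwer[ok] >= res$pairs$p_raw[ok] - 1e-12))
  okn <- !is.na(res$networks$p_fwer)
  expect_true(all(res$networks$p_fwer[okn] >= res$networks$p_raw[okn] - 1e-12))
  # observed pair statistics equal the standalone computation
  expect_equal(res$pairs$welch_t, pair_enrichment(f$t, p)$welch_t)
  f$null_t <- NULL
  expect_error(run_nla(f, p), class = "nla_bad_arg")
})

test_that("the default bootstrap depth for inference is 2,000 iterations", {
  expect_equal(formals(fit_edgewise)$B, 2000)
  expect_equal(formals(wild_bootstrap_null)$B, 2000)
})
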