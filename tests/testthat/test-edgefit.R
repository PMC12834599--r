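test_that("build_design assembles intercept + interest + covariates with clusters", {
  co <- gen_cohort(50, n_sites = 5, seed = 1)
  d <- build_design(co)
  expect_equal(d$coef_names[1], "(Intercept)")
  expect_equal(d$interest_index, 2L)
  expect_equal(ncol(d$X), 5)
  expect_equal(length(d$cluster_ids), 50)
  d2 <- build_design(co, cluster_by = "family")
  expect_equal(d2$cluster_ids, as.character(co$family_id))
  expect_error(build_design(co, covariates = "nope"), class = "nla_bad_design")
})

test_that("a duplicated covariate raises a rank-deficiency error naming it", {
  co <- gen_cohort(40, n_sites = 4, seed = 2)
  co$ses2 <- co$ses
  err <- expect_error(build_design(co, covariates = c("ses", "ses2")),
                      class = "nla_rank_deficient")
  expect_match(conditionMessage(err), "ses2")
})

test_that("OLS matches hand-solved normal equations on a 5-subject toy", {
  # X = [1, x], x = 0..4, y = (1,3,2,5,4):
  # X'X = [[5,10],[10,30]], X'y = [15,38] => beta = (1.4, 0.8) by hand
  X <- cbind(1, 0:4)
  y <- matrix(c(1, 3, 2, 5, 4), 5, 1)
  f <- fit_marginal(y, X)
  expect_equal(as.numeric(f$beta), c(1.4, 0.8), tolerance = 1e-12)
  expect_lt(max(abs(crossprod(X, f$residuals))), 1e-8)
})

test_that("OLS edge cases: exact fit, permutation invariance, n <= p", {
  set.seed(3)
  X <- cbind(1, rnorm(20), rnorm(20))
  Y <- X %*% matrix(rnorm(6), 3, 2)
  f <- fit_marginal(Y, X)
  expect_lt(max(abs(f$residuals)), 1e-10)
  Y2 <- Y + matrix(rnorm(40), 20, 2)
  perm <- sample(20)
  expect_equal(fit_marginal(Y2, X)$beta,
               fit_marginal(Y2[perm, ], X[perm, ])$beta, tolerance = 1e-10)
  expect_error(fit_marginal(Y2[1:3, ], X[1:3, ]), class = "nla_bad_design")
})

test_that("binary predictor coefficient is the adjusted group difference", {
  co <- gen_cohort(200, n_sites = 5, prevalence_stim = 0.4, seed = 4)
  d <- build_design(co, covariates = character(0))
  set.seed(5)
  y <- matrix(rnorm(200) + 0.5 * co$stimulant, 200, 1)
  f <- fit_marginal(y, d$X)
  expect_equal(f$beta[d$interest_index, 1],
               mean(y[co$stimulant == 1, ]) - mean(y[co$stimulant == 0, ]),
               tolerance = 1e-10)
})

test_that("cluster-robust SEs match the explicit summation oracle to 1e-10", {
  set.seed(6)
  n <- 15
  X <- cbind(1, rnorm(n))
  cl <- rep(c("a", "b", "c"), each = 5)
  e <- matrix(rnorm(n * 3), n, 3)
  for (type in c("CR0", "CR1")) {
    se <- cluster_robust_se(X, e, cl, small_sample = type)
    for (edge in 1:3) {
      V <- oracle_cluster_vcov(X, e[, edge], cl, type)
      expect_equal(se[, edge], sqrt(diag(V)), tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
})

test_that("cluster-robust SEs agree with sandwich::vcovCL", {
  skip_if_not_installed("sandwich")
  set.seed(7)
  n <- 60
  x <- rnorm(n)
  cl <- sample(letters[1:6], n, replace = TRUE)
  y <- 0.3 * x + rnorm(n)
  m <- lm(y ~ x)
  se0 <- cluster_robust_se(model.matrix(m), matrix(resid(m)), cl, "CR0")
  expect_equal(as.numeric(se0),
               sqrt(diag(sandwich::vcovCL(m, cluster = cl, type = "HC0",
                                          cadjust = FALSE))),
               tolerance = 1e-10, ignore_attr = TRUE)
  se1 <- cluster_robust_se(model.matrix(m), matrix(resid(m)), cl, "CR1")
  expect_equal(as.numeric(se1),
               sqrt(diag(sandwich::vcovCL(m, cluster = cl, type = "HC1",
                                          cadjust = TRUE))),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("singleton clusters reduce CR0 to HC0", {
  set.seed(8)
  n <- 25
  X <- cbind(1, rnorm(n))
  e <- matrix(rnorm(n), n, 1)
  se <- cluster_robust_se(X, e, as.character(1:n), "CR0")
  A <- solve(crossprod(X))
  hc0 <- sqrt(diag(A %*% t(X) %*% diag(as.numeric(e)^2) %*% X %*% A))
  expect_equal(as.numeric(se), hc0, tolerance = 1e-10)
  expect_error(cluster_robust_se(X, e, rep("one", n)),
               class = "nla_single_cluster")
})

test_that("robust and classical SEs agree under independent homoskedastic noise", {
  set.seed(9)
  n <- 2000
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  cl <- seq_len(n)          # singleton clusters: no dependence to absorb
  Y <- matrix(rnorm(n * 20), n, 20)
  f <- fit_marginal(Y, X)
  se_r <- cluster_robust_se(X, f$residuals, cl, "CR1", coef_index = 2L)
  sigma2 <- colSums(f$residuals^2) / (n - 3)
  se_c <- sqrt(solve(crossprod(X))[2, 2] * sigma2)
  ratio <- se_r[1, ] / se_c
  expect_true(all(ratio > 0.9 & ratio < 1.1))
})

test_that("wild bootstrap with all +1 weights reproduces the observed t", {
  # v = +1 for every cluster gives y* = y exactly
  set.seed(10)
  n <- 40
  X <- cbind(1, rnorm(n), rnorm(n))
  cl <- rep(1:5, each = 8)
  Y <- matrix(rnorm(n * 4), n, 4)
  f <- fit_marginal(Y, X)
  se <- cluster_robust_se(X, f$residuals, cl, coef_index = 2L)
  t_obs <- f$beta[2, ] / se[1, ]
  nul <- wild_bootstrap_null(Y, X, interest_index = 2L, cluster_ids = cl,
                             B = 1, weights = matrix(1, 1, 5))
  expect_equal(as.numeric(nul$null_t), t_obs, tolerance = 1e-10)
})

test_that("closed-form bootstrap equals the literal refit oracle", {
  set.seed(11)
  n <- 30
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  cl <- sample(letters[1:4], n, replace = TRUE)
  Y <- matrix(rnorm(n * 5), n, 5)
  V <- matrix(sample(c(-1, 1), 20 * 4, replace = TRUE), 20, 4)
  nul <- wild_bootstrap_null(Y, X, interest_index = 2L, cluster_ids = cl,
                             B = 20, weights = V)
  oracle <- oracle_wild_bootstrap(Y, X, 2L, cl, V)
  expect_equal(nul$null_t, oracle, tolerance = 1e-10)
})

test_that("bootstrap null is centred and deterministic; signs shared across edges", {
  set.seed(12)
  n <- 300
  X <- cbind(1, rbinom(n, 1, 0.3))
  cl <- sample(12, n, replace = TRUE)
  Y <- matrix(rnorm(n * 50), n, 50)
  a <- wild_bootstrap_null(Y, X, 2L, cl, B = 500, seed = 3)
  b <- wild_bootstrap_null(Y, X, 2L, cl, B = 500, seed = 3)
  expect_identical(a$null_t, b$null_t)
  expect_lt(abs(mean(a$null_t)), 3 * sd(a$null_t) / sqrt(500))
  # duplicated outcome columns must produce identical null columns,
  # which only holds if every edge shares the replicate's cluster signs
  Y2 <- cbind(Y[, 1], Y[, 1])
  n2 <- wild_bootstrap_null(Y2, X, 2L, cl, B = 50, seed = 4)
  expect_equal(n2$null_t[, 1], n2$null_t[, 2], tolerance = 1e-12)
})

test_that("restricted-model rank deficiency is caught", {
  X <- cbind(1, rnorm(10), 1)  # dropping col 2 leaves duplicate intercepts
  expect_error(wild_bootstrap_null(matrix(rnorm(10)), X, 2L,
                                   rep(1:2, 5), B = 2),
               class = "nla_rank_deficient")
})

test_that("bootstrap p-values follow the counting convention", {
  null_t <- matrix(c(1.0, 2.5, 0.5, 3.0), 4, 1)
  expect_equal(edgewise_pvalues(2.0, null_t), 0.5)   # 2 of 4 at least as extreme
  expect_equal(edgewise_pvalues(0, null_t), 1)
  expect_equal(edgewise_pvalues(10, null_t), 0)
  expect_equal(edgewise_pvalues(10, null_t, method = "plus_one"), 0.2)
})

test_that("cluster-robust inference is calibrated where naive OLS is not", {
  # strong site clustering with a site-level predictor: the worst case
  # for naive SEs
  set.seed(13)
  n <- 200; G <- 20; E <- 500
  site <- rep(1:G, each = n / G)
  x <- rnorm(G)[site]
  X <- cbind(1, x)
  Y <- matrix(rnorm(G * E, sd = 0.5), G, E)[site, ] + matrix(rnorm(n * E), n, E)
  f <- fit_marginal(Y, X)
  # naive classical OLS p-values
  sigma2 <- colSums(f$residuals^2) / (n - 2)
  se_c <- sqrt(solve(crossprod(X))[2, 2] * sigma2)
  p_naive <- 2 * pt(-abs(f$beta[2, ] / se_c), df = n - 2)
  expect_gt(mean(p_naive < 0.05), 0.07)          # anti-conservative
  se_r <- cluster_robust_se(X, f$residuals, site, coef_index = 2L)
  t_r <- f$beta[2, ] / se_r[1, ]
  nul <- wild_bootstrap_null(Y, X, 2L, site, B = 500, seed = 5)
  p_r <- edgewise_pvalues(t_r, nul)
  expect_gt(mean(p_r < 0.05), 0.03)
  expect_lt(mean(p_r < 0.05), 0.07)
})

test_that("fit_edgewise wraps the pieces consistently", {
  p <- gen_parcellation(12, 0, seed = 1)
  co <- gen_cohort(80, n_sites = 8, prevalence_stim = 0.3, seed = 14)
  fc <- gen_fc_data(co, p, seed = 15)
  d <- build_design(co)
  f <- fit_edgewise(fc$z, d, B = 100, seed = 16)
  expect_equal(dim(f$null_t), c(100, n_edges(12)))
  expect_equal(f$t, f$beta / f$se, tolerance = 1e-12)
  expect_equal(formals(fit_edgewise)$B, 2000)
  expect_true(all(f$p >= 0 & f$p <= 1))
})
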