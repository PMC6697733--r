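test_that("slr_test reproduces exact fits and agrees with lm()", {
  # 3-point exact line y = 1 + 2x needs m >= 4: extend with a 4th point on
  # the same line, still residual-free
  x <- c(0, 1, 2, 3); y <- 1 + 2 * x
  fit <- slr_test(y, x, "gexact")
  expect_equal(fit$beta, 2, tolerance = 1e-12)
  expect_equal(fit$beta0, 1, tolerance = 1e-12)
  expect_equal(fit$p_value, 1e-300)        # perfect fit clamps p

  # y identical to x: slope 1, p at the clamp
  fit2 <- slr_test(x, x)
  expect_equal(fit2$beta, 1, tolerance = 1e-12)
  expect_equal(fit2$p_value, 1e-300)

  # cross-check against stats::lm on noisy data
  set.seed(10)
  xr <- rnorm(50); yr <- 0.3 + 0.7 * xr + rnorm(50)
  ours <- slr_test(yr, xr)
  ref <- summary(lm(yr ~ xr))$coefficients
  expect_equal(ours$beta, ref["xr", "Estimate"], tolerance = 1e-10)
  expect_equal(ours$se, ref["xr", "Std. Error"], tolerance = 1e-10)
  expect_equal(ours$p_value, ref["xr", "Pr(>|t|)"], tolerance = 1e-10)
  expect_equal(ours$statistic, ours$beta / ours$se, tolerance = 1e-10)

  expect_error(slr_test(yr, rep(1, 50), "gflat"), "gflat")
  expect_error(slr_test(c(1, 2, 3), c(1, 2, 3)), "4 samples")
})

test_that("SLR null calibration: rejection rate near alpha on independent data", {
  set.seed(2024)
  m <- 2000L
  y <- setNames(rnorm(m), sprintf("S%04d", 1:m))
  X <- matrix(rnorm(m * 1000L), m, 1000L,
              dimnames = list(names(y), sprintf("g%04d", 1:1000)))
  res <- association_scan(X, y, method = "slr")
  rate <- mean(res$p_value < 0.05)
  expect_gte(rate, 0.03); expect_lte(rate, 0.07)
})

test_that("spectral variance-component fit matches a brute-force 2-D grid oracle", {
  set.seed(31)
  for (rep in 1:5) {
    m <- 12L
    K <- random_kinship(m, seed = 300L + rep)
    y <- draw_mvn_phenotype(K, sg2 = 1, se2 = 1, beta0 = 0.5)
    fit <- fit_null_variance_components(y, K)
    oracle <- oracle_vc_grid(y, K)
    scale_tol <- 1e-3 * (oracle$sigma_g2 + oracle$sigma_e2)
    expect_lt(abs(fit$sigma_g2 - oracle$sigma_g2), scale_tol)
    expect_lt(abs(fit$sigma_e2 - oracle$sigma_e2), scale_tol)
    # likelihood at the spectral optimum at least matches the oracle's
    ll_spec <- oracle_null_loglik(y, K, fit$sigma_g2,
                                  max(fit$sigma_e2, 1e-12))
    expect_gte(ll_spec, oracle$log_likelihood - 1e-6)
  }
})

test_that("variance components: boundary behaviour and parameter recovery", {
  # iid phenotype: fitted structured component collapses toward zero in the
  # majority of replicates
  set.seed(77)
  m <- 100L
  K <- random_kinship(m, seed = 8L)
  eg <- eigen(K, symmetric = TRUE)
  hits <- 0L
  for (i in 1:50) {
    y <- rnorm(m)
    vc <- fit_null_variance_components(y, K, eigen_K = eg)
    if (vc$sigma_g2 < 0.05 * vc$sigma_e2) hits <- hits + 1L
  }
  expect_gt(hits, 25L)

  # data simulated at variance ratio 0.5 recovers the ratio on average
  set.seed(88)
  K5 <- compute_kinship(standardize_expression(
    simulate_dataset(simulation_config(m = 500L, n = 1000L,
                                       n_confounded = 200L,
                                       module_sizes = 100L,
                                       seed = 5L))$expr))
  eg5 <- eigen(K5, symmetric = TRUE)
  ratios <- vapply(1:30, function(i) {
    y <- draw_mvn_phenotype(K5, sg2 = 1, se2 = 1)
    fit_null_variance_components(y, K5, eigen_K = eg5)$heritability
  }, 0)
  expect_lt(abs(mean(ratios) - 0.5), 0.05)

  # likelihood at the optimum is never below the iid boundary model
  y <- draw_mvn_phenotype(K, sg2 = 2, se2 = 0.5)
  vc <- fit_null_variance_components(y, K, eigen_K = eg)
  ll_boundary <- -0.5 * (m * log(2 * pi) +
                           m * log(mean((y - mean(y))^2)) + m)
  expect_gte(vc$log_likelihood, ll_boundary - 1e-6)
})

test_that("lmm_test equals the dense-matrix GLS formula and is sign-equivariant", {
  set.seed(12)
  m <- 8L
  K <- random_kinship(m, seed = 41L)
  y <- draw_mvn_phenotype(K, 1, 0.7)
  x <- rnorm(m)
  vc <- fit_null_variance_components(y, K)
  V <- vc$sigma_g2 * K + vc$sigma_e2 * diag(m)
  ref <- oracle_gls_dense(y, x, V)
  ours <- lmm_test(y, x, vc)
  expect_lt(abs(ours$beta - ref$beta), 1e-10)
  expect_lt(abs(ours$beta0 - ref$beta0), 1e-10)
  expect_lt(abs(ours$se - ref$se), 1e-10)

  # the published /n covariance variant scales the se by sqrt(m)
  ours_pv <- lmm_test(y, x, vc, paper_variance = TRUE)
  expect_equal(ours_pv$se, ours$se / sqrt(m), tolerance = 1e-10)

  neg <- lmm_test(y, -x, vc)
  expect_equal(neg$beta, -ours$beta, tolerance = 1e-12)
  expect_equal(neg$statistic, -ours$statistic, tolerance = 1e-12)
  expect_equal(neg$p_value, ours$p_value, tolerance = 1e-12)
})

test_that("with sigma_g2 = 0 the LMM reduces to OLS, Wald ~ t for large m", {
  set.seed(9)
  m <- 500L
  ids <- sprintf("S%03d", 1:m)
  X <- matrix(rnorm(m * 50L), m, 50L,
              dimnames = list(ids, sprintf("g%03d", 1:50)))
  y <- setNames(rnorm(m), ids)
  K <- compute_kinship(standardize_expression(X))
  vc <- fit_null_variance_components(as.numeric(y), unname(K))
  vc$sigma_g2 <- 0
  vc$sigma_e2 <- mean((y - mean(y))^2)
  lmm <- association_scan(X, y, method = "lmm", vc = vc)
  slr <- association_scan(X, y, method = "slr")
  expect_equal(lmm$beta, slr$beta, tolerance = 1e-10)
  expect_lt(max(abs(lmm$p_value - slr$p_value)), 1e-3)
})

test_that("scan is order-independent and the rotated path equals dense GLS per gene", {
  ds <- small_sim(seed = 61L)
  K <- compute_kinship(standardize_expression(ds$expr))
  res <- suppressMessages(
    association_scan(ds$expr, ds$y, method = "lmm", K = K))
  expect_equal(res$statistic, res$beta / res$se, tolerance = 1e-10)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))

  # permuting gene columns leaves each per-gene result unchanged
  set.seed(4)
  perm <- sample(ncol(ds$expr))
  res_perm <- suppressMessages(
    association_scan(ds$expr[, perm], ds$y, method = "lmm", K = K))
  ord <- match(res$gene, res_perm$gene)
  expect_equal(res_perm$beta[ord], res$beta, tolerance = 1e-12)
  expect_equal(res_perm$p_value[ord], res$p_value, tolerance = 1e-12)

  # EMMAX equivalence: rotated O(m) result equals dense GLS for a sample of
  # genes
  vc <- attr(res, "vc")
  V <- vc$sigma_g2 * unname(K) + vc$sigma_e2 * diag(nrow(K))
  for (g in sample(res$gene, 5)) {
    ref <- oracle_gls_dense(as.numeric(ds$y), ds$expr[, g], V)
    row <- res[res$gene == g, ]
    expect_equal(row$beta, ref$beta, tolerance = 1e-8)
    expect_equal(row$se, ref$se, tolerance = 1e-8)
  }

  # zero-variance gene is skipped, not an error
  X2 <- cbind(ds$expr, gconst = rep(1, nrow(ds$expr)))
  expect_message(res2 <- association_scan(X2, ds$y, method = "slr"),
                 "zero-variance")
  expect_false("gconst" %in% res2$gene)

  expect_error(association_scan(ds$expr[1:5, ], ds$y[1:5], method = "slr"),
               "fewer than 10")
})

test_that("confounded null genes are rejected by SLR but controlled by the full-K LMM", {
  ds <- small_sim(seed = 71L)
  conf <- ds$truth$gene[ds$truth$class == "confounded"]
  slr <- suppressMessages(association_scan(ds$expr, ds$y, method = "slr"))
  K <- compute_kinship(standardize_expression(ds$expr))
  lmm <- suppressMessages(association_scan(ds$expr, ds$y, method = "lmm",
                                           K = K))
  rate_slr <- mean(slr$p_value[slr$gene %in% conf] < 0.05)
  rate_lmm <- mean(lmm$p_value[lmm$gene %in% conf] < 0.05)
  expect_gt(rate_slr, 0.25)
  expect_lt(rate_lmm, 0.15)   # smaller cohort than the acceptance setting
  # depleted K restores the spurious associations
  K_dep <- suppressMessages(compute_kinship_excluding(ds$expr, conf))
  dep <- suppressMessages(association_scan(ds$expr, ds$y, method = "lmm",
                                           K = K_dep))
  expect_gt(mean(dep$p_value[dep$gene %in% conf] < 0.05), 0.2)
})

test_that("per-gene variance refit stays close to the EMMAX approximation on null genes", {
  ds <- small_sim(seed = 81L)
  sub <- ds$expr[, c(1:3, 381:400)]    # few confounded + null genes
  K <- compute_kinship(standardize_expression(ds$expr))
  fixed <- suppressMessages(
    association_scan(sub, ds$y, method = "lmm", K = K))
  refit <- suppressMessages(
    association_scan(sub, ds$y, method = "lmm", K = K,
                     refit_per_gene = TRUE))
  expect_equal(refit$beta, fixed$beta, tolerance = 0.2)
  expect_gt(cor(refit$statistic, fixed$statistic), 0.98)
})
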