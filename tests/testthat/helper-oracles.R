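# Fixture builders and independent brute-force oracles used across tests.

# --- fixture builders -------------------------------------------------------

make_seg_file <- function(lines, path = tempfile(fileext = ".seg")) {
  writeLines(lines, path)
  path
}

make_expr_file <- function(mat, path = tempfile(fileext = ".tsv"),
                           orientation = "samples") {
  m <- if (orientation == "genes") t(mat) else mat
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

random_expr <- function(m, n, seed = 1L, prefix = "g") {
  set.seed(seed)
  matrix(rnorm(m * n), m, n,
         dimnames = list(sprintf("S%03d", seq_len(m)),
                         sprintf("%s%04d", prefix, seq_len(n))))
}

make_segmented_sample <- function(id, start, end, value, chrom = "1") {
  structure(list(sample_id = id,
                 segments = data.frame(chrom = chrom, start = start,
                                       end = end, num_markers = NA_real_,
                                       seg_value = value,
                                       stringsAsFactors = FALSE)),
            class = "segmented_sample")
}

# random kinship built the same way the package builds it, but from scratch
random_kinship <- function(m, n_genes = 3L * m, seed = 1L) {
  Z <- random_expr(m, n_genes, seed = seed)
  Z <- scale(Z) * sqrt(m / (m - 1))          # population standardization
  K <- tcrossprod(Z) / n_genes
  (K + t(K)) / 2
}

# draw y from N(beta0*1, sg2*K + se2*I)
draw_mvn_phenotype <- function(K, sg2, se2, beta0 = 0) {
  m <- nrow(K)
  eg <- eigen(K, symmetric = TRUE)
  d <- sqrt(pmax(eg$values, 0) * sg2 + se2)
  beta0 + drop(eg$vectors %*% (d * rnorm(m)))
}

# --- brute-force oracles ----------------------------------------------------

# dense evaluation of the printed null log-likelihood, intercept profiled
# out by GLS at the given variance components
oracle_null_loglik <- function(y, K, sg2, se2) {
  m <- length(y)
  V <- sg2 * K + se2 * diag(m)
  Vi <- solve(V)
  one <- rep(1, m)
  b0 <- drop((t(one) %*% Vi %*% y) / (t(one) %*% Vi %*% one))
  r <- y - b0 * one
  -0.5 * (m * log(2 * pi) + determinant(V)$modulus[1] +
            drop(t(r) %*% Vi %*% r))
}

# direct 2-D grid maximization of the null likelihood over (sg2, se2),
# iteratively zoomed; independent of the spectral path. Because K is
# singular (K 1 = 0) and the intercept absorbs the null direction, the
# likelihood is unbounded as se2 -> 0, so (like the estimator itself, whose
# design fixes the search to the variance ratio se2/sg2 in [1e-5, 1e5]) the
# grid maximizes over that same closed region, plus the iid boundary model
# sg2 = 0.
oracle_vc_grid <- function(y, K, n_grid = 49L, n_zoom = 8L) {
  m <- length(y)
  vy <- mean((y - mean(y))^2)
  ok_ratio <- function(sg2, se2) {
    sg2 > 0 && se2 / sg2 >= 1e-5 && se2 / sg2 <= 1e5
  }
  # log-scale grid: the edge optimum can sit at se2 ~ 1e-5 * sg2, which a
  # linear grid cannot resolve
  lo <- log10(c(1e-4 * vy, 1e-8 * vy))
  hi <- log10(c(10 * vy, 10 * vy))
  best <- c(NA, NA)
  for (z in seq_len(n_zoom)) {
    gs <- 10^seq(lo[1], hi[1], length.out = n_grid)
    es <- 10^seq(lo[2], hi[2], length.out = n_grid)
    ll <- matrix(-Inf, n_grid, n_grid)
    for (i in seq_len(n_grid)) for (j in seq_len(n_grid)) {
      if (!ok_ratio(gs[i], es[j])) next
      ll[i, j] <- oracle_null_loglik(y, K, gs[i], es[j])
    }
    ij <- arrayInd(which.max(ll), dim(ll))
    best <- c(gs[ij[1]], es[ij[2]])
    # generous re-centering window: the (sg2, se2) likelihood has a narrow
    # diagonal valley and a tight window strands the zoom inside it
    step <- c((hi[1] - lo[1]) / (n_grid - 1), (hi[2] - lo[2]) / (n_grid - 1))
    lo <- log10(best) - 6 * step
    hi <- log10(best) + 6 * step
  }
  out <- list(sigma_g2 = best[1], sigma_e2 = best[2],
              log_likelihood = oracle_null_loglik(y, K, best[1], best[2]))
  # iid boundary candidate sg2 = 0 with its ML variance
  ll0 <- -0.5 * (m * log(2 * pi) + m * log(vy) + m)
  if (ll0 >= out$log_likelihood)
    out <- list(sigma_g2 = 0, sigma_e2 = vy, log_likelihood = ll0)
  out
}

# dense-matrix GLS of y on [1, x] under V, with the residual scale
# re-estimated from the GLS residuals (same estimator the package defines)
oracle_gls_dense <- function(y, x, V) {
  m <- length(y)
  X <- cbind(1, x)
  Vi <- solve(V)
  A <- solve(t(X) %*% Vi %*% X)
  beta <- drop(A %*% t(X) %*% Vi %*% y)
  r <- y - drop(X %*% beta)
  scale <- drop(t(r) %*% Vi %*% r) / (m - 2L)
  cov <- scale * A
  list(beta0 = unname(beta[1]), beta = unname(beta[2]), cov = unname(cov),
       se = sqrt(unname(cov[2, 2])))
}

# naive O(N * |set|) running-sum enrichment score
oracle_es <- function(genes_ranked, metric, set, p = 1) {
  N <- length(genes_ranked)
  hit <- genes_ranked %in% set
  nh <- sum(hit)
  nm <- N - nh
  w <- abs(metric)^p
  tot <- sum(w[hit])
  if (tot <= 0) { w[hit] <- 1; tot <- nh }
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) cur + w[i] / tot else cur - (if (nm > 0) 1 / nm else 0)
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

# shared small synthetic dataset for the cheaper module tests
small_sim <- function(seed = 11L) {
  simulate_dataset(simulation_config(
    m = 200L, n = 400L, n_confounded = 80L, module_sizes = 60L,
    n_causal_independent = 3L, n_causal_in_module = 3L, seed = seed))
}
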