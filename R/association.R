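#' Simple linear regression association test for one gene
#'
#' Fits `y = beta0 + beta1 * x + e` by ordinary least squares and tests
#' `beta1 = 0` with a two-sided t-test on m - 2 degrees of freedom. This is
#' the model used by conventional expression-vs-aneuploidy association
#' studies; it makes no correction for inter-sample structure.
#'
#' @param y Numeric phenotype vector (e.g. ICNA scores), same order as `x`.
#' @param x Numeric expression vector for one gene.
#' @param gene_id Label carried into the result.
#' @return One-row data frame: `gene`, `beta0`, `beta`, `se`, `statistic`,
#'   `p_value`, `method = "SLR"`.
#' @export
slr_test <- function(y, x, gene_id = "gene") {
  m <- length(y)
  if (length(x) != m) stop("x and y lengths differ")
  if (m < 4L) stop("SLR test needs at least 4 samples")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 1e-18 * m)
    stop("gene '", gene_id, "' has zero variance; cannot test")
  xc <- x - mean(x); yc <- y - mean(y)
  beta <- sum(xc * yc) / sxx
  beta0 <- mean(y) - beta * mean(x)
  rss <- sum((yc - beta * xc)^2)
  df <- m - 2L
  se <- sqrt(max(rss, 0) / df / sxx)
  if (se == 0) {
    stat <- sign(beta) * Inf
    p <- 1e-300
  } else {
    stat <- beta / se
    p <- max(2 * pt(-abs(stat), df), 1e-300)
  }
  data.frame(gene = gene_id, beta0 = beta0, beta = beta, se = se,
             statistic = stat, p_value = p, method = "SLR",
             stringsAsFactors = FALSE)
}

# profile log-likelihood machinery in the eigenbasis of K.
# For V = sg2 K + se2 I and delta = se2/sg2, rotating by the eigenvectors U of
# K diagonalizes V: V = sg2 * U diag(s + delta) U'. With the intercept
# profiled out by GLS and sg2 profiled analytically, the ML problem reduces to
# a 1-D search over delta.
.null_profile <- function(delta, s, t1, ty, m) {
  w <- 1 / (s + delta)
  b0 <- sum(w * t1 * ty) / sum(w * t1 * t1)
  r <- ty - b0 * t1
  sg2 <- sum(w * r * r) / m
  ll <- -0.5 * (m * log(2 * pi) + m * log(sg2) + sum(log(s + delta)) + m)
  list(ll = ll, sg2 = sg2, beta0 = b0)
}

#' Fit null-model variance components by maximum likelihood
#'
#' Fits the intercept-only mixed model `y = beta0 1 + u + e`,
#' `u ~ N(0, sg2 K)`, `e ~ N(0, se2 I)`, by maximizing the multivariate
#' normal log-likelihood
#' `-(1/2) [ m log(2 pi) + log|V| + (y - beta0 1)' V^-1 (y - beta0 1) ]`
#' with `V = sg2 K + se2 I` (full ML, not REML; the intercept is profiled out
#' by GLS at each candidate). One eigendecomposition of K reduces the search
#' to the variance ratio `delta = se2 / sg2`, optimized on a 100-point
#' log-spaced grid over \[1e-5, 1e5\] with golden-section refinement to 1e-8
#' relative precision; the boundary solution `sg2 = 0` is also evaluated and
#' reported when it attains the maximum (ties resolved toward the larger
#' residual variance).
#'
#' @param y Named numeric phenotype vector.
#' @param K Kinship matrix from [compute_kinship()], with sample ids matching
#'   `names(y)` in the same order.
#' @param eigen_K Optional precomputed `eigen(K, symmetric = TRUE)`.
#' @return Object of class `"variance_components"`: list with `sigma_g2`,
#'   `sigma_e2`, `delta`, `log_likelihood`, `heritability`
#'   (`sg2 / (sg2 + se2)`), `beta0`, `m`, `boundary` flag and the cached
#'   `eigen` decomposition (reused by [lmm_test()] / [association_scan()]).
#' @export
fit_null_variance_components <- function(y, K, eigen_K = NULL) {
  m <- length(y)
  if (nrow(K) != m || ncol(K) != m) stop("K dimensions do not match y")
  if (!is.null(names(y)) && !is.null(rownames(K)) &&
      !identical(names(y), rownames(K)))
    stop("sample ids of y and K differ or are ordered differently; ",
         "join them explicitly before fitting")
  if (var(y) <= 0) stop("phenotype has zero variance")
  if (is.null(eigen_K)) eigen_K <- eigen(K, symmetric = TRUE)
  s <- pmax(eigen_K$values, 0)   # clamp tiny negative eigenvalues
  U <- eigen_K$vectors
  ty <- drop(crossprod(U, y))
  t1 <- drop(crossprod(U, rep(1, m)))

  grid <- 10^seq(-5, 5, length.out = 100L)
  lls <- vapply(grid, function(d) .null_profile(d, s, t1, ty, m)$ll, 0)
  if (all(!is.finite(lls)))
    stop("likelihood non-finite at every grid point; check K and y")
  i <- which.max(lls)
  lo <- log10(grid[max(i - 1L, 1L)])
  hi <- log10(grid[min(i + 1L, length(grid))])
  opt <- optimize(function(ld) .null_profile(10^ld, s, t1, ty, m)$ll,
                  interval = c(lo, hi), maximum = TRUE, tol = 1e-9)
  delta <- 10^opt$maximum
  fit <- .null_profile(delta, s, t1, ty, m)

  # boundary model sg2 = 0: iid residuals, ML variance with denominator m
  se2_0 <- mean((y - mean(y))^2)
  ll_0 <- -0.5 * (m * log(2 * pi) + m * log(se2_0) + m)
  boundary <- ll_0 >= fit$ll - 1e-10   # ties go to the larger se2 (iid) model
  if (boundary) {
    out <- list(sigma_g2 = 0, sigma_e2 = se2_0, delta = Inf,
                log_likelihood = ll_0, heritability = 0, beta0 = mean(y))
  } else {
    out <- list(sigma_g2 = fit$sg2, sigma_e2 = fit$sg2 * delta, delta = delta,
                log_likelihood = fit$ll,
                heritability = 1 / (1 + delta), beta0 = fit$beta0)
  }
  out$m <- m
  out$boundary <- boundary
  out$eigen <- list(values = s, vectors = U)
  class(out) <- "variance_components"
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (ML):\n",
      sprintf("  sigma_g2 = %.6g\n  sigma_e2 = %.6g\n", x$sigma_g2,
              x$sigma_e2),
      sprintf("  heritability analog = %.4f\n  logLik = %.4f  (m = %d%s)\n",
              x$heritability, x$log_likelihood, x$m,
              if (x$boundary) ", boundary sg2 = 0" else ""), sep = "")
  invisible(x)
}

#' Mixed-model association test for one gene
#'
#' Tests `beta1 = 0` in `y = beta0 1 + beta1 x + u + e` with the variance
#' components held at their null-model ML estimates (EMMAX-style: components
#' are fitted once under the null and reused for every gene). The fixed
#' effects are estimated by generalized least squares,
#' `beta_hat = (X' V^-1 X)^-1 X' V^-1 y`, and the Wald statistic
#' `beta1 / se(beta1)` is referred to a standard normal. Computation is done
#' in the eigenbasis of K, so the per-gene cost is O(m) after rotation.
#'
#' The covariance is `sigma_hat^2 (X' V^-1 X)^-1`, the GLS covariance with
#' the correlation structure of V held at the null fit and the residual scale
#' `sigma_hat^2` re-estimated per gene from the GLS residuals (denominator
#' m - 2). This is standard mixed-model GWAS practice and makes the test
#' collapse exactly onto the OLS t-test when `sigma_g2 = 0`.
#' `paper_variance = TRUE` additionally divides the covariance by the sample
#' count, reproducing a published variant of the asymptotic formula (it
#' shrinks standard errors by sqrt(m) and is provided for reproducibility
#' only).
#'
#' @param y Numeric phenotype vector.
#' @param x Numeric expression vector for one gene.
#' @param vc `"variance_components"` fitted on this `y` and K by
#'   [fit_null_variance_components()].
#' @param gene_id Label carried into the result.
#' @param paper_variance Use the `(X'V^-1X)^-1 / m` covariance variant.
#' @return One-row data frame: `gene`, `beta0`, `beta`, `se`, `statistic`,
#'   `p_value`, `method = "LMM"`.
#' @export
lmm_test <- function(y, x, vc, gene_id = "gene", paper_variance = FALSE) {
  if (!inherits(vc, "variance_components"))
    stop("vc must come from fit_null_variance_components()")
  m <- vc$m
  if (length(y) != m || length(x) != m) stop("y/x length does not match vc")
  d <- vc$sigma_g2 * vc$eigen$values + vc$sigma_e2
  if (any(d <= 0)) stop("V is numerically singular (sigma_e2 = 0 with ",
                        "singular K)")
  U <- vc$eigen$vectors
  tx <- drop(crossprod(U, x))
  res <- .gls_rotated(drop(crossprod(U, y)), tx,
                      drop(crossprod(U, rep(1, m))), 1 / d,
                      if (paper_variance) m else 1L)
  data.frame(gene = gene_id, beta0 = res$beta0, beta = res$beta,
             se = res$se, statistic = res$stat, p_value = res$p,
             method = "LMM", stringsAsFactors = FALSE)
}

# GLS of y on [1, x] in a basis where V is diagonal with weights w = 1/d.
# The covariance keeps the correlation structure of V but re-estimates the
# residual scale per gene from the GLS residuals (denominator m - 2), the
# standard mixed-model GWAS practice: with sg2 = 0 the test then reduces
# exactly to OLS. var_div = 1 normally; = m for the published /n variant.
.gls_rotated <- function(ty, tx, t1, w, var_div = 1L) {
  m <- length(ty)
  a11 <- sum(w * t1 * t1); a12 <- sum(w * t1 * tx); a22 <- sum(w * tx * tx)
  b1 <- sum(w * t1 * ty); b2 <- sum(w * tx * ty)
  det <- a11 * a22 - a12 * a12
  if (det <= 0) stop("design is singular under V (zero-variance gene?)")
  beta0 <- (a22 * b1 - a12 * b2) / det
  beta <- (a11 * b2 - a12 * b1) / det
  r <- ty - beta0 * t1 - beta * tx      # explicit residuals: avoids the
  scale <- sum(w * r * r) / (m - 2L)    # cancellation of the sum-of-squares
                                        # shortcut at extreme weight spreads
  se <- sqrt(scale * a11 / det / var_div)
  if (se == 0) {
    stat <- sign(beta) * Inf
    p <- 1e-300
  } else {
    stat <- beta / se
    p <- max(2 * pnorm(-abs(stat)), 1e-300)
  }
  list(beta0 = beta0, beta = beta, se = se, stat = stat, p = p)
}

#' Genome-wide association scan
#'
#' Runs the per-gene association test for every gene in the expression
#' matrix, joining samples by id. For the LMM, variance components are fitted
#' once under the intercept-only null and reused for every gene (EMMAX
#' approximation; `refit_per_gene = TRUE` refits the variance ratio with the
#' gene in the mean model, at substantially higher cost). Benjamini-Hochberg
#' q-values are appended across the scan. Zero-variance genes are skipped
#' with a message, not an error.
#'
#' @param expr Samples-by-genes expression matrix with dimnames.
#' @param y Named phenotype vector (e.g. [icna_scores()] output).
#' @param method `"slr"` or `"lmm"`.
#' @param K Kinship matrix (required for `method = "lmm"` unless `vc` is
#'   given). Built on the same samples as the join of `expr` and `y`.
#' @param vc Optional prefitted `"variance_components"`.
#' @param refit_per_gene Refit the variance ratio per gene (LMM only).
#' @param paper_variance See [lmm_test()].
#' @return Data frame with one row per tested gene (input gene order):
#'   `gene`, `beta0`, `beta`, `se`, `statistic`, `p_value`, `q_value`,
#'   `method`; attributes `m` (samples used), `n_dropped_samples`,
#'   `skipped_genes`, and for LMM the fitted `vc`.
#' @export
association_scan <- function(expr, y, method = c("slr", "lmm"), K = NULL,
                             vc = NULL, refit_per_gene = FALSE,
                             paper_variance = FALSE) {
  method <- match.arg(method)
  ids <- intersect(rownames(expr), names(y))
  if (length(ids) < 10L)
    stop("fewer than 10 samples shared between expression matrix and ",
         "phenotype (", length(ids), ")")
  n_drop <- (nrow(expr) - length(ids)) + (length(y) - length(ids))
  if (n_drop > 0L)
    message("association_scan: dropped ", nrow(expr) - length(ids),
            " expression sample(s) and ", length(y) - length(ids),
            " phenotype sample(s) without a match")
  X <- expr[ids, , drop = FALSE]
  yv <- as.numeric(y[ids])
  if (var(yv) <= 0) stop("phenotype has zero variance on the joined samples")
  m <- length(ids)

  v <- colMeans(X * X) - colMeans(X)^2
  ok <- v > 1e-18
  if (any(!ok))
    message("association_scan: skipped ", sum(!ok), " zero-variance gene(s)")
  X <- X[, ok, drop = FALSE]
  genes <- colnames(X)

  if (method == "slr") {
    xc <- sweep(X, 2L, colMeans(X), `-`)
    yc <- yv - mean(yv)
    sxx <- colSums(xc * xc)
    sxy <- drop(crossprod(xc, yc))
    syy <- sum(yc * yc)
    beta <- sxy / sxx
    beta0 <- mean(yv) - beta * colMeans(X)
    rss <- pmax(syy - beta * sxy, 0)
    df <- m - 2L
    se <- sqrt(rss / df / sxx)
    stat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
    p <- pmax(2 * pt(-abs(stat), df), 1e-300)
    out <- data.frame(gene = genes, beta0 = beta0, beta = beta, se = se,
                      statistic = stat, p_value = p, method = "SLR",
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(vc)) {
      if (is.null(K)) stop("method = 'lmm' needs K or a prefitted vc")
      if (!is.null(rownames(K))) K <- K[ids, ids, drop = FALSE]
      vc <- fit_null_variance_components(yv, unname_matrix(K))
    }
    if (vc$m != m) stop("vc was fitted on a different sample set")
    U <- vc$eigen$vectors
    s <- vc$eigen$values
    ty <- drop(crossprod(U, yv))
    t1 <- drop(crossprod(U, rep(1, m)))
    TX <- crossprod(U, X)                       # rotate all genes at once
    if (refit_per_gene) {
      rows <- lapply(seq_along(genes), function(j) {
        dj <- .fit_delta_with_covariate(ty, TX[, j], t1, s, m)
        res <- .gls_rotated(ty, TX[, j], t1, 1 / (dj$sg2 * s + dj$se2),
                            if (paper_variance) m else 1L)
        c(res$beta0, res$beta, res$se, res$stat, res$p)
      })
      rows <- do.call(rbind, rows)
      out <- data.frame(gene = genes, beta0 = rows[, 1], beta = rows[, 2],
                        se = rows[, 3], statistic = rows[, 4],
                        p_value = rows[, 5], method = "LMM",
                        stringsAsFactors = FALSE)
    } else {
      w <- 1 / (vc$sigma_g2 * s + vc$sigma_e2)
      a11 <- sum(w * t1 * t1)
      b1 <- sum(w * t1 * ty)
      a12 <- drop(crossprod(TX, w * t1))
      a22 <- colSums(w * TX * TX)
      b2 <- drop(crossprod(TX, w * ty))
      det <- a11 * a22 - a12 * a12
      beta0 <- (a22 * b1 - a12 * b2) / det
      beta <- (a11 * b2 - a12 * b1) / det
      # explicit weighted residuals per gene (numerically stable)
      R <- (ty - outer(t1, beta0)) - sweep(TX, 2L, beta, `*`)
      scale <- colSums(w * R * R) / (m - 2L)
      se <- sqrt(scale * a11 / det / (if (paper_variance) m else 1L))
      stat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
      p <- pmax(2 * pnorm(-abs(stat)), 1e-300)
      out <- data.frame(gene = genes, beta0 = beta0, beta = beta, se = se,
                        statistic = stat, p_value = p, method = "LMM",
                        stringsAsFactors = FALSE)
    }
  }
  out$q_value <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "n_dropped_samples") <- n_drop
  attr(out, "skipped_genes") <- colnames(expr)[!ok]
  if (method == "lmm") attr(out, "vc") <- vc
  out
}

unname_matrix <- function(K) { dimnames(K) <- NULL; K }

# per-gene ML refit of the variance ratio with x in the mean model
.fit_delta_with_covariate <- function(ty, tx, t1, s, m) {
  prof <- function(delta) {
    w <- 1 / (s + delta)
    fit <- .gls_rotated(ty, tx, t1, w)
    r <- ty - fit$beta0 * t1 - fit$beta * tx
    sg2 <- sum(w * r * r) / m
    ll <- -0.5 * (m * log(2 * pi) + m * log(sg2) + sum(log(s + delta)) + m)
    list(ll = ll, sg2 = sg2)
  }
  grid <- 10^seq(-5, 5, length.out = 40L)
  lls <- vapply(grid, function(d) prof(d)$ll, 0)
  i <- which.max(lls)
  opt <- optimize(function(ld) prof(10^ld)$ll,
                  c(log10(grid[max(i - 1L, 1L)]),
                    log10(grid[min(i + 1L, length(grid))])),
                  maximum = TRUE, tol = 1e-8)
  fit <- prof(10^opt$maximum)
  list(sg2 = fit$sg2, se2 = fit$sg2 * 10^opt$maximum)
}
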