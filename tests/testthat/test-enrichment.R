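ranked_from <- function(genes, metric) {
  res <- data.frame(gene = genes, statistic = metric,
                    stringsAsFactors = FALSE)
  build_ranked_list(res)
}

test_that("build_ranked_list orders by metric with deterministic ties", {
  r <- ranked_from(c("a", "b", "c"), c(2, -1, 3))
  expect_equal(r$gene, c("c", "a", "b"))
  # all-equal metrics: lexicographic gene order
  r_tie <- ranked_from(c("b", "c", "a"), c(1, 1, 1))
  expect_equal(r_tie$gene, c("a", "b", "c"))
  # negating all metrics exactly reverses a tie-free order
  set.seed(2)
  met <- rnorm(20)
  g <- sprintf("g%02d", 1:20)
  expect_equal(ranked_from(g, -met)$gene, rev(ranked_from(g, met)$gene))
  expect_error(ranked_from(c("a", "a"), c(1, 2)), "duplicate")
})

test_that("pearson_r metric converts SLR t-statistics to correlations", {
  set.seed(15)
  m <- 60L
  X <- random_expr(m, 10L, seed = 16L)
  y <- setNames(rnorm(m), rownames(X))
  res <- association_scan(X, y, method = "slr")
  r <- build_ranked_list(res, metric = "pearson_r")
  ref <- drop(cor(X, y))
  expect_equal(sort(r$metric), sort(unname(ref)), tolerance = 1e-10)
})

test_that("streaming enrichment score equals the brute-force oracle on random instances", {
  # frozen oracle value: top-3 set, equal positive metrics, p = 0 -> the
  # running sum peaks at position 3 with all hits seen and no misses: ES = 1
  r <- ranked_from(sprintf("g%02d", 1:10), rep(1, 10))
  top3 <- r$gene[1:3]
  expect_equal(enrichment_score(r, top3, weight_p = 0)$es, 1)
  expect_equal(oracle_es(r$gene, r$metric, top3, p = 0), 1)

  set.seed(99)
  for (rep in 1:30) {
    N <- sample(5:50, 1)
    met <- rnorm(N)
    r <- ranked_from(sprintf("g%03d", 1:N), met)
    k <- sample.int(N, 1)
    set_genes <- sample(r$gene, k)
    for (p in c(0, 1, 2)) {
      stream <- enrichment_score(r, set_genes, weight_p = p)$es
      expect_equal(stream, oracle_es(r$gene, r$metric, set_genes, p),
                   tolerance = 1e-12)
      expect_gte(stream, -1); expect_lte(stream, 1)
    }
  }
})

test_that("running sum: starts/ends at zero for p = 0, set covering the whole list, skipped sets", {
  r <- ranked_from(sprintf("g%02d", 1:12), rnorm(12))
  prof <- enrichment_score(r, r$gene[c(2, 5, 9)], weight_p = 0)$running_sum
  expect_equal(prof[length(prof)], 0, tolerance = 1e-12)

  # set = all genes: degenerate miss denominator handled; equals the oracle
  all_es <- enrichment_score(r, r$gene, weight_p = 0)$es
  expect_equal(all_es, oracle_es(r$gene, r$metric, r$gene, p = 0))
  expect_equal(all_es, 1)

  # reversing the list negates ES for a symmetric unweighted instance
  r_fwd <- ranked_from(sprintf("g%02d", 1:10), 10:1)
  r_rev <- ranked_from(sprintf("g%02d", 1:10), 1:10)
  s <- c("g01", "g02", "g03")
  expect_equal(enrichment_score(r_rev, s, weight_p = 0)$es,
               -enrichment_score(r_fwd, s, weight_p = 0)$es)

  expect_error(enrichment_score(r, c("zz1", "zz2")), "no overlap")
})

test_that("permutation_fdr: determinism, extreme-set bound, sane q-values", {
  set.seed(123)
  N <- 100L
  met <- sort(rnorm(N), decreasing = TRUE)
  r <- ranked_from(sprintf("g%03d", 1:N), met)
  coll <- structure(list(
    top = list(description = "", genes = r$gene[1:10]),
    rand = list(description = "", genes = sample(r$gene, 15)),
    bottom = list(description = "", genes = r$gene[91:100])),
    class = "gene_set_collection")
  a <- permutation_fdr(r, coll, n_perm = 500L, seed = 7L)
  b <- permutation_fdr(r, coll, n_perm = 500L, seed = 7L)
  expect_identical(a, b)                      # bit-for-bit determinism
  top_row <- a[a$set_name == "top", ]
  expect_lte(top_row$p_value, 1 / 500)        # p <= 1/(n_perm+1) rounded up
  expect_gt(top_row$es, 0)
  expect_lt(a$es[a$set_name == "bottom"], 0)
  expect_true(all(a$fdr_q >= 0 & a$fdr_q <= 1))
  expect_true(all(sign(a$nes[a$es != 0]) == sign(a$es[a$es != 0])))

  # FDR q monotone in |NES| within each sign after adjustment
  for (sgn in c(1, -1)) {
    sel <- if (sgn > 0) a$nes >= 0 else a$nes < 0
    if (sum(sel) > 1) {
      ord <- order(-abs(a$nes[sel]))
      expect_true(all(diff(a$fdr_q[sel][ord]) >= -1e-12))
    }
  }

  # a set with no overlap is skipped with a message
  coll2 <- structure(list(gone = list(description = "", genes = "zzz"),
                          rand = coll$rand),
                     class = "gene_set_collection")
  expect_message(res2 <- permutation_fdr(r, coll2, n_perm = 200L, seed = 1L),
                 "skipped")
  expect_equal(res2$set_name, "rand")
})

test_that("permutation p-values are calibrated for random sets under a null ranking", {
  set.seed(555)
  n_rep <- 200L
  N <- 150L
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    r <- ranked_from(sprintf("g%03d", 1:N), rnorm(N))
    coll <- structure(list(s = list(description = "",
                                    genes = sample(r$gene, 15L))),
                      class = "gene_set_collection")
    p <- permutation_fdr(r, coll, n_perm = 200L, seed = 1000L + i)$p_value
    rej[i] <- p < 0.05
  }
  expect_gte(mean(rej), 0.02); expect_lte(mean(rej), 0.08)
})

test_that("LOESS extrapolation fills only q = 0 rows and stays in (0, 1]", {
  # monotone NES -> -log10 q relation with one saturated outlier per sign
  set.seed(3)
  nes <- c(seq(1, 3, length.out = 12), 3.8,
           seq(-1, -2.5, length.out = 8), -3.5)
  q <- c(10^(-seq(0.2, 2.5, length.out = 12)), 0,
         10^(-seq(0.3, 2, length.out = 8)), 0)
  res <- data.frame(set_name = sprintf("s%02d", seq_along(nes)),
                    size = 10L, es = sign(nes), nes = nes, p_value = 0.5,
                    fdr_q = q, fdr_q_extrapolated = NA_real_,
                    stringsAsFactors = FALSE)
  out <- extrapolate_q(res)
  expect_equal(out$fdr_q, res$fdr_q)            # original q untouched
  filled <- !is.na(out$fdr_q_extrapolated)
  expect_equal(filled, res$fdr_q == 0)
  expect_true(all(out$fdr_q_extrapolated[filled] > 0 &
                    out$fdr_q_extrapolated[filled] <= 1))
  # extrapolated significance exceeds the strongest observed one per sign
  pos_sat <- which(res$fdr_q == 0 & res$nes > 0)
  expect_lt(out$fdr_q_extrapolated[pos_sat],
            min(res$fdr_q[res$fdr_q > 0 & res$nes > 0]))
  neg_sat <- which(res$fdr_q == 0 & res$nes < 0)
  expect_lt(out$fdr_q_extrapolated[neg_sat],
            min(res$fdr_q[res$fdr_q > 0 & res$nes < 0]))

  # nothing to fill: output equals input
  res2 <- res[res$fdr_q > 0, ]
  expect_equal(extrapolate_q(res2)$fdr_q_extrapolated,
               rep(NA_real_, nrow(res2)))

  # too few nonzero-q points on a sign: warning, left NA
  res3 <- res[c(1:3, 13), ]
  expect_warning(out3 <- extrapolate_q(res3), "fewer than 5")
  expect_true(is.na(out3$fdr_q_extrapolated[out3$fdr_q == 0]))
})

test_that("mask_collection removes genes everywhere and drops emptied sets", {
  coll <- structure(list(
    a = list(description = "", genes = c("h1", "h2", "x1")),
    b = list(description = "", genes = c("h1", "h2"))),
    class = "gene_set_collection")
  expect_message(out <- mask_collection(coll, c("h1", "h2")), "dropped 1")
  expect_equal(names(out), "a")
  expect_equal(out$a$genes, "x1")
})
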