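#' Identify purity-associated genes
#'
#' Tests every gene's expression for correlation with the per-sample
#' consensus purity estimate (CPE) and returns the genes whose
#' Bonferroni-corrected p-value falls below `alpha` (default 0.01). Pearson
#' correlation is the default, matching the package's linear-regression
#' machinery; Spearman (rank-transformed Pearson with the t approximation)
#' is available. The Bonferroni family is the number of genes actually
#' tested (after zero-variance removal).
#'
#' @param expr Samples-by-genes expression matrix.
#' @param cpe Named numeric purity vector in \[0, 1\] (see [read_purity()]).
#' @param alpha Family-wise significance level on the corrected p (default
#'   0.01).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `genes` (character vector of significant genes) and
#'   `table` (data frame: `gene`, `r`, `p_value`, `p_bonferroni`,
#'   `significant`).
#' @export
purity_associated_genes <- function(expr, cpe, alpha = 0.01,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ids <- intersect(rownames(expr), names(cpe))
  if (length(ids) < 10L)
    stop("fewer than 10 samples shared between expression and purity data")
  X <- expr[ids, , drop = FALSE]
  p_vec <- as.numeric(cpe[ids])
  m <- length(ids)
  v <- colMeans(X * X) - colMeans(X)^2
  ok <- v > 1e-18
  if (any(!ok))
    message("purity_associated_genes: skipped ", sum(!ok),
            " zero-variance gene(s)")
  X <- X[, ok, drop = FALSE]
  if (method == "spearman") {
    X <- apply(X, 2L, rank)
    p_vec <- rank(p_vec)
  }
  r <- drop(cor(X, p_vec))
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((m - 2) / pmax(1 - r^2, 1e-300))
  p <- pmax(2 * pt(-abs(tstat), m - 2L), 1e-300)
  p_bonf <- pmin(p * ncol(X), 1)
  tab <- data.frame(gene = colnames(X), r = r, p_value = p,
                    p_bonferroni = p_bonf, significant = p_bonf < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(genes = tab$gene[tab$significant], table = tab)
}

#' Distribution of purity-associated genes across an association ranking
#'
#' Bins the rank positions of purity-associated genes along the
#' association-strength-ordered gene list (most positively associated first)
#' and summarizes their enrichment at the extremes: the fraction of purity
#' genes falling in the top or bottom decile versus the 0.2 expected under a
#' uniform spread, with a two-sided binomial test. Under a purity-confounded
#' scan the purity genes pile up at both ends; under an effective correction
#' they spread uniformly.
#'
#' @param results Association results data frame.
#' @param purity_genes Character vector of purity-associated gene ids.
#' @param bins Number of equal-width rank bins (default 20).
#' @return List: `counts` (per-bin counts, first bin = most positively
#'   associated), `breaks`, `n_purity` (purity genes present in the ranking),
#'   `extreme_fraction`, `expected_fraction` (0.2), `p_value` (binomial).
#' @export
overlap_report <- function(results, purity_genes, bins = 20L) {
  ranked <- build_ranked_list(results)
  N <- nrow(ranked)
  pos <- which(ranked$gene %in% purity_genes)
  breaks <- seq(0, N, length.out = bins + 1L)
  counts <- as.integer(table(cut(pos, breaks = breaks, labels = FALSE,
                                 include.lowest = TRUE)))
  counts <- {
    full <- integer(bins)
    tab <- table(cut(pos, breaks = breaks, labels = FALSE,
                     include.lowest = TRUE))
    full[as.integer(names(tab))] <- as.integer(tab)
    full
  }
  k <- length(pos)
  cut_lo <- ceiling(0.1 * N)
  cut_hi <- N - cut_lo
  extreme <- sum(pos <= cut_lo | pos > cut_hi)
  p <- if (k > 0)
    stats::binom.test(extreme, k, p = 0.2)$p.value else NA_real_
  list(counts = counts, breaks = breaks, n_purity = k,
       extreme_fraction = if (k > 0) extreme / k else NA_real_,
       expected_fraction = 0.2, p_value = p)
}
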