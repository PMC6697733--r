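#' Build a ranked gene list from association results
#'
#' Orders genes by a signed association-strength metric, descending (most
#' positively associated first), with ties broken by gene id. The default
#' metric is the signed test statistic; `"pearson_r"` converts an SLR
#' t-statistic to the sample correlation `r = t / sqrt(t^2 + df)` (requires
#' a scan result carrying its sample count).
#'
#' @param results Association results data frame (one row per gene).
#' @param metric `"signed_statistic"` (default) or `"pearson_r"`.
#' @return Object of class `"ranked_list"`: data frame with columns `gene`
#'   and `metric`, sorted.
#' @export
build_ranked_list <- function(results,
                              metric = c("signed_statistic", "pearson_r")) {
  metric <- match.arg(metric)
  if (anyDuplicated(results$gene))
    stop("duplicate gene in association results: ",
         results$gene[duplicated(results$gene)][1L])
  if (metric == "signed_statistic") {
    score <- results$statistic
  } else {
    m <- attr(results, "m")
    if (is.null(m) || !all(results$method == "SLR"))
      stop("pearson_r metric needs an SLR scan result with its sample count")
    df <- m - 2L
    score <- results$statistic / sqrt(results$statistic^2 + df)
  }
  if (any(!is.finite(score)))
    score[!is.finite(score)] <- sign(score[!is.finite(score)]) * 1e6
  ord <- order(-score, results$gene)
  structure(data.frame(gene = results$gene[ord], metric = score[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

# core weighted Kolmogorov-Smirnov enrichment statistic.
# hit_pos: sorted positions (1-based) of the set's genes in the ranked list;
# absw: |metric|^p for every position; N: list length.
# Returns the signed extremum of the running sum P_hit - P_miss. The extremum
# over the full profile is attained immediately after a hit or immediately
# before the next hit, so only O(|set|) candidates need checking.
.es_from_positions <- function(hit_pos, absw, N) {
  nh <- length(hit_pos)
  nm <- N - nh
  wsum <- cumsum(absw[hit_pos])
  tot <- wsum[nh]
  if (tot <= 0) {                       # all-zero weights: unweighted fallback
    wsum <- seq_len(nh)
    tot <- nh
  }
  phit_after <- wsum / tot
  pmiss_after <- if (nm > 0L) (hit_pos - seq_len(nh)) / nm else rep(0, nh)
  after <- phit_after - pmiss_after     # just after each hit
  phit_before <- c(0, phit_after[-nh])
  pmiss_before <- if (nm > 0L) (hit_pos - seq_len(nh)) / nm else rep(0, nh)
  before <- phit_before - pmiss_before  # just before each hit
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Enrichment score of one gene set on a ranked list
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic: walking down the ranked
#' list, the running sum rises by `|metric|^p / sum(|metric|^p over hits)` at
#' each set member ("hit") and falls by `1 / (N - N_hit)` at each non-member.
#' The enrichment score (ES) is the signed extremum of the running sum, in
#' \[-1, 1\]: positive when members concentrate at the top of the list,
#' negative when at the bottom.
#'
#' @param ranked A `"ranked_list"`.
#' @param genes Character vector: the gene set.
#' @param weight_p Weighting exponent p (default 1, the classic weighted
#'   statistic; p = 0 is the unweighted KS form).
#' @return List with `es`, `running_sum` (full profile, length N) and
#'   `hit_positions`.
#' @export
enrichment_score <- function(ranked, genes, weight_p = 1) {
  N <- nrow(ranked)
  hit <- ranked$gene %in% genes
  nh <- sum(hit)
  if (nh == 0L) stop("gene set has no overlap with the ranked list")
  absw <- abs(ranked$metric)^weight_p
  hit_pos <- which(hit)
  es <- .es_from_positions(hit_pos, absw, N)
  w <- absw
  w[!hit] <- 0
  tot <- sum(w)
  if (tot <= 0) { w[hit] <- 1; tot <- nh }
  phit <- cumsum(w) / tot
  pmiss <- if (N > nh) cumsum(!hit) / (N - nh) else rep(0, N)
  list(es = es, running_sum = phit - pmiss, hit_positions = hit_pos)
}

#' Pre-ranked enrichment with permutation p-values and FDR
#'
#' Scores every set in the collection on the ranked list and assesses
#' significance by gene-label permutation: for each set, `n_perm` random
#' gene sets of the same size are drawn and scored. The normalized enrichment
#' score (NES) divides the observed ES by the mean same-sign permuted |ES|
#' for that set; the p-value is the same-sign permutation tail frequency;
#' the FDR q-value compares the pooled permuted NES
#' distribution against the observed NES distribution in the standard
#' pre-ranked scheme, followed by a monotonicity adjustment within each NES
#' sign. Deterministic for a given seed.
#'
#' @param ranked A `"ranked_list"`.
#' @param collection A `"gene_set_collection"`; sets are intersected with the
#'   ranked genes, empty intersections are skipped with a message.
#' @param n_perm Number of permutations per set (>= 100; default 10000).
#' @param seed Integer seed for the permutation generator.
#' @param weight_p Weighting exponent, see [enrichment_score()].
#' @param mask_genes Optional character vector removed from every set before
#'   scoring (see [mask_collection()]).
#' @return Data frame: `set_name`, `size`, `es`, `nes`, `p_value`, `fdr_q`,
#'   `fdr_q_extrapolated` (NA until [extrapolate_q()] is applied).
#' @export
permutation_fdr <- function(ranked, collection, n_perm = 10000L, seed = 1L,
                            weight_p = 1, mask_genes = NULL) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (!is.null(mask_genes)) collection <- mask_collection(collection,
                                                          mask_genes)
  N <- nrow(ranked)
  absw <- abs(ranked$metric)^weight_p
  sizes <- integer(0)
  keep <- character(0)
  hits <- list()
  for (nm in names(collection)) {
    pos <- which(ranked$gene %in% collection[[nm]]$genes)
    if (length(pos) == 0L) {
      message("permutation_fdr: set '", nm, "' has no overlap; skipped")
      next
    }
    keep <- c(keep, nm)
    hits[[nm]] <- pos
    sizes[nm] <- length(pos)
  }
  if (length(keep) == 0L) stop("no gene set overlaps the ranked list")

  es_obs <- vapply(keep, function(nm)
    .es_from_positions(hits[[nm]], absw, N), 0)

  # one permutation null per distinct set size (sets of equal size share it)
  set.seed(seed)
  uniq <- sort(unique(sizes))
  perm_by_size <- list()
  for (k in uniq) {
    perm_by_size[[as.character(k)]] <- vapply(seq_len(n_perm), function(b)
      .es_from_positions(sort.int(sample.int(N, k)), absw, N), 0)
  }

  nes_obs <- numeric(length(keep))
  p_val <- numeric(length(keep))
  null_nes <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    perm <- perm_by_size[[as.character(sizes[keep[j]])]]
    pos_mean <- mean(perm[perm >= 0])
    neg_mean <- mean(abs(perm[perm < 0]))
    e <- es_obs[j]
    # classic same-sign permutation tail frequency (can be 0 when the
    # observed ES beats every same-sign permutation)
    if (e >= 0) {
      nes_obs[j] <- if (is.finite(pos_mean) && pos_mean > 0) e / pos_mean else 0
      np <- sum(perm >= 0)
      p_val[j] <- if (np > 0) sum(perm[perm >= 0] >= e) / np else 0
    } else {
      nes_obs[j] <- if (is.finite(neg_mean) && neg_mean > 0) e / neg_mean else 0
      np <- sum(perm < 0)
      p_val[j] <- if (np > 0) sum(perm[perm < 0] <= e) / np else 0
    }
    nn <- perm
    nn[perm >= 0] <- if (is.finite(pos_mean) && pos_mean > 0)
      perm[perm >= 0] / pos_mean else 0
    nn[perm < 0] <- if (is.finite(neg_mean) && neg_mean > 0)
      perm[perm < 0] / neg_mean else 0
    null_nes[[j]] <- nn
  }
  pool <- unlist(null_nes)

  fdr <- vapply(seq_along(keep), function(j) {
    nes <- nes_obs[j]
    if (nes >= 0) {
      num_den <- sum(pool >= 0)
      num <- if (num_den > 0) sum(pool >= nes) / num_den else 0
      den_den <- sum(nes_obs >= 0)
      den <- sum(nes_obs >= nes) / den_den
    } else {
      num_den <- sum(pool < 0)
      num <- if (num_den > 0) sum(pool <= nes) / num_den else 0
      den_den <- sum(nes_obs < 0)
      den <- sum(nes_obs <= nes) / den_den
    }
    min(1, if (den > 0) num / den else 0)
  }, 0)

  # within-sign monotonicity: q must not decrease as |NES| decreases
  for (sgn in c(1, -1)) {
    idx <- if (sgn > 0) which(nes_obs >= 0) else which(nes_obs < 0)
    if (length(idx) > 1L) {
      ord <- idx[order(-abs(nes_obs[idx]))]     # most extreme first
      fdr[ord] <- rev(cummin(rev(fdr[ord])))    # BH-style step-up
    }
  }

  data.frame(set_name = keep, size = as.integer(sizes[keep]), es = es_obs,
             nes = nes_obs, p_value = p_val, fdr_q = fdr,
             fdr_q_extrapolated = NA_real_, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' LOESS extrapolation of zero FDR q-values
#'
#' With a finite number of permutations, strongly enriched sets saturate at
#' q = 0, making their relative enrichment incomparable. This fits a LOESS
#' curve of `-log10(q)` on NES through the sets with nonzero q (separately
#' for each NES sign, since the two tails need not be symmetric) and
#' extrapolates it to the NES of the q = 0 sets; the extrapolated q is
#' `10^(-fit(NES))`, clamped to (0, 1\]. Original q-values are never
#' modified.
#'
#' @param results Data frame from [permutation_fdr()].
#' @param span LOESS span (default 0.75).
#' @return `results` with `fdr_q_extrapolated` filled for q = 0 rows (NA
#'   elsewhere). If a sign has fewer than 5 nonzero-q sets, its q = 0 rows
#'   are left NA with a warning.
#' @export
extrapolate_q <- function(results, span = 0.75) {
  results$fdr_q_extrapolated <- NA_real_
  for (sgn in c(1, -1)) {
    on_sign <- if (sgn > 0) results$nes >= 0 else results$nes < 0
    fitpts <- on_sign & results$fdr_q > 0
    need <- on_sign & results$fdr_q == 0
    if (!any(need)) next
    if (sum(fitpts) < 5L) {
      warning("extrapolate_q: fewer than 5 nonzero-q sets with ",
              if (sgn > 0) "positive" else "negative",
              " NES; extrapolation skipped", call. = FALSE)
      next
    }
    fit <- loess(y ~ x,
                 data = data.frame(x = results$nes[fitpts],
                                   y = -log10(results$fdr_q[fitpts])),
                 span = span, degree = 2,
                 control = loess.control(surface = "direct"))
    pred <- predict(fit, newdata = data.frame(x = results$nes[need]))
    q <- 10^(-pred)
    q[!is.finite(q)] <- NA_real_
    q <- pmin(pmax(q, 1e-300), 1)
    results$fdr_q_extrapolated[need] <- q
  }
  results
}
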