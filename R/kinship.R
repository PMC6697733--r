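#' Standardize an expression matrix gene-wise
#'
#' Centers every gene (column) to mean 0 and scales to variance 1 using the
#' population standard deviation (denominator m). With this convention each
#' standardized column has sum of squares exactly m, so the kinship matrix
#' `Z Z' / n` has trace exactly m — a clean, testable invariant. Genes with
#' (numerically) zero variance carry no information and are removed, with a
#' message.
#'
#' @param expr Samples-by-genes numeric matrix with dimnames (see
#'   [read_expression()]).
#' @return Standardized matrix `Z` (samples x retained genes) with attribute
#'   `removed_genes` (zero-variance gene ids).
#' @export
standardize_expression <- function(expr) {
  if (is.null(dim(expr)) || nrow(expr) < 3L)
    stop("standardization needs at least 3 samples")
  mu <- colMeans(expr)
  v <- colMeans(expr * expr) - mu * mu       # population variance
  zero <- !(v > 1e-18)
  if (all(zero)) stop("all genes have zero variance")
  if (any(zero))
    message("standardize_expression: removed ", sum(zero),
            " zero-variance gene(s)")
  Z <- sweep(expr[, !zero, drop = FALSE], 2L, mu[!zero], `-`)
  Z <- sweep(Z, 2L, sqrt(v[!zero]), `/`)
  attr(Z, "removed_genes") <- colnames(expr)[zero]
  attr(Z, "zero_variance_genes") <- NULL
  Z
}

#' Inter-sample covariance (expression kinship) matrix
#'
#' Builds the m x m matrix `K = Z Z' / n` from a standardized expression
#' matrix. K plays the role the genetic relationship matrix plays in GWAS
#' mixed models: samples with correlated genome-wide expression profiles
#' (driven by shared purity, batch, or co-regulated programs) have large
#' entries, and the LMM uses K to absorb phenotype variance explained by that
#' shared structure. Because columns of Z are centered, `K 1 = 0` exactly and
#' K is singular; the mixed-model covariance `V = sg2 K + se2 I` remains
#' positive definite for `se2 > 0`.
#'
#' @param Z Standardized matrix from [standardize_expression()] (or any
#'   samples-by-genes matrix with column mean 0, variance 1).
#' @return Symmetric m x m matrix with sample ids as dimnames and attribute
#'   `n_genes_used`.
#' @export
compute_kinship <- function(Z) {
  if (is.null(dim(Z)) || ncol(Z) < 1L) stop("Z must have at least one gene")
  K <- tcrossprod(Z) / ncol(Z)
  K <- (K + t(K)) / 2            # enforce exact symmetry
  dimnames(K) <- list(rownames(Z), rownames(Z))
  attr(K, "n_genes_used") <- ncol(Z)
  K
}

#' Kinship matrix excluding a set of genes
#'
#' Builds K after removing the given genes from the raw expression matrix,
#' re-standardizing the remaining genes. This is the "depleted-K" control:
#' removing all purity-associated genes from K strips the purity signal from
#' the variance component, so purity-driven associations reappear in the LMM
#' output — demonstrating that the full K was specifically capturing them.
#'
#' @param expr Raw samples-by-genes expression matrix.
#' @param excluded_genes Character vector of gene ids to leave out. Names not
#'   present in `expr` are ignored with a message.
#' @return Kinship matrix as in [compute_kinship()].
#' @export
compute_kinship_excluding <- function(expr, excluded_genes = character()) {
  missing_genes <- setdiff(excluded_genes, colnames(expr))
  if (length(missing_genes) > 0L)
    message("compute_kinship_excluding: ", length(missing_genes),
            " excluded gene(s) not present in the expression matrix; ignored")
  keep <- setdiff(colnames(expr), excluded_genes)
  if (length(keep) < 2L)
    stop("exclusion leaves fewer than 2 genes; cannot build kinship")
  compute_kinship(standardize_expression(expr[, keep, drop = FALSE]))
}
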