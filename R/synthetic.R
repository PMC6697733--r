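#' Simulation configuration
#'
#' Defines the generative world used to test the association machinery: a
#' latent tumor-purity confounder loading on many genes, co-regulated gene
#' modules, a few causal genes, and an aneuploidy-like phenotype driven by
#' the causal genes plus the confounder. Defaults encode a cohort of 800
#' samples and 2000 genes, of which 400 load on purity, one 200-gene module
#' is co-regulated, and 5 + 5 genes are causal (outside and inside the
#' module). Effect sizes were frozen after a pilot calibration and are
#' documented in the package vignette.
#'
#' @param m Sample count (default 800).
#' @param n Gene count (default 2000).
#' @param n_confounded Genes loading on the latent purity variable (default
#'   400); these are causally null.
#' @param module_sizes Integer vector of co-regulated module sizes (default
#'   200).
#' @param n_causal_independent Causal genes with no correlation to any other
#'   gene (default 5).
#' @param n_causal_in_module Causal genes inside the first module (default 5).
#' @param beta_causal Phenotype effect per causal gene, in phenotype-noise sd
#'   units (default 0.35).
#' @param gamma_confounder Direct purity-to-phenotype effect (default 1).
#' @param loading_strength Purity (and module-factor) loading on expression
#'   (default 1).
#' @param noise_sd Expression noise standard deviation (default 1).
#' @param seed Integer seed; fixes the whole dataset.
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(m = 800L, n = 2000L, n_confounded = 400L,
                              module_sizes = 200L,
                              n_causal_independent = 5L,
                              n_causal_in_module = 5L,
                              beta_causal = 0.35, gamma_confounder = 1,
                              loading_strength = 1, noise_sd = 1,
                              seed = 1L) {
  cfg <- list(m = as.integer(m), n = as.integer(n),
              n_confounded = as.integer(n_confounded),
              module_sizes = as.integer(module_sizes),
              n_causal_independent = as.integer(n_causal_independent),
              n_causal_in_module = as.integer(n_causal_in_module),
              beta_causal = beta_causal,
              gamma_confounder = gamma_confounder,
              loading_strength = loading_strength, noise_sd = noise_sd,
              seed = as.integer(seed))
  with(cfg, {
    if (m < 4L || n < 2L) stop("need m >= 4 and n >= 2")
    if (any(c(n_confounded, module_sizes, n_causal_independent,
              n_causal_in_module) < 0L)) stop("counts must be >= 0")
    if (n_confounded + sum(module_sizes) + n_causal_independent > n)
      stop("gene classes exceed the total gene count n")
    if (length(module_sizes) >= 1L && n_causal_in_module > module_sizes[1L])
      stop("n_causal_in_module exceeds the first module's size")
    if (length(module_sizes) == 0L && n_causal_in_module > 0L)
      stop("n_causal_in_module > 0 requires at least one module")
    if (noise_sd <= 0) stop("noise_sd must be positive")
  })
  structure(cfg, class = "simulation_config")
}

#' Simulate an expression/phenotype dataset with known ground truth
#'
#' Generative model (all draws from the seeded generator):
#' * latent purity `p ~ N(0, 1)` per sample; module factors `f_j ~ N(0, 1)`;
#' * confounded gene: `x = lambda p + eps`; module gene: `x = lambda f_j +
#'   eps`; independent causal and null genes: `x = eps`, with
#'   `eps ~ N(0, noise_sd^2)`;
#' * phenotype `y_raw = beta sum(causal x) + gamma p + e`, `e ~ N(0, 1)`,
#'   then standardized to mean 0, variance 1.
#'
#' Confounded genes do not enter the phenotype: any association they show is
#' spurious, mediated purely by the shared purity variable — the structure
#' the mixed model is meant to absorb. The exported CPE is `pnorm(p)`, a
#' monotone map of the latent purity into \[0, 1\].
#'
#' @param config A `"simulation_config"`.
#' @return Object of class `"synthetic_dataset"`: list with `expr` (m x n
#'   matrix), `y` (named, standardized), `truth` (data frame: `gene`,
#'   `class` in confounded/module/causal_independent/causal_module/null,
#'   `module` id or NA), `purity` (latent), `cpe`, `module_factors`,
#'   `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  m <- config$m; n <- config$n
  sample_ids <- sprintf("S%04d", seq_len(m))
  gene_ids <- sprintf("g%05d", seq_len(n))

  p <- rnorm(m)
  n_mod <- length(config$module_sizes)
  f <- if (n_mod > 0L) matrix(rnorm(m * n_mod), m, n_mod) else
    matrix(0, m, 0L)

  class_vec <- rep("null", n)
  module_vec <- rep(NA_integer_, n)
  idx <- 0L
  conf_idx <- seq_len(config$n_confounded)
  class_vec[conf_idx] <- "confounded"
  idx <- config$n_confounded
  mod_idx <- vector("list", n_mod)
  for (j in seq_len(n_mod)) {
    mod_idx[[j]] <- idx + seq_len(config$module_sizes[j])
    class_vec[mod_idx[[j]]] <- "module"
    module_vec[mod_idx[[j]]] <- j
    idx <- idx + config$module_sizes[j]
  }
  causal_ind_idx <- idx + seq_len(config$n_causal_independent)
  class_vec[causal_ind_idx] <- "causal_independent"
  idx <- idx + config$n_causal_independent
  causal_mod_idx <- integer(0)
  if (config$n_causal_in_module > 0L) {
    causal_mod_idx <- mod_idx[[1L]][seq_len(config$n_causal_in_module)]
    class_vec[causal_mod_idx] <- "causal_module"
  }

  X <- matrix(rnorm(m * n, sd = config$noise_sd), m, n,
              dimnames = list(sample_ids, gene_ids))
  lam <- config$loading_strength
  if (config$n_confounded > 0L) {
    # purity loads on genes with both signs (immune/stromal programs rise
    # with falling purity while tumor-intrinsic programs fall), so purity
    # genes appear at both extremes of a confounded association ranking
    lam_sign <- sample(c(-1, 1), config$n_confounded, replace = TRUE)
    X[, conf_idx] <- X[, conf_idx] +
      matrix(p, m, config$n_confounded) *
        matrix(lam * lam_sign, m, config$n_confounded, byrow = TRUE)
  }
  for (j in seq_len(n_mod))
    X[, mod_idx[[j]]] <- X[, mod_idx[[j]]] + lam * f[, j]

  causal <- c(causal_ind_idx, causal_mod_idx)
  y_raw <- config$gamma_confounder * p + rnorm(m)
  if (length(causal) > 0L)
    y_raw <- y_raw + config$beta_causal * rowSums(X[, causal, drop = FALSE])
  y <- as.numeric(scale(y_raw))
  names(y) <- sample_ids

  truth <- data.frame(gene = gene_ids, class = class_vec,
                      module = module_vec, stringsAsFactors = FALSE)
  structure(list(expr = X, y = y, truth = truth,
                 purity = setNames(p, sample_ids),
                 cpe = setNames(pnorm(p), sample_ids),
                 module_factors = f, config = config),
            class = "synthetic_dataset")
}

#' Derive a SEG-format copy-number track from a simulated phenotype
#'
#' Builds, for each sample, a random set of genomic segments whose summed
#' `length x |value|` equals `exp(y)` for that sample, so that running the
#' ICNA scorer (absolute transform, one-based dialect) on the emitted SEG
#' data recovers a phenotype monotone in the simulated one. This supports
#' end-to-end testing from SEG input through the full pipeline.
#'
#' @param y Named phenotype vector (e.g. from [simulate_dataset()]).
#' @param n_segments Segments per sample (default 30).
#' @param seed Integer seed.
#' @return A `"seg_data"` object (one-based dialect).
#' @export
simulate_seg <- function(y, n_segments = 30L, seed = 1L) {
  set.seed(seed)
  samples <- lapply(names(y), function(id) {
    k <- n_segments
    chrom <- as.character(sample.int(22L, k, replace = TRUE))
    start <- floor(runif(k, 1, 1e8))
    len <- floor(runif(k, 1e5, 5e6))
    end <- start + len - 1
    value <- rnorm(k, sd = 0.3) * sample(c(-1, 1), k, replace = TRUE)
    value[abs(value) < 1e-3] <- 1e-3
    target <- exp(y[[id]])
    raw <- sum(len * abs(value))
    value <- value * target / raw
    structure(list(sample_id = id,
                   segments = data.frame(chrom = chrom, start = start,
                                         end = end,
                                         num_markers = NA_real_,
                                         seg_value = value,
                                         stringsAsFactors = FALSE)),
              class = "segmented_sample")
  })
  names(samples) <- names(y)
  structure(samples, class = "seg_data", n_dropped = 0L,
            dialect = "one-based")
}

#' Evaluate an association scan against simulation ground truth
#'
#' @param results Association results data frame covering the truth genes.
#' @param truth Truth data frame from [simulate_dataset()].
#' @param alpha Per-test rejection level for type-I/power rates (default
#'   0.05, on the raw p-value).
#' @param top_frac Fraction of the scan defining "top-ranked" for causal
#'   detection (default 0.01, i.e. the top 1% of p-values).
#' @return List: `class_rates` (data frame: `class`, `n`,
#'   `rejection_rate`), `causal` (data frame: `gene`, `class`, `p_value`,
#'   `rank`, `in_top`), `power_top` (named by causal class: fraction of
#'   causal genes ranked in the top `top_frac`), `alpha`, `top_frac`.
#' @export
evaluate_scan <- function(results, truth, alpha = 0.05, top_frac = 0.01) {
  tab <- merge(truth, results[, c("gene", "p_value")], by = "gene")
  if (nrow(tab) == 0L) stop("results do not cover the truth genes")
  rates <- do.call(rbind, lapply(split(tab, tab$class), function(g)
    data.frame(class = g$class[1L], n = nrow(g),
               rejection_rate = mean(g$p_value < alpha),
               stringsAsFactors = FALSE)))
  rownames(rates) <- NULL
  rk <- rank(results$p_value, ties.method = "min")
  names(rk) <- results$gene
  n_top <- max(1L, ceiling(top_frac * nrow(results)))
  causal_classes <- c("causal_independent", "causal_module")
  caus <- tab[tab$class %in% causal_classes, , drop = FALSE]
  causal <- data.frame(gene = caus$gene, class = caus$class,
                       p_value = caus$p_value,
                       rank = as.integer(rk[caus$gene]),
                       in_top = rk[caus$gene] <= n_top,
                       stringsAsFactors = FALSE, row.names = NULL)
  power_top <- vapply(causal_classes, function(cl) {
    sel <- causal$class == cl
    if (!any(sel)) 0 else mean(causal$in_top[sel])
  }, 0)
  list(class_rates = rates, causal = causal, power_top = power_top,
       alpha = alpha, top_frac = top_frac)
}
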