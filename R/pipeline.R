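#' Configuration for a full pipeline run
#'
#' @param seg Path to a SEG file (copy-number segments).
#' @param expr Path to an expression TSV (samples in rows by default).
#' @param out_dir Output directory (created if absent).
#' @param purity Optional path to a two-column purity TSV.
#' @param gmt Optional path to a GMT gene set file.
#' @param methods Character subset of `c("slr", "lmm")`.
#' @param expr_orientation `"samples"` or `"genes"` (rows on disk).
#' @param seg_dialect `"one-based"` or `"half-open"`.
#' @param value_transform ICNA transform, `"absolute"` or `"identity"`.
#' @param mask_genes Optional path to a one-gene-per-line file removed from
#'   every gene set before enrichment.
#' @param n_perm Permutations per gene set (default 10000).
#' @param purity_alpha Bonferroni level for purity-associated genes.
#' @param seed Integer seed (enrichment permutations).
#' @return Object of class `"run_config"` (a fully serializable list).
#' @export
run_config <- function(seg, expr, out_dir, purity = NULL, gmt = NULL,
                       methods = c("slr", "lmm"),
                       expr_orientation = "samples",
                       seg_dialect = "one-based",
                       value_transform = "absolute", mask_genes = NULL,
                       n_perm = 10000L, purity_alpha = 0.01, seed = 1L) {
  methods <- match.arg(methods, c("slr", "lmm"), several.ok = TRUE)
  structure(list(seg = seg, expr = expr, out_dir = out_dir, purity = purity,
                 gmt = gmt, methods = methods,
                 expr_orientation = expr_orientation,
                 seg_dialect = seg_dialect,
                 value_transform = value_transform, mask_genes = mask_genes,
                 n_perm = as.integer(n_perm), purity_alpha = purity_alpha,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full expression-vs-aneuploidy analysis
#'
#' Orchestrates: ICNA scoring from SEG input, sample join, kinship
#' construction, SLR and/or LMM association scans, optional pre-ranked
#' enrichment per scan, optional purity-gene overlap report, and a
#' machine-readable manifest. Every stage failure aborts with the stage name.
#' Reruns with the same config and seed produce identical result files.
#'
#' @param config A `"run_config"`.
#' @return The output directory path, invisibly. Artifacts written:
#'   `scores.tsv`, `join_report.tsv`, `K.tsv` (LMM runs), `assoc_slr.tsv` /
#'   `assoc_lmm.tsv`, `enrichment_slr.tsv` / `enrichment_lmm.tsv` (with GMT
#'   input), `purity_genes.tsv` and `overlap_<method>.tsv` (with purity
#'   input), `config.json`, `manifest.json`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(force(code),
             error = function(e) stop("pipeline stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }
  artifacts <- character(0)
  emit <- function(name) artifacts <<- c(artifacts, name)

  seg <- stage("read_seg", read_seg(config$seg, dialect = config$seg_dialect))
  scores <- stage("icna", icna_scores(seg,
                                      value_transform = config$value_transform))
  write.table(data.frame(sample = names(scores),
                         icna_score = as.numeric(scores)),
              file.path(config$out_dir, "scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  emit("scores.tsv")

  expr <- stage("read_expression",
                read_expression(config$expr,
                                orientation = config$expr_orientation))
  ids <- intersect(rownames(expr), names(scores))
  join <- data.frame(
    source = c("expression", "icna_scores"),
    n_total = c(nrow(expr), length(scores)),
    n_kept = length(ids),
    n_dropped = c(nrow(expr), length(scores)) - length(ids))
  write.table(join, file.path(config$out_dir, "join_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  emit("join_report.tsv")
  if (length(ids) < 10L)
    stop("pipeline stage 'join' failed: fewer than 10 shared samples")
  expr <- expr[ids, , drop = FALSE]
  y <- setNames(as.numeric(scores[ids]), ids)

  gene_sets <- if (!is.null(config$gmt)) stage("read_gmt",
                                               read_gmt(config$gmt)) else NULL
  if (!is.null(gene_sets) && !is.null(config$mask_genes))
    gene_sets <- mask_collection(gene_sets, readLines(config$mask_genes))

  K <- NULL
  if ("lmm" %in% config$methods) {
    K <- stage("kinship", compute_kinship(standardize_expression(expr)))
    write_matrix_tsv(K, file.path(config$out_dir, "K.tsv"))
    emit("K.tsv")
  }

  scans <- list()
  for (method in config$methods) {
    res <- stage(paste0("association_", method),
                 association_scan(expr, y, method = method, K = K))
    scans[[method]] <- res
    write_association_table(res, file.path(config$out_dir,
                                           paste0("assoc_", method, ".tsv")))
    emit(paste0("assoc_", method, ".tsv"))
    if (!is.null(gene_sets)) {
      enr <- stage(paste0("enrichment_", method), {
        ranked <- build_ranked_list(res)
        extrapolate_q(permutation_fdr(ranked, gene_sets,
                                      n_perm = config$n_perm,
                                      seed = config$seed))
      })
      write.table(enr, file.path(config$out_dir,
                                 paste0("enrichment_", method, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      emit(paste0("enrichment_", method, ".tsv"))
    }
  }

  if (!is.null(config$purity)) {
    cpe <- stage("read_purity", read_purity(config$purity))
    pg <- stage("purity_genes",
                purity_associated_genes(expr, cpe,
                                        alpha = config$purity_alpha))
    write.table(pg$table, file.path(config$out_dir, "purity_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    emit("purity_genes.tsv")
    for (method in names(scans)) {
      ov <- overlap_report(scans[[method]], pg$genes)
      write.table(data.frame(bin = seq_along(ov$counts), count = ov$counts),
                  file.path(config$out_dir,
                            paste0("overlap_", method, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      emit(paste0("overlap_", method, ".tsv"))
    }
  }

  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  emit("config.json")
  manifest <- list(
    package = "aneulmm",
    version = as.character(utils::packageVersion("aneulmm")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' Subsampling experiment: confounding correction versus cohort size
#'
#' Draws random sample subsets of the given sizes (without replacement),
#' reruns the LMM scan on each subset with a freshly built kinship matrix,
#' and records per-gene-class rejection rates and the mean absolute Wald
#' statistic. With ground truth attached, the spurious-association metric on
#' confounder-loaded null genes shows how much larger cohorts let the LMM
#' separate confounding from signal.
#'
#' @param expr Samples-by-genes expression matrix.
#' @param y Named phenotype vector.
#' @param sizes Integer vector of subset sizes (each <= number of joined
#'   samples).
#' @param reps Repeats per size (default 1).
#' @param seed Integer seed; subset draws are reproducible.
#' @param truth Optional truth data frame (see [simulate_dataset()]) for
#'   per-class metrics; without it a single "all" class is reported.
#' @param alpha Rejection level (default 0.05).
#' @return Long data frame: `size`, `rep`, `class`, `n_genes`,
#'   `rejection_rate`, `mean_abs_stat`.
#' @export
subsample_experiment <- function(expr, y, sizes, reps = 1L, seed = 1L,
                                 truth = NULL, alpha = 0.05) {
  ids <- intersect(rownames(expr), names(y))
  if (any(sizes > length(ids)))
    stop("requested subset size ", max(sizes), " exceeds available samples (",
         length(ids), ")")
  set.seed(seed)
  out <- list()
  for (size in sizes) {
    for (r in seq_len(reps)) {
      sub <- sample(ids, size)
      Xs <- expr[sub, , drop = FALSE]
      K <- compute_kinship(standardize_expression(Xs))
      res <- suppressMessages(
        association_scan(Xs, y[sub], method = "lmm", K = K))
      cls <- if (is.null(truth)) {
        data.frame(gene = res$gene, class = "all", stringsAsFactors = FALSE)
      } else truth[, c("gene", "class")]
      tab <- merge(cls, res[, c("gene", "statistic", "p_value")],
                   by = "gene")
      per <- do.call(rbind, lapply(split(tab, tab$class), function(g)
        data.frame(size = size, rep = r, class = g$class[1L],
                   n_genes = nrow(g),
                   rejection_rate = mean(g$p_value < alpha),
                   mean_abs_stat = mean(abs(g$statistic)),
                   stringsAsFactors = FALSE)))
      out[[length(out) + 1L]] <- per
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
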