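#' @importFrom stats var sd cor pnorm pt p.adjust loess predict loess.control
#'   rnorm runif quantile setNames optimize
#' @importFrom utils read.delim write.table count.fields head
NULL

# normalize a header token for alias matching: lower-case, strip punctuation
.norm_name <- function(x) tolower(gsub("[^a-z0-9]", "", tolower(x)))

# find the input column matching any alias; NA if absent
.match_column <- function(cols, aliases) {
  hit <- match(vapply(aliases, .norm_name, ""), .norm_name(cols))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

.seg_aliases <- list(
  sample      = c("sample", "sample_id", "sampleid", "id", "track"),
  chrom       = c("chrom", "chromosome", "chr"),
  start       = c("start", "loc.start", "loc_start", "start.pos", "startpos"),
  end         = c("end", "loc.end", "loc_end", "end.pos", "endpos"),
  seg_value   = c("seg.mean", "seg_mean", "segmean", "segment_mean", "value",
                  "seg.value", "seg_value", "mean", "log2ratio"),
  num_markers = c("num.mark", "num_mark", "nummark", "num.markers", "markers",
                  "num.probes", "probes", "nprobes")
)

#' Read segmented copy-number data (SEG format)
#'
#' Parses a tab-delimited SEG file (one row per copy-number segment) into a
#' list of per-sample segment tables. Column headers are matched
#' case-insensitively against common SEG dialect names (`Sample`, `Chromosome`,
#' `Start`/`loc.start`, `End`/`loc.end`, `Seg.Mean`/`value`; an optional marker
#' count column). Rows whose segment value cannot be parsed as a finite number
#' are dropped and counted.
#'
#' @param path Path to a tab-delimited SEG file with a header row.
#' @param dialect Coordinate convention: `"one-based"` (inclusive; segment
#'   length `end - start + 1`, the default) or `"half-open"` (0-based;
#'   length `end - start`). Stored on the result and consumed by
#'   [icna_score()].
#' @return An object of class `"seg_data"`: a named list with one element per
#'   sample (in order of first appearance), each a list with `sample_id` and a
#'   `segments` data frame (`chrom`, `start`, `end`, `num_markers`,
#'   `seg_value`, input row order preserved). Attributes: `n_dropped` (rows
#'   removed for unparseable segment values) and `dialect`.
#' @export
read_seg <- function(path, dialect = c("one-based", "half-open")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("SEG file not found: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
  if (nrow(raw) == 0L) stop("SEG file is empty (no data rows): ", path)
  cols <- colnames(raw)
  idx <- lapply(.seg_aliases, function(a) .match_column(cols, a))
  required <- c("sample", "chrom", "start", "end", "seg_value")
  for (f in required) {
    if (is.na(idx[[f]]))
      stop("SEG file is missing a required column: '", f,
           "' (accepted headers: ", paste(.seg_aliases[[f]], collapse = ", "),
           ")")
  }
  seg <- data.frame(
    sample    = as.character(raw[[idx$sample]]),
    chrom     = as.character(raw[[idx$chrom]]),
    start     = as.numeric(raw[[idx$start]]),
    end       = as.numeric(raw[[idx$end]]),
    num_markers = if (is.na(idx$num_markers)) NA_real_
                  else suppressWarnings(as.numeric(raw[[idx$num_markers]])),
    seg_value = suppressWarnings(as.numeric(as.character(raw[[idx$seg_value]]))),
    stringsAsFactors = FALSE
  )
  keep <- is.finite(seg$seg_value)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message("read_seg: dropped ", n_dropped,
            " segment row(s) with missing/unparseable segment values")
  seg <- seg[keep, , drop = FALSE]
  if (nrow(seg) == 0L) stop("SEG file has no usable segment rows: ", path)
  if (any(!is.finite(seg$start)) || any(!is.finite(seg$end)))
    stop("SEG file has non-numeric start/end coordinates")
  if (any(seg$end < seg$start))
    stop("SEG file has segment(s) with end < start (first at data row ",
         which(seg$end < seg$start)[1L], " after filtering)")
  ids <- unique(seg$sample)
  samples <- lapply(ids, function(id) {
    s <- seg[seg$sample == id, c("chrom", "start", "end", "num_markers",
                                 "seg_value"), drop = FALSE]
    rownames(s) <- NULL
    structure(list(sample_id = id, segments = s), class = "segmented_sample")
  })
  names(samples) <- ids
  structure(samples, class = "seg_data", n_dropped = n_dropped,
            dialect = dialect)
}

#' Write segmented copy-number data to a SEG file
#'
#' @param seg A `"seg_data"` object (see [read_seg()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(seg, path) {
  rows <- do.call(rbind, lapply(seg, function(s)
    cbind(Sample = s$sample_id, s$segments)))
  colnames(rows) <- c("Sample", "Chromosome", "Start", "End", "Num_Probes",
                      "Segment_Mean")
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a log-expression matrix from TSV
#'
#' Reads a rectangular, labelled TSV into a samples-by-genes numeric matrix.
#' Either orientation on disk is accepted; the result is always samples in
#' rows. Genes with zero variance across samples are flagged (attribute
#' `zero_variance_genes`) but not removed; the kinship/association layers
#' remove them.
#'
#' @param path Path to a tab-delimited file: first column holds row labels,
#'   header holds column labels.
#' @param orientation `"samples"` if samples are in rows on disk (default),
#'   `"genes"` if genes are in rows.
#' @return A numeric matrix (samples x genes) with sample ids as rownames and
#'   gene ids as colnames, plus attribute `zero_variance_genes`.
#' @export
read_expression <- function(path, orientation = c("samples", "genes")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("expression file not found: ", path)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) < 2L) stop("expression file must have a header and data rows")
  if (length(unique(nf)) != 1L)
    stop("expression file is ragged: row ", which(nf != nf[1L])[1L],
         " has ", nf[nf != nf[1L]][1L], " fields, expected ", nf[1L])
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  row_labels <- as.character(tab[[1L]])
  if (anyDuplicated(row_labels))
    stop("duplicate row labels in expression file: ",
         row_labels[duplicated(row_labels)][1L])
  col_labels <- colnames(tab)[-1L]
  if (anyDuplicated(col_labels))
    stop("duplicate column labels in expression file: ",
         col_labels[duplicated(col_labels)][1L])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-finite expression value at row '", row_labels[bad[1L, 1L]],
         "', column '", col_labels[bad[1L, 2L]], "'")
  dimnames(vals) <- list(row_labels, col_labels)
  if (orientation == "genes") vals <- t(vals)
  v <- matrixStats_colVar(vals)
  attr(vals, "zero_variance_genes") <- colnames(vals)[v < 1e-18]
  vals
}

# population column variances without extra deps
matrixStats_colVar <- function(x) {
  mu <- colMeans(x)
  colMeans(x * x) - mu * mu
}

#' Write an expression matrix to TSV
#'
#' @param expr Samples-by-genes numeric matrix with dimnames.
#' @param path Output path.
#' @param orientation Row content on disk: `"samples"` (default) or `"genes"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, orientation = c("samples", "genes")) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "genes") t(expr) else expr
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- if (orientation == "genes") "gene" else "sample"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample tumor purity estimates
#'
#' Reads a two-column TSV mapping sample id to a consensus purity estimate
#' (CPE) in \[0, 1\]. A header row is detected automatically (first line whose
#' second field is not numeric is treated as a header).
#'
#' @param path Path to a two-column tab-delimited file.
#' @return Named numeric vector of purity values in \[0, 1\].
#' @export
read_purity <- function(path) {
  if (!file.exists(path)) stop("purity file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  has_header <- length(first) >= 2L &&
    is.na(suppressWarnings(as.numeric(first[2L])))
  tab <- read.delim(path, sep = "\t", header = has_header,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("purity file must have two tab-delimited columns")
  cpe <- suppressWarnings(as.numeric(tab[[2L]]))
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in purity file")
  if (any(!is.finite(cpe))) stop("non-numeric purity value for sample '",
                                 ids[!is.finite(cpe)][1L], "'")
  if (any(cpe < 0 | cpe > 1))
    stop("purity values must lie in [0, 1]; offending sample '",
         ids[cpe < 0 | cpe > 1][1L], "'")
  setNames(cpe, ids)
}

#' Write purity estimates to a two-column TSV
#' @param cpe Named numeric vector in \[0, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_purity <- function(cpe, path) {
  write.table(data.frame(sample = names(cpe), cpe = as.numeric(cpe)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene set collection (GMT format)
#'
#' Each non-empty line holds: set name, description, and one or more gene ids,
#' tab-delimited. Duplicate genes within a set are stored once (first
#' occurrence kept).
#'
#' @param path Path to a GMT file.
#' @return Object of class `"gene_set_collection"`: a named list, each element
#'   a list with `description` and `genes` (character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  sets <- list()
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has ", length(fields),
           " field(s); need name, description and at least one gene")
    name <- fields[1L]
    if (name %in% names(sets)) stop("duplicate gene set name: ", name)
    sets[[name]] <- list(description = fields[2L],
                         genes = unique(fields[-(1:2)]))
  }
  if (length(sets) == 0L) stop("GMT file contains no gene sets: ", path)
  structure(sets, class = "gene_set_collection")
}

#' Write a gene set collection to GMT
#' @param collection A `"gene_set_collection"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm)
    paste(c(nm, collection[[nm]]$description, collection[[nm]]$genes),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Remove a set of genes from every gene set in a collection
#'
#' Generic masking step (e.g. removing histone genes from canonical pathway
#' sets before enrichment, so that sets containing many of them are not scored
#' on those genes). Sets emptied by masking are dropped with a message.
#'
#' @param collection A `"gene_set_collection"`.
#' @param genes Character vector of gene ids to remove.
#' @return The masked collection.
#' @export
mask_collection <- function(collection, genes) {
  out <- lapply(collection, function(s) {
    s$genes <- setdiff(s$genes, genes)
    s
  })
  empty <- vapply(out, function(s) length(s$genes) == 0L, TRUE)
  if (any(empty))
    message("mask_collection: dropped ", sum(empty), " emptied set(s)")
  structure(out[!empty], class = "gene_set_collection")
}

#' Write an association results table
#'
#' Writes a TSV with columns `gene`, `beta0`, `beta`, `se`, `statistic`,
#' `p_value`, `q_value`, `method`, ordered by ascending p-value with ties
#' broken by gene id.
#'
#' @param results Association results data frame (see [association_scan()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(results, path) {
  if (is.null(results) || nrow(results) == 0L)
    stop("no association results to write")
  if (!"q_value" %in% names(results)) results$q_value <- NA_real_
  ord <- order(results$p_value, results$gene)
  out <- results[ord, c("gene", "beta0", "beta", "se", "statistic",
                        "p_value", "q_value", "method"), drop = FALSE]
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) format(x, digits = 17,
                                                  scientific = TRUE,
                                                  trim = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an association results table written by [write_association_table()]
#' @param path Path to the TSV.
#' @return Data frame with the table's columns, numerics restored.
#' @export
read_association_table <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  for (cl in c("beta0", "beta", "se", "statistic", "p_value", "q_value"))
    tab[[cl]] <- as.numeric(tab[[cl]])
  tab
}

#' Write a square matrix (e.g. kinship) as a labelled TSV
#' @param K Square numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(K, path) {
  df <- data.frame(sample = rownames(K), K, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
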