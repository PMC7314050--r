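#' Expression matrix container
#'
#' A `coex_expr` object holds a genes x samples matrix of log-scale
#' expression values (ratios for two-channel arrays) together with one batch
#' label per sample. Missing values are represented as `NA` in the matrix;
#' downstream network stages require a complete matrix, obtained via
#' [qc_filter()].
#'
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   are gene identifiers (e.g. locus tags such as `"DR_0997"`), colnames are
#'   sample identifiers. Both must be unique.
#' @param batch character vector of batch labels, one per sample
#'   (recycled to `"unknown"` when omitted).
#' @return An object of class `coex_expr`: a list with elements `values`
#'   (the matrix) and `batch` (named character vector).
#' @export
coex_expr <- function(values, batch = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate gene IDs: ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs")
  if (any(is.infinite(values)))
    stop("non-finite (infinite) expression values present")
  if (is.null(batch)) batch <- rep("unknown", ncol(values))
  if (length(batch) != ncol(values))
    stop("need exactly one batch label per sample")
  batch <- as.character(batch)
  names(batch) <- colnames(values)
  structure(list(values = values, batch = batch), class = "coex_expr")
}

#' @export
print.coex_expr <- function(x, ...) {
  cat(sprintf("coex_expr: %d genes x %d samples, %d batch(es), %d missing cells\n",
              nrow(x$values), ncol(x$values), length(unique(x$batch)),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.coex_expr <- function(x) dim(x$values)

#' Load an expression matrix from tab-separated text
#'
#' Reads a genes x samples table: first row sample IDs, first column gene
#' IDs, cells tab-separated. Empty cells and the literal strings `NA`/`nan`
#' become missing values. An optional manifest maps sample IDs to batch
#' labels (two tab-separated columns, no header); samples absent from the
#' manifest get batch `"unknown"`.
#'
#' @param path path to the expression TSV.
#' @param manifest_path optional path to a sample/batch manifest TSV.
#' @return A [coex_expr] object.
#' @export
load_expression <- function(path, manifest_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("expression file needs a header and >=1 gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  # header may or may not carry a leading cell for the gene-ID column
  ncol_data <- length(fields[[2]]) - 1L
  samples <- if (length(header) == ncol_data + 1L) header[-1] else header
  if (length(samples) != ncol_data)
    stop("header has ", length(samples), " sample IDs but rows have ",
         ncol_data, " value columns")
  gene_ids <- character(length(fields) - 1L)
  vals <- matrix(NA_real_, length(fields) - 1L, ncol_data)
  for (i in seq_along(gene_ids)) {
    f <- fields[[i + 1L]]
    if (length(f) != ncol_data + 1L)
      stop("ragged row at line ", i + 1L, ": expected ", ncol_data + 1L,
           " fields, found ", length(f))
    gene_ids[i] <- f[1]
    v <- f[-1]
    v[v %in% c("", "NA", "na", "nan", "NaN")] <- NA
    vals[i, ] <- as.numeric(v)
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene IDs: ", paste(dup, collapse = ", "))
  dimnames(vals) <- list(gene_ids, samples)
  batch <- rep("unknown", length(samples))
  if (!is.null(manifest_path)) {
    man <- utils::read.delim(manifest_path, header = FALSE,
                             colClasses = "character")
    if (ncol(man) < 2) stop("manifest needs two tab-separated columns")
    hit <- match(samples, man[[1]])
    batch[!is.na(hit)] <- man[[2]][hit[!is.na(hit)]]
  }
  coex_expr(vals, batch)
}

#' Write an expression matrix (and optional manifest) to TSV
#'
#' Inverse of [load_expression()]: round-trips values bit-exactly (via
#' full-precision formatting) and preserves the missing-value mask.
#'
#' @param expr a [coex_expr] object.
#' @param path output path for the expression TSV.
#' @param manifest_path optional output path for the sample/batch manifest.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, manifest_path = NULL) {
  v <- expr$values
  body <- apply(v, 1L, function(r) {
    s <- sprintf("%.17g", r)
    s[is.na(r)] <- "NA"
    paste(s, collapse = "\t")
  })
  lines <- c(paste(c("gene_id", colnames(v)), collapse = "\t"),
             paste(rownames(v), body, sep = "\t"))
  writeLines(lines, path)
  if (!is.null(manifest_path))
    writeLines(paste(colnames(v), expr$batch, sep = "\t"), manifest_path)
  invisible(path)
}

#' Merge several expression matrices into one frame
#'
#' Sample columns are prefixed with their batch label (`batch:sample`) to keep
#' them globally unique, then concatenated in input order. Gene handling:
#' `"intersect"` keeps genes present in every input; `"union"` keeps all
#' genes, masking cells where a gene is absent from a batch.
#'
#' @param matrices list of [coex_expr] objects.
#' @param mode `"intersect"` or `"union"`.
#' @return A merged [coex_expr].
#' @export
merge_expression <- function(matrices, mode = c("intersect", "union")) {
  mode <- match.arg(mode)
  if (!length(matrices)) stop("need at least one matrix")
  if (length(matrices) == 1L) return(matrices[[1]])
  gene_sets <- lapply(matrices, function(m) rownames(m$values))
  genes <- if (mode == "intersect") Reduce(intersect, gene_sets)
           else unique(unlist(gene_sets))
  if (!length(genes)) stop("no genes survive the intersection")
  cols <- unlist(lapply(matrices, function(m)
    paste(m$batch, colnames(m$values), sep = ":")))
  if (anyDuplicated(cols))
    stop("colliding sample IDs after batch prefixing: ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  out <- matrix(NA_real_, length(genes), length(cols),
                dimnames = list(genes, cols))
  batch <- character(length(cols))
  at <- 0L
  for (m in matrices) {
    idx <- at + seq_len(ncol(m$values))
    common <- intersect(genes, rownames(m$values))
    out[common, idx] <- m$values[common, , drop = FALSE]
    batch[idx] <- m$batch
    at <- at + ncol(m$values)
  }
  coex_expr(out, batch)
}

#' Quality-filter an expression matrix
#'
#' Drops genes whose missing fraction exceeds `max_missing_frac` or whose
#' non-missing values have zero variance (either makes correlations
#' undefined). Remaining missing cells are optionally imputed with the
#' gene's median.
#'
#' @param expr a [coex_expr] object.
#' @param max_missing_frac maximum tolerated fraction of missing samples per
#'   gene, in `[0, 1)`.
#' @param impute if `TRUE` (default), median-impute surviving missing cells.
#' @return A [coex_expr] with attribute `"removed"`: a data.frame of dropped
#'   genes and the reason (`"missing"` or `"zero variance"`).
#' @export
qc_filter <- function(expr, max_missing_frac = 0.5, impute = TRUE) {
  if (max_missing_frac < 0 || max_missing_frac >= 1)
    stop("'max_missing_frac' must be in [0, 1)")
  v <- expr$values
  miss <- rowMeans(is.na(v))
  sds <- apply(v, 1L, stats::sd, na.rm = TRUE)
  drop_miss <- miss > max_missing_frac
  drop_var <- !drop_miss & (is.na(sds) | sds == 0)
  keep <- !(drop_miss | drop_var)
  if (!any(keep)) stop("all genes dropped by qc_filter")
  removed <- data.frame(
    gene_id = rownames(v)[!keep],
    reason = ifelse(drop_miss[!keep], "missing", "zero variance"),
    stringsAsFactors = FALSE)
  v <- v[keep, , drop = FALSE]
  if (impute && anyNA(v)) {
    for (i in which(rowSums(is.na(v)) > 0)) {
      med <- stats::median(v[i, ], na.rm = TRUE)
      v[i, is.na(v[i, ])] <- med
    }
  }
  out <- coex_expr(v, expr$batch)
  attr(out, "removed") <- removed
  out
}

#' Per-batch distribution summaries and MDS embedding
#'
#' Computes, per batch, the five-number summary (min, Q1, median, Q3, max;
#' quartiles by the linear-interpolation convention, `quantile type 6`) of all
#' pooled expression values, and a classical metric MDS (principal
#' coordinates) of the samples: the squared Euclidean inter-sample distance
#' matrix is double-centered and eigendecomposed, and the top two coordinate
#' axes, scaled by the square roots of their eigenvalues, are returned. Used
#' to inspect -- not correct -- batch effects before network construction.
#'
#' @param expr a complete (no missing values) [coex_expr] with >= 3 samples.
#' @return A list of class `batch_diagnostics`: `summaries` (batch x 5
#'   matrix), `coords` (samples x 2), `eigenvalues` (non-increasing).
#' @export
batch_diagnostics <- function(expr) {
  v <- expr$values
  if (ncol(v) < 3) stop("need at least 3 samples")
  if (anyNA(v)) stop("missing values present; run qc_filter first")
  batches <- sort(unique(expr$batch))
  summ <- t(vapply(batches, function(b) {
    pooled <- as.vector(v[, expr$batch == b, drop = FALSE])
    q <- stats::quantile(pooled, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
    c(min = min(pooled), q1 = q[1], median = q[2], q3 = q[3], max = max(pooled))
  }, numeric(5)))
  d <- stats::dist(t(v))
  mds <- stats::cmdscale(d, k = 2, eig = TRUE)
  coords <- mds$points
  colnames(coords) <- c("coord1", "coord2")
  structure(list(summaries = summ, coords = coords,
                 eigenvalues = sort(mds$eig, decreasing = TRUE)),
            class = "batch_diagnostics")
}
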