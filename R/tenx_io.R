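#' Sparse gene-by-cell count matrix container
#'
#' A `CountMatrix` bundles a sparse non-negative integer matrix of raw UMI
#' counts (genes as rows, cells as columns — the 10x on-disk convention) with
#' gene identifiers, gene symbols, cell barcodes and a per-gene mitochondrial
#' flag. All downstream operations in the package state explicitly which axis
#' holds cells.
#'
#' @param counts sparse (or dense) numeric matrix, genes x cells, non-negative
#'   integers.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param gene_symbols character vector of gene symbols, same length as
#'   `gene_ids`. Defaults to the ids.
#' @param barcodes character vector of unique cell barcodes (columns).
#' @param mito logical per-gene flag marking mitochondrial genes. If `NULL`,
#'   flags are derived from `gene_symbols` via `mito_prefix`.
#' @param mito_prefix case-insensitive symbol prefix used to flag
#'   mitochondrial genes when `mito` is not given. Default `"mt-"`, the
#'   zebrafish nomenclature.
#' @return an object of class `CountMatrix`: a list with elements `counts`
#'   (a `dgCMatrix`), `genes` (data.frame with `id`, `symbol`, `mito`) and
#'   `barcodes`.
#' @export
count_matrix <- function(counts, gene_ids, gene_symbols = gene_ids, barcodes,
                         mito = NULL, mito_prefix = "mt-") {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(gene_ids))
    stop("gene list length (", length(gene_ids),
         ") does not match matrix rows (", nrow(counts), ")")
  if (ncol(counts) != length(barcodes))
    stop("barcode list length (", length(barcodes),
         ") does not match matrix columns (", ncol(counts), ")")
  if (length(gene_symbols) != length(gene_ids))
    stop("gene_symbols length does not match gene_ids")
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  if (anyDuplicated(barcodes)) stop("cell barcodes must be unique")
  x <- counts@x
  if (any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers")
  if (is.null(mito)) {
    mito <- startsWith(tolower(as.character(gene_symbols)), tolower(mito_prefix))
  }
  stopifnot(length(mito) == length(gene_ids))
  structure(list(
    counts = counts,
    genes = data.frame(id = as.character(gene_ids),
                       symbol = as.character(gene_symbols),
                       mito = as.logical(mito),
                       stringsAsFactors = FALSE),
    barcodes = as.character(barcodes)
  ), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells, %d nonzeros, %d mito genes\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x),
              sum(x$genes$mito)))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Per-sample metadata record
#'
#' @param sample sample identifier (unique within a dataset).
#' @param age_months numeric age in months.
#' @param status spermatogenesis status: `"complete"`, `"incomplete"` or
#'   `"unknown"`.
#' @return a one-row data.frame with columns `sample`, `age_months`, `status`.
#' @export
sample_meta <- function(sample, age_months, status = c("unknown", "complete", "incomplete")) {
  status <- match.arg(status)
  data.frame(sample = as.character(sample), age_months = as.numeric(age_months),
             status = status, stringsAsFactors = FALSE)
}

.open_maybe_gz <- function(dir, base) {
  for (f in c(file.path(dir, base), file.path(dir, paste0(base, ".gz")))) {
    if (file.exists(f)) return(f)
  }
  stop("missing file in 10x directory '", dir, "': ", base, "(.gz)")
}

#' Read a 10x-style matrix directory
#'
#' Expects `matrix.mtx`, `features.tsv` and `barcodes.tsv` (optionally
#' gzipped) under `path`. The features file may have one column (gene id) or
#' two or more (id, symbol, ...). Mitochondrial genes are flagged by symbol
#' prefix unless an explicit gene list is supplied.
#'
#' @param path directory containing the three files.
#' @param mito_prefix case-insensitive symbol prefix for mito genes.
#' @param mito_genes optional explicit character vector of mito gene ids or
#'   symbols, overriding the prefix rule.
#' @return a [count_matrix()] object.
#' @export
read_mtx_dir <- function(path, mito_prefix = "mt-", mito_genes = NULL) {
  mtx_f <- .open_maybe_gz(path, "matrix.mtx")
  feat_f <- .open_maybe_gz(path, "features.tsv")
  bc_f <- .open_maybe_gz(path, "barcodes.tsv")
  m <- tryCatch(Matrix::readMM(mtx_f),
                error = function(e) stop("malformed Matrix Market file '",
                                         mtx_f, "': ", conditionMessage(e)))
  m <- methods::as(methods::as(m, "dMatrix"), "CsparseMatrix")
  feats <- utils::read.delim(feat_f, header = FALSE, stringsAsFactors = FALSE)
  bcs <- utils::read.delim(bc_f, header = FALSE, stringsAsFactors = FALSE)[[1]]
  if (nrow(feats) != nrow(m))
    stop("features file '", feat_f, "' has ", nrow(feats),
         " rows but matrix '", mtx_f, "' has ", nrow(m), " rows")
  if (length(bcs) != ncol(m))
    stop("barcodes file '", bc_f, "' has ", length(bcs),
         " entries but matrix '", mtx_f, "' has ", ncol(m), " columns")
  if (any(m@x != round(m@x)))
    stop("non-integer entries in '", mtx_f, "'")
  ids <- as.character(feats[[1]])
  symbols <- if (ncol(feats) >= 2) as.character(feats[[2]]) else ids
  mito <- NULL
  if (!is.null(mito_genes)) mito <- ids %in% mito_genes | symbols %in% mito_genes
  count_matrix(m, ids, symbols, bcs, mito = mito, mito_prefix = mito_prefix)
}

#' Write a CountMatrix as a 10x-style directory
#'
#' Writes Matrix Market coordinate format with 1-based indices, genes as rows
#' and cells as columns, plus `features.tsv` (id, symbol) and `barcodes.tsv`.
#' Plain (uncompressed) files are written.
#'
#' @param x a [count_matrix()] object.
#' @param path output directory, created if needed.
#' @return invisibly, `path`.
#' @export
write_mtx_dir <- function(x, path) {
  stopifnot(inherits(x, "CountMatrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  Matrix::writeMM(x$counts, file.path(path, "matrix.mtx"))
  utils::write.table(x$genes[, c("id", "symbol")],
                     file.path(path, "features.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(x$barcodes, file.path(path, "barcodes.tsv"))
  invisible(path)
}

#' Merge per-sample count matrices into one dataset
#'
#' Genes are unioned by gene id (entries absent from a sample are zero);
#' cells are concatenated with sample-prefixed barcodes. Gene symbols and
#' mito flags are taken from the first sample carrying each gene.
#'
#' @param matrices list of [count_matrix()] objects, one per sample.
#' @param metas data.frame of per-sample metadata (one row per matrix, see
#'   [sample_meta()]), or a list of such rows.
#' @return a list with `matrix` (merged `CountMatrix`), `cells` (data.frame
#'   with `cell`, `sample`, `age_months`, `status` for every merged cell) and
#'   `metas` (the row-bound metadata).
#' @export
merge_samples <- function(matrices, metas) {
  if (length(matrices) < 1) stop("need at least one sample")
  if (is.list(metas) && !is.data.frame(metas)) metas <- do.call(rbind, metas)
  stopifnot(nrow(metas) == length(matrices))
  if (anyDuplicated(metas$sample)) stop("duplicate sample ids in metadata")

  all_ids <- unique(unlist(lapply(matrices, function(m) m$genes$id)))
  gene_tab <- do.call(rbind, lapply(matrices, function(m) m$genes))
  gene_tab <- gene_tab[!duplicated(gene_tab$id), , drop = FALSE]
  gene_tab <- gene_tab[match(all_ids, gene_tab$id), , drop = FALSE]

  blocks <- vector("list", length(matrices))
  cell_meta <- vector("list", length(matrices))
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    sid <- metas$sample[i]
    idx <- match(m$genes$id, all_ids)
    cm <- m$counts
    tm <- Matrix::sparseMatrix(i = idx[cm@i + 1L],
                               j = rep.int(seq_len(ncol(cm)), diff(cm@p)),
                               x = cm@x,
                               dims = c(length(all_ids), ncol(cm)))
    blocks[[i]] <- tm
    cell_meta[[i]] <- data.frame(
      cell = paste0(sid, "_", m$barcodes),
      sample = sid,
      age_months = metas$age_months[i],
      status = metas$status[i],
      stringsAsFactors = FALSE)
  }
  merged <- do.call(cbind, blocks)
  cells <- do.call(rbind, cell_meta)
  out <- count_matrix(merged, gene_tab$id, gene_tab$symbol, cells$cell,
                      mito = gene_tab$mito)
  list(matrix = out, cells = cells, metas = metas)
}
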