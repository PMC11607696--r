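#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the number of detected genes (count > 0), the
#' total UMI count and the mitochondrial percentage
#' (100 * mito counts / total counts). Cells with zero total counts get
#' `pct_mito = 0` rather than NaN.
#'
#' @param x a [count_matrix()] object.
#' @return data.frame with columns `cell`, `n_genes`, `total_counts`,
#'   `pct_mito`, one row per cell in matrix order.
#' @export
compute_cell_qc <- function(x) {
  stopifnot(inherits(x, "CountMatrix"))
  if (ncol(x$counts) == 0 || nrow(x$counts) == 0)
    stop("empty count matrix")
  total <- Matrix::colSums(x$counts)
  ngene <- Matrix::colSums(x$counts > 0)
  mito_counts <- if (any(x$genes$mito)) {
    Matrix::colSums(x$counts[x$genes$mito, , drop = FALSE])
  } else rep(0, ncol(x$counts))
  pct <- ifelse(total > 0, 100 * mito_counts / total, 0)
  data.frame(cell = x$barcodes, n_genes = as.integer(ngene),
             total_counts = as.numeric(total), pct_mito = as.numeric(pct),
             stringsAsFactors = FALSE)
}

#' Cell-filter parameters
#'
#' @param max_pct_mito cells with mito percentage strictly above this are
#'   removed (default 5, i.e. the ">5%" rule).
#' @param min_genes cells must detect strictly more than this many genes
#'   (default 200, exclusive).
#' @param upper_rule how the per-sample upper gene-count threshold `n` is
#'   derived from the pre-filter distribution of detected genes:
#'   `"q3"` (the third quartile itself), `"tukey_fence"` (Q3 + 1.5 IQR) or
#'   `"fixed"` (use `fixed_upper`).
#' @param fixed_upper required when `upper_rule = "fixed"`.
#' @return a `filter_params` list.
#' @export
filter_params <- function(max_pct_mito = 5, min_genes = 200,
                          upper_rule = c("q3", "tukey_fence", "fixed"),
                          fixed_upper = NULL) {
  upper_rule <- match.arg(upper_rule)
  stopifnot(min_genes >= 0, max_pct_mito > 0, max_pct_mito <= 100)
  if (upper_rule == "fixed" && is.null(fixed_upper))
    stop("upper_rule = 'fixed' requires fixed_upper")
  structure(list(max_pct_mito = max_pct_mito, min_genes = min_genes,
                 upper_rule = upper_rule, fixed_upper = fixed_upper),
            class = "filter_params")
}

#' Upper gene-count threshold from the interquartile range
#'
#' Quartiles use the linear-interpolation quantile definition
#' (`stats::quantile` type 7): with sorted values x_(1) <= ... <= x_(n), the
#' p-th quantile interpolates linearly between the order statistics at
#' positions 1 + p(n-1). This definition is fixed so thresholds are
#' reproducible across implementations.
#'
#' @param values numeric vector of per-cell detected gene counts (>= 4
#'   values).
#' @param rule `"q3"` returns Q3; `"tukey_fence"` returns Q3 + 1.5 (Q3 - Q1);
#'   `"fixed"` returns `fixed_upper`.
#' @param fixed_upper threshold used when `rule = "fixed"`.
#' @return the threshold `n` (cells are kept when detected genes < n).
#' @export
iqr_upper_threshold <- function(values, rule = c("q3", "tukey_fence", "fixed"),
                                fixed_upper = NULL) {
  rule <- match.arg(rule)
  if (rule == "fixed") {
    if (is.null(fixed_upper)) stop("rule = 'fixed' requires fixed_upper")
    return(as.numeric(fixed_upper))
  }
  if (length(values) < 4)
    stop("need at least 4 values to estimate quartiles, got ", length(values))
  q <- stats::quantile(values, probs = c(0.25, 0.75), names = FALSE, type = 7)
  if (rule == "q3") q[2] else q[2] + 1.5 * (q[2] - q[1])
}

#' Two-sided cell filter
#'
#' Keeps cells satisfying all of: `pct_mito <= max_pct_mito` (the filter
#' removes only cells strictly above the cutoff), `n_genes > min_genes`
#' (exclusive lower bound) and `n_genes < n` where `n` is the upper threshold
#' computed per sample on the pre-filter distribution by
#' [iqr_upper_threshold()]. Criteria are conjunctive, so their order is
#' immaterial.
#'
#' @param x a [count_matrix()] object.
#' @param qc the matching QC table from [compute_cell_qc()].
#' @param params a [filter_params()] object.
#' @param samples optional per-cell sample labels; the upper threshold is
#'   computed within each sample. Default: one sample.
#' @return list with `matrix` (filtered `CountMatrix`, same gene axis),
#'   `report` (class `filter_report`: per-sample thresholds, rule, cells
#'   in/out, removals per criterion — a cell failing several criteria is
#'   counted under each) and `keep` (logical over input cells).
#' @export
filter_cells <- function(x, qc, params = filter_params(), samples = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  if (!identical(qc$cell, x$barcodes))
    stop("QC table is not aligned to the matrix cells")
  n_cells <- ncol(x$counts)
  if (is.null(samples)) samples <- rep("all", n_cells)
  stopifnot(length(samples) == n_cells)

  upper <- vapply(split(qc$n_genes, samples), function(v) {
    iqr_upper_threshold(v, rule = params$upper_rule,
                        fixed_upper = params$fixed_upper)
  }, numeric(1))
  upper_per_cell <- upper[match(samples, names(upper))]

  fail_mito <- qc$pct_mito > params$max_pct_mito
  fail_low <- qc$n_genes <= params$min_genes
  fail_high <- unname(qc$n_genes >= upper_per_cell)
  keep <- !(fail_mito | fail_low | fail_high)

  report <- structure(list(
    rule = params$upper_rule,
    max_pct_mito = params$max_pct_mito,
    min_genes = params$min_genes,
    upper_thresholds = as.list(upper),
    cells_in = n_cells,
    cells_kept = sum(keep),
    removed_pct_mito = sum(fail_mito),
    removed_low_genes = sum(fail_low),
    removed_high_genes = sum(fail_high)
  ), class = "filter_report")
  if (sum(keep) == 0) warning("no cells survive the filter")

  filtered <- count_matrix(x$counts[, keep, drop = FALSE],
                           x$genes$id, x$genes$symbol,
                           x$barcodes[keep], mito = x$genes$mito)
  list(matrix = filtered, report = report, keep = keep)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "filter_report: %d -> %d cells (rule=%s; mito>%g%%: %d, genes<=%d: %d, genes>=upper: %d)\n",
    x$cells_in, x$cells_kept, x$rule, x$max_pct_mito, x$removed_pct_mito,
    x$min_genes, x$removed_low_genes, x$removed_high_genes))
  invisible(x)
}

#' Write a filter report as JSON
#'
#' @param report a `filter_report` from [filter_cells()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
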