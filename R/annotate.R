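#' Log-normalize a count matrix
#'
#' Per cell: counts / total counts * scale, then natural log1p — the standard
#' log-normalization used for clustering. Zero-count cells yield an all-zero
#' column rather than a division error.
#'
#' @param x a [count_matrix()] object (usually post-filter).
#' @param scale library-size scale factor (default 10000).
#' @return an `ExprMatrix`: list with `expr` (sparse genes x cells
#'   log-normalized matrix, gene symbols as rownames, barcodes as colnames),
#'   `genes` (the gene table) and `scale`.
#' @export
normalize_log <- function(x, scale = 10000) {
  stopifnot(inherits(x, "CountMatrix"))
  total <- Matrix::colSums(x$counts)
  sf <- ifelse(total > 0, scale / total, 0)
  expr <- x$counts %*% Matrix::Diagonal(x = sf)
  expr@x <- log1p(expr@x)
  expr <- methods::as(expr, "CsparseMatrix")
  dimnames(expr) <- list(x$genes$symbol, x$barcodes)
  structure(list(expr = expr, genes = x$genes, scale = scale),
            class = "ExprMatrix")
}

#' @export
print.ExprMatrix <- function(x, ...) {
  cat(sprintf("ExprMatrix: %d genes x %d cells (log1p, scale=%g)\n",
              nrow(x$expr), ncol(x$expr), x$scale))
  invisible(x)
}

.row_vars <- function(m) {
  # variance per gene of a sparse genes x cells matrix, n-1 denominator
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  sq <- Matrix::rowSums(m^2)
  pmax((sq - n * mu^2) / (n - 1), 0)
}

#' Select highly variable genes
#'
#' Top `n_top` genes by variance of log-normalized expression. Ties are
#' broken deterministically by gene id (lexicographic), so the selection is
#' reproducible.
#'
#' @param expr an `ExprMatrix` from [normalize_log()].
#' @param n_top number of genes to keep (default 2000; capped at the number
#'   of genes).
#' @return character vector of selected gene ids.
#' @export
select_hvg <- function(expr, n_top = 2000) {
  stopifnot(inherits(expr, "ExprMatrix"))
  n_top <- min(n_top, nrow(expr$expr))
  v <- .row_vars(expr$expr)
  ord <- order(-v, expr$genes$id, method = "radix")
  expr$genes$id[ord[seq_len(n_top)]]
}

#' PCA embedding of cells
#'
#' Centers (and by default unit-scales) the selected gene vectors and
#' projects cells onto the top `d` principal axes. The sign of each
#' component is fixed so that its largest-magnitude gene loading is
#' positive, making the embedding deterministic.
#'
#' @param expr an `ExprMatrix`.
#' @param genes gene ids to use (e.g. from [select_hvg()]); `NULL` = all.
#' @param d number of components (default 20; must be < min(cells, genes)).
#' @param scale_genes unit-scale genes before PCA (constant genes are left
#'   unscaled). Default `TRUE`.
#' @return an `Embedding`: list with `coords` (cells x d matrix, rownames =
#'   barcodes), `var_explained` (fraction per component) and `d`.
#' @export
embed_pca <- function(expr, genes = NULL, d = 20, scale_genes = TRUE) {
  stopifnot(inherits(expr, "ExprMatrix"))
  m <- expr$expr
  if (!is.null(genes)) {
    keep <- match(genes, expr$genes$id)
    if (anyNA(keep)) stop("unknown gene ids in 'genes'")
    m <- m[keep, , drop = FALSE]
  }
  if (d >= min(ncol(m), nrow(m)))
    stop("d must be smaller than min(cells, genes)")
  x <- t(as.matrix(m))                      # cells x genes
  x <- scale(x, center = TRUE, scale = FALSE)
  if (scale_genes) {
    s <- apply(x, 2, stats::sd)
    s[s == 0] <- 1
    x <- sweep(x, 2, s, "/")
  }
  sv <- svd(x, nu = 0, nv = d)
  # sign convention: largest-magnitude loading positive
  flip <- vapply(seq_len(d), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  v <- sweep(sv$v[, seq_len(d), drop = FALSE], 2, flip, "*")
  coords <- x %*% v
  rownames(coords) <- colnames(m)
  colnames(coords) <- paste0("PC", seq_len(d))
  total_var <- sum(sv$d^2)
  ve <- if (total_var > 0) sv$d[seq_len(d)]^2 / total_var else rep(0, d)
  structure(list(coords = coords, var_explained = ve, d = d),
            class = "Embedding")
}

# exact k nearest neighbours (Euclidean, brute force in blocks)
# returns n x k matrix of neighbour indices, self excluded,
# ties broken by index for determinism
.knn_indices <- function(coords, k, block = 1024L) {
  n <- nrow(coords)
  stopifnot(k >= 1, k < n)
  sq <- rowSums(coords^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(coords[idx, , drop = FALSE], coords)
    for (r in seq_along(idx)) {
      d2[r, idx[r]] <- Inf
      ord <- order(d2[r, ], seq_len(n), method = "radix")
      out[idx[r], ] <- ord[seq_len(k)]
    }
  }
  out
}

# symmetric 0/1 adjacency (union of directed kNN edges), no self-edges
.knn_adjacency <- function(coords, k) {
  nn <- .knn_indices(coords, k)
  n <- nrow(coords)
  i <- rep(seq_len(n), each = k)
  j <- as.vector(t(nn))
  a <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(n, n), use.last.ij = FALSE)
  a@x[] <- 1
  a
}

#' Cluster cells on a kNN graph
#'
#' Builds a symmetrized exact kNN graph on the embedding and partitions it.
#' The default `"label_prop"` method is deterministic asynchronous label
#' propagation: cells are visited in a canonical order (lexicographic on
#' their embedding coordinates, so the partition is invariant to cell-order
#' permutation), each adopting the most frequent label among its
#' neighbours, ties broken by the smallest label, until no label changes.
#' Label propagation resolves separated groups (one cluster per blob) but
#' collapses a connected differentiation continuum into a single cluster;
#' the `"leiden"` method (igraph modularity-based Leiden, run on the
#' canonically ordered graph with a fixed RNG state, hence equally
#' deterministic and permutation-invariant) partitions such a continuum
#' into segments and is what the trajectory root selection uses. Labels are
#' renumbered 0,1,... by decreasing cluster size (ties by first occurrence
#' in canonical order).
#'
#' @param embedding an `Embedding` from [embed_pca()], or a plain cells x d
#'   matrix.
#' @param k_neighbors neighbours per cell (default 15; must be >= 2 and
#'   < number of cells).
#' @param method `"label_prop"` (default) or `"leiden"`.
#' @param max_iter sweep limit for label propagation (default 100).
#' @return a `ClusterLabels`: list with `labels` (integer per cell, 0-based,
#'   contiguous), `n_clusters`, and `k_neighbors`.
#' @export
cluster_cells <- function(embedding, k_neighbors = 15,
                          method = c("label_prop", "leiden"), max_iter = 100) {
  method <- match.arg(method)
  coords <- if (inherits(embedding, "Embedding")) embedding$coords else as.matrix(embedding)
  n <- nrow(coords)
  if (k_neighbors < 2) stop("k_neighbors must be >= 2")
  if (n <= k_neighbors) stop("fewer cells (", n, ") than k_neighbors + 1")

  canon <- do.call(order, c(lapply(seq_len(ncol(coords)), function(j) coords[, j]),
                            list(method = "radix")))
  if (method == "leiden") {
    adj <- .knn_adjacency(coords[canon, , drop = FALSE], k_neighbors)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    mem <- withr::with_seed(0L, igraph::membership(
      igraph::cluster_leiden(g, objective_function = "modularity",
                             n_iterations = 10)))
    lab <- integer(n)
    lab[canon] <- as.integer(mem)
  } else {
    adj <- .knn_adjacency(coords, k_neighbors)
    nbr <- lapply(seq_len(n), function(i) adj@i[(adj@p[i] + 1L):adj@p[i + 1L]] + 1L)
    # initial labels: rank in canonical order (permutation-invariant)
    lab <- integer(n)
    lab[canon] <- seq_len(n)
    for (iter in seq_len(max_iter)) {
      changed <- FALSE
      for (i in canon) {
        nl <- lab[nbr[[i]]]
        if (length(nl) == 0) next
        tab <- tabulate(nl, nbins = n)
        best <- which(tab == max(tab))[1L]   # smallest label among modal
        if (best != lab[i]) { lab[i] <- best; changed <- TRUE }
      }
      if (!changed) break
    }
  }
  # renumber by decreasing size, ties by first occurrence in canonical order
  first_seen <- match(sort(unique(lab)), lab[canon])
  u <- sort(unique(lab))
  sizes <- tabulate(match(lab, u), nbins = length(u))
  ord <- order(-sizes, first_seen)
  new_id <- integer(length(u))
  new_id[ord] <- seq_along(u) - 1L
  labels <- new_id[match(lab, u)]
  structure(list(labels = labels, n_clusters = length(u),
                 k_neighbors = k_neighbors),
            class = "ClusterLabels")
}

#' @export
print.ClusterLabels <- function(x, ...) {
  cat(sprintf("ClusterLabels: %d cells in %d clusters (k=%d)\n",
              length(x$labels), x$n_clusters, x$k_neighbors))
  invisible(x)
}

#' Marker panel for zebrafish testis cell types
#'
#' The canonical markers used to identify testis cell types:
#' spermatogonia (ddx4), spermatocytes (sycp3), spermatids (ccnb3),
#' spermatozoa (tssk6), Sertoli cells (gsdf), Leydig cells (star),
#' smooth muscle cells (tagln, acta2), blood (hbba1), macrophages (mpeg1.1)
#' and lymphocytes (lck, the pan-T-cell kinase). The panel also carries a
#' configurable list of reportable genes of interest (spermatogonial
#' regulators, pluripotency factors and oogenesis genes) for dot-plot
#' summaries.
#'
#' @param extra named character vector of additional gene -> type mappings.
#' @param reportable character vector of genes to report in summaries.
#' @return a `MarkerPanel`: list with `markers` (data.frame gene, type) and
#'   `reportable`.
#' @export
default_marker_panel <- function(extra = NULL,
                                 reportable = c("e2f5", "piwil1", "ilf2",
                                                "sumo3b", "nanog", "pou5f3",
                                                "zp3.2", "nanos3", "dmrt1")) {
  genes <- c(ddx4 = "spermatogonia", sycp3 = "spermatocytes",
             ccnb3 = "spermatids", tssk6 = "spermatozoa",
             gsdf = "sertoli", star = "leydig",
             tagln = "smooth_muscle", acta2 = "smooth_muscle",
             hbba1 = "blood", mpeg1.1 = "macrophage", lck = "lymphocyte")
  if (!is.null(extra)) genes <- c(genes, extra)
  if (anyDuplicated(names(genes))) stop("each gene must map to exactly one type")
  structure(list(
    markers = data.frame(gene = names(genes), type = unname(genes),
                         stringsAsFactors = FALSE),
    reportable = reportable
  ), class = "MarkerPanel")
}

#' Look up the cell type of a marker gene
#'
#' @param panel a `MarkerPanel`.
#' @param gene gene symbol.
#' @return the mapped cell type, or `NA_character_` if the gene is not in
#'   the panel (an absent gene is not an error).
#' @export
panel_lookup <- function(panel, gene) {
  i <- match(gene, panel$markers$gene)
  if (is.na(i)) NA_character_ else panel$markers$type[i]
}

#' Marker-based cell typing of clusters
#'
#' For each cluster and each cell type, the mean log-normalized expression of
#' the type's markers is averaged, then z-scored across clusters. A cluster
#' is assigned the arg-max type when that z-score reaches `z_threshold`
#' (default 1), otherwise `"unknown"`; cells inherit their cluster's call.
#' Types whose markers are all absent from the matrix are unassignable (a
#' warning names the missing genes).
#'
#' @param expr an `ExprMatrix`.
#' @param labels a `ClusterLabels` (or integer vector per cell).
#' @param panel a `MarkerPanel` from [default_marker_panel()].
#' @param z_threshold minimum across-cluster z-score for assignment.
#' @return a `TypeAssignment`: list with `cell_type` (per cell), `cluster`
#'   (per cell), `cluster_type` (per cluster data.frame: cluster, type,
#'   best_z) and `scores` (clusters x types z-score matrix).
#' @export
score_cell_types <- function(expr, labels, panel = default_marker_panel(),
                             z_threshold = 1.0) {
  stopifnot(inherits(expr, "ExprMatrix"))
  lab <- if (inherits(labels, "ClusterLabels")) labels$labels else as.integer(labels)
  stopifnot(length(lab) == ncol(expr$expr))
  if (nrow(panel$markers) == 0) stop("empty marker panel")

  present <- panel$markers$gene %in% expr$genes$symbol
  if (any(!present))
    warning("marker genes absent from matrix: ",
            paste(panel$markers$gene[!present], collapse = ", "))
  mk <- panel$markers[present, , drop = FALSE]
  types <- unique(panel$markers$type)

  clusters <- sort(unique(lab))
  # cluster x type mean marker expression
  mean_mat <- matrix(NA_real_, length(clusters), length(types),
                     dimnames = list(clusters, types))
  for (ty in types) {
    g <- mk$gene[mk$type == ty]
    if (length(g) == 0) next   # unassignable type
    rows <- match(g, expr$genes$symbol)
    sub <- expr$expr[rows, , drop = FALSE]
    cm <- vapply(clusters, function(cl)
      mean(Matrix::colMeans(sub[, lab == cl, drop = FALSE])), numeric(1))
    mean_mat[, ty] <- cm
  }
  z <- apply(mean_mat, 2, function(col) {
    if (all(is.na(col))) return(col)
    s <- stats::sd(col)
    if (is.na(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  z <- matrix(z, nrow = length(clusters),
              dimnames = list(clusters, types))
  call_type <- character(length(clusters))
  best_z <- numeric(length(clusters))
  for (r in seq_along(clusters)) {
    zr <- z[r, ]
    zr[is.na(zr)] <- -Inf
    j <- which.max(zr)
    best_z[r] <- zr[j]
    call_type[r] <- if (is.finite(zr[j]) && zr[j] >= z_threshold)
      types[j] else "unknown"
  }
  cluster_type <- data.frame(cluster = clusters, type = call_type,
                             best_z = best_z, stringsAsFactors = FALSE)
  cell_type <- call_type[match(lab, clusters)]
  structure(list(cell_type = cell_type, cluster = lab,
                 cluster_type = cluster_type, scores = z),
            class = "TypeAssignment")
}

#' @export
print.TypeAssignment <- function(x, ...) {
  tab <- sort(table(x$cell_type), decreasing = TRUE)
  cat("TypeAssignment:", length(x$cell_type), "cells\n")
  print(tab)
  invisible(x)
}

# vectorized one-vs-rest Wilcoxon rank-sum across genes for one grouping.
# Ranks each gene once over all cells; per-group U from the group rank sum,
# normal approximation with tie correction.
.ranksum_one_vs_rest <- function(mat, in_group) {
  n <- ncol(mat)
  n1 <- sum(in_group)
  n2 <- n - n1
  stats_out <- matrix(NA_real_, nrow(mat), 3,
                      dimnames = list(rownames(mat), c("auc", "U", "p")))
  for (g in seq_len(nrow(mat))) {
    v <- mat[g, ]
    r <- rank(v)
    U <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      zc <- (U - n1 * n2 / 2)
      zc <- sign(zc) * max(abs(zc) - 0.5, 0) / sqrt(sigma2)  # continuity corr.
      p <- 2 * stats::pnorm(-abs(zc))
    }
    stats_out[g, ] <- c(U / (n1 * n2), U, min(p, 1))
  }
  stats_out
}

#' Rank marker genes per cluster
#'
#' One-vs-rest Wilcoxon rank-sum test for every gene in every cluster
#' (normal approximation with tie and continuity correction), with
#' Benjamini-Hochberg adjustment across genes within each cluster. The
#' effect size is the rank-biserial correlation 2*AUC - 1 (0 for a constant
#' gene, positive when the gene is higher inside the cluster). Rows are
#' sorted by cluster, then decreasing effect.
#'
#' @param expr an `ExprMatrix`.
#' @param labels a `ClusterLabels` or integer vector (>= 2 clusters).
#' @param genes optional gene symbols to restrict the test to.
#' @param min_cluster_size clusters smaller than this are skipped with a
#'   warning (default 3).
#' @return a data.frame with columns `gene`, `cluster`, `effect`, `statistic`
#'   (rank-sum U), `p_adj`, `frac_in`, `frac_out`.
#' @export
rank_markers <- function(expr, labels, genes = NULL, min_cluster_size = 3) {
  stopifnot(inherits(expr, "ExprMatrix"))
  lab <- if (inherits(labels, "ClusterLabels")) labels$labels else as.integer(labels)
  clusters <- sort(unique(lab))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  m <- expr$expr
  symbols <- expr$genes$symbol
  if (!is.null(genes)) {
    rows <- match(genes, expr$genes$symbol)
    if (anyNA(rows)) stop("unknown gene symbols in 'genes'")
    m <- m[rows, , drop = FALSE]
    symbols <- symbols[rows]
  }
  dm <- as.matrix(m)
  rownames(dm) <- symbols
  out <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    in_g <- lab == cl
    if (sum(in_g) < min_cluster_size) {
      warning("cluster ", cl, " has fewer than ", min_cluster_size,
              " cells; skipped")
      next
    }
    st <- .ranksum_one_vs_rest(dm, in_g)
    frac_in <- rowMeans(dm[, in_g, drop = FALSE] > 0)
    frac_out <- rowMeans(dm[, !in_g, drop = FALSE] > 0)
    df <- data.frame(gene = rownames(dm), cluster = cl,
                     effect = 2 * st[, "auc"] - 1,
                     statistic = st[, "U"],
                     p_adj = stats::p.adjust(st[, "p"], method = "BH"),
                     frac_in = frac_in, frac_out = frac_out,
                     stringsAsFactors = FALSE, row.names = NULL)
    out[[ci]] <- df[order(-df$effect, df$gene), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Subset cells by type and recluster
#'
#' Subsets the cells whose call is in `target_types`, then recomputes
#' highly-variable genes, PCA and kNN label-propagation clustering on the
#' subset only.
#'
#' @param expr an `ExprMatrix`.
#' @param assignment a `TypeAssignment` aligned to `expr` cells.
#' @param target_types character vector of types to keep (non-empty).
#' @param n_top,d,k_neighbors parameters passed to [select_hvg()],
#'   [embed_pca()] and [cluster_cells()].
#' @return list with `expr` (subset `ExprMatrix`), `embedding`, `labels` and
#'   `cells` (barcodes of the subset).
#' @export
subset_recluster <- function(expr, assignment, target_types,
                             n_top = 2000, d = 20, k_neighbors = 15) {
  stopifnot(inherits(expr, "ExprMatrix"))
  if (length(target_types) == 0) stop("target_types must be non-empty")
  keep <- assignment$cell_type %in% target_types
  if (!any(keep)) stop("no cells of the requested types: ",
                       paste(target_types, collapse = ", "))
  sub <- structure(list(expr = expr$expr[, keep, drop = FALSE],
                        genes = expr$genes, scale = expr$scale),
                   class = "ExprMatrix")
  hvg <- select_hvg(sub, n_top)
  d_use <- min(d, sum(keep) - 1, length(hvg) - 1)
  emb <- embed_pca(sub, hvg, d = d_use)
  k_use <- min(k_neighbors, sum(keep) - 1)
  lab <- cluster_cells(emb, k_neighbors = k_use)
  list(expr = sub, embedding = emb, labels = lab,
       cells = colnames(sub$expr))
}
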