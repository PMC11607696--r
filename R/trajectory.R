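#' Square-root rule for the number of nearest neighbours
#'
#' The kNN used for the germ-cell graph follows the square-root-of-cells
#' rule: k = round(sqrt(n)), floored at 2 and capped at n - 1. For a 40,000
#' cell object this gives k = 200; for 7,744 cells, k = 88.
#'
#' @param n_cells number of cells (>= 4).
#' @return integer k.
#' @export
knn_for_n <- function(n_cells) {
  if (n_cells < 4) stop("need at least 4 cells, got ", n_cells)
  k <- round(sqrt(n_cells))
  as.integer(min(max(k, 2), n_cells - 1))
}

#' Build the symmetrized kNN graph over germ cells
#'
#' Exact Euclidean k nearest neighbours on the embedding, symmetrized by
#' edge union, no self-edges. Connected components are labelled so that
#' floods can be restricted to the root component.
#'
#' @param embedding an `Embedding` (or cells x d matrix) of germ cells.
#' @param k neighbours per cell (default [knn_for_n()] of the cell count).
#' @return a `GermGraph`: list with `adj` (sparse symmetric 0/1 adjacency),
#'   `k`, `cells` (barcodes or indices) and `component` (integer per cell,
#'   1-based, 1 = largest).
#' @export
build_germ_graph <- function(embedding, k = NULL) {
  coords <- if (inherits(embedding, "Embedding")) embedding$coords else as.matrix(embedding)
  n <- nrow(coords)
  if (is.null(k)) k <- knn_for_n(n)
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (", n, ")")
  adj <- .knn_adjacency(coords, k)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  # relabel components by decreasing size, ties by smallest member index
  ord <- order(-comp$csize, vapply(seq_len(comp$no), function(c)
    which(comp$membership == c)[1L], integer(1)))
  remap <- integer(comp$no)
  remap[ord] <- seq_len(comp$no)
  cells <- rownames(coords)
  if (is.null(cells)) cells <- as.character(seq_len(n))
  structure(list(adj = adj, k = as.integer(k), cells = cells,
                 component = remap[comp$membership]),
            class = "GermGraph")
}

#' Build a GermGraph from an explicit adjacency matrix
#'
#' Mainly useful for floods over hand-specified graphs (path graphs, random
#' graphs); [build_germ_graph()] is the embedding-based constructor.
#'
#' @param adj square symmetric 0/1 adjacency (sparse or dense), no
#'   self-edges.
#' @param cells optional cell names.
#' @return a `GermGraph`.
#' @export
germ_graph_from_adjacency <- function(adj, cells = NULL) {
  adj <- methods::as(methods::as(Matrix::Matrix(adj, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
  n <- nrow(adj)
  stopifnot(ncol(adj) == n, Matrix::isSymmetric(adj))
  if (any(Matrix::diag(adj) != 0)) stop("no self-edges allowed")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  ord <- order(-comp$csize, vapply(seq_len(comp$no), function(c)
    which(comp$membership == c)[1L], integer(1)))
  remap <- integer(comp$no)
  remap[ord] <- seq_len(comp$no)
  if (is.null(cells)) cells <- as.character(seq_len(n))
  structure(list(adj = adj, k = NA_integer_, cells = cells,
                 component = remap[comp$membership]),
            class = "GermGraph")
}

#' @export
print.GermGraph <- function(x, ...) {
  cat(sprintf("GermGraph: %d cells, k=%d, %d edges, %d component(s)\n",
              length(x$cells), x$k, length(x$adj@x) / 2,
              max(x$component)))
  invisible(x)
}

#' Flood-simulation parameters
#'
#' @param n_simulations number of subsampled flood simulations to average
#'   (default 50).
#' @param cells_per_step_fraction probability that each non-root cell is
#'   retained in a given simulation (default 0.8).
#' @param min_visited_neighbors visited-neighbour quorum for a cell to become
#'   visited (default 2); a cell with fewer retained neighbours than the
#'   quorum needs only 1.
#' @param seed RNG seed for the subsampling.
#' @return a `flood_params` list.
#' @export
flood_params <- function(n_simulations = 50, cells_per_step_fraction = 0.8,
                         min_visited_neighbors = 2, seed = 1) {
  stopifnot(n_simulations >= 1,
            cells_per_step_fraction > 0, cells_per_step_fraction <= 1,
            min_visited_neighbors >= 1)
  structure(list(n_simulations = as.integer(n_simulations),
                 cells_per_step_fraction = cells_per_step_fraction,
                 min_visited_neighbors = as.integer(min_visited_neighbors),
                 seed = as.integer(seed)),
            class = "flood_params")
}

#' Select root clusters by marker expression
#'
#' Clusters are ranked by mean log-normalized expression of the marker; the
#' cells of the top `n_clusters` clusters are returned. Ties at the cutoff
#' rank are broken deterministically by cluster id (smaller id first) and a
#' message reports the tie. Defaults mirror the study design: the forward
#' flood roots in the two clusters highest in ddx4 (spermatogonia), the
#' reverse flood in the single cluster highest in tssk6 (spermatozoa).
#'
#' @param expr an `ExprMatrix` over the graph's cells.
#' @param labels a `ClusterLabels` or integer vector per cell.
#' @param marker marker gene symbol (must be present; the error lists
#'   the standard fallbacks tssk6 -> ccnb3 -> sycp3 for objects lacking
#'   spermatozoa).
#' @param n_clusters number of top clusters to take as roots.
#' @return list with `root_cells` (integer indices into the cells),
#'   `root_clusters`, and `cluster_means` (named numeric).
#' @export
select_root_clusters <- function(expr, labels, marker, n_clusters = 2) {
  stopifnot(inherits(expr, "ExprMatrix"))
  lab <- if (inherits(labels, "ClusterLabels")) labels$labels else as.integer(labels)
  row <- match(marker, expr$genes$symbol)
  if (is.na(row))
    stop("marker '", marker, "' absent from the matrix; consider the ",
         "fallback order tssk6 -> ccnb3 -> sycp3 for late-stage roots")
  clusters <- sort(unique(lab))
  if (n_clusters > length(clusters))
    stop("n_clusters (", n_clusters, ") exceeds number of clusters (",
         length(clusters), ")")
  v <- expr$expr[row, ]
  means <- vapply(clusters, function(cl) mean(v[lab == cl]), numeric(1))
  names(means) <- clusters
  ord <- order(-means, clusters)   # tie-break: smaller cluster id
  cutoff <- means[ord][n_clusters]
  if (sum(means == cutoff) > 1)
    message("tie at rank ", n_clusters, " on marker ", marker,
            "; broken by cluster id")
  roots <- clusters[ord[seq_len(n_clusters)]]
  list(root_cells = which(lab %in% roots), root_clusters = roots,
       cluster_means = means)
}

#' Graph-flood pseudotime
#'
#' Runs `n_simulations` stochastic floods from the root cells. In each
#' simulation every non-root cell is retained independently with probability
#' `cells_per_step_fraction`; roots are visited at step 0 and, at each step,
#' an unvisited retained cell becomes visited when at least
#' `min_visited_neighbors` of its neighbours are visited (1 suffices for
#' cells with fewer retained neighbours than the quorum). A cell's
#' pseudotime is the mean over simulations of visit step / max step of that
#' simulation, and the final vector is min-max rescaled to [0, 1]. Cells
#' never visited in any simulation are flagged and assigned pseudotime 1;
#' when more than 5% of cells are flagged they are excluded from the
#' rescaling (with a warning). Deterministic given the seed in `params`.
#'
#' @param graph a `GermGraph`.
#' @param roots integer indices (or cell names) of root cells.
#' @param params a [flood_params()] object.
#' @return list with `pt` (numeric per cell in [0,1]), `never_visited`
#'   (logical flag per cell) and `n_unreached`.
#' @export
flood_pseudotime <- function(graph, roots, params = flood_params()) {
  stopifnot(inherits(graph, "GermGraph"))
  n <- length(graph$cells)
  if (is.character(roots)) roots <- match(roots, graph$cells)
  roots <- unique(as.integer(roots))
  if (length(roots) == 0 || anyNA(roots) || any(roots < 1 | roots > n))
    stop("roots must be a non-empty set of cells inside the graph")
  root_comp <- graph$component[roots]
  main <- graph$component == graph$component[roots[1L]]
  if (!any(main & seq_len(n) %in% roots))
    warning("roots span no cells of their component")  # unreachable in practice

  adj <- graph$adj
  is_root <- rep(FALSE, n); is_root[roots] <- TRUE
  m <- params$min_visited_neighbors

  pt_sum <- numeric(n)
  pt_cnt <- integer(n)
  set.seed(params$seed)
  for (s in seq_len(params$n_simulations)) {
    retained <- is_root
    nr <- !is_root
    if (params$cells_per_step_fraction >= 1) {
      retained[nr] <- TRUE
    } else {
      retained[nr] <- stats::runif(sum(nr)) < params$cells_per_step_fraction
    }
    ret_num <- as.numeric(retained)
    rn <- as.vector(adj %*% ret_num)          # retained neighbours per cell
    quorum <- ifelse(rn < m, 1, m)
    visited <- is_root
    step_of <- rep(NA_integer_, n)
    step_of[roots] <- 0L
    step <- 0L
    repeat {
      cnt <- as.vector(adj %*% as.numeric(visited))
      newly <- retained & !visited & (cnt >= quorum)
      if (!any(newly)) break
      step <- step + 1L
      step_of[newly] <- step
      visited <- visited | newly
    }
    if (step > 0L) {
      got <- !is.na(step_of)
      pt_sum[got] <- pt_sum[got] + step_of[got] / step
      pt_cnt[got] <- pt_cnt[got] + 1L
    } else {
      # degenerate: nothing flooded beyond the roots this simulation
      pt_cnt[roots] <- pt_cnt[roots] + 1L
    }
  }

  never <- pt_cnt == 0L
  pt <- ifelse(never, 1, ifelse(pt_cnt > 0, pt_sum / pt_cnt, 1))
  frac_never <- mean(never)
  scale_set <- if (frac_never > 0.05) {
    warning(sprintf("%.1f%% of cells never flooded; excluded from rescaling",
                    100 * frac_never))
    !never
  } else rep(TRUE, n)
  rng <- range(pt[scale_set])
  if (diff(rng) > 0) {
    pt <- (pt - rng[1]) / (rng[2] - rng[1])
    pt <- pmin(pmax(pt, 0), 1)
  } else {
    pt <- rep(0, n)
  }
  pt[never] <- 1
  if (all(is_root)) pt <- rep(0, n)
  list(pt = pt, never_visited = never, n_unreached = sum(never))
}

#' Spermatogenesis differentiation score
#'
#' Averages the forward pseudotime with the inverse of the reverse
#' pseudotime, D = (pt_fwd + (1 - pt_rev)) / 2, then min-max rescales over
#' the object so 0 is the most spermatogonial state and 1 the most
#' differentiated spermatozoa state.
#'
#' @param pt_fwd forward pseudotime per cell (roots: spermatogonia).
#' @param pt_rev reverse pseudotime per cell (roots: spermatozoa), over the
#'   same cells in the same order.
#' @return numeric D in [0,1] per cell.
#' @export
differentiation_score <- function(pt_fwd, pt_rev) {
  if (length(pt_fwd) != length(pt_rev))
    stop("forward and reverse pseudotime cover different cell sets")
  if (!is.null(names(pt_fwd)) && !is.null(names(pt_rev)) &&
      !identical(names(pt_fwd), names(pt_rev)))
    stop("forward and reverse pseudotime cover different cell sets")
  d <- (pt_fwd + (1 - pt_rev)) / 2
  rng <- range(d)
  if (diff(rng) > 0) (d - rng[1]) / diff(rng) else rep(0, length(d))
}

#' Bidirectional flood pseudotime over a germ-cell object
#'
#' Convenience wrapper running the full scoring recipe on a germ-cell
#' expression matrix: HVG -> PCA -> clustering -> kNN graph (k =
#' round(sqrt(n)) by default) -> forward flood from the `n_fwd` clusters
#' highest in the forward marker (ddx4) -> reverse flood from the `n_rev`
#' clusters highest in the reverse marker (tssk6, falling back to ccnb3 then
#' sycp3 when absent or never expressed, as in objects lacking spermatozoa)
#' -> differentiation score.
#'
#' @param expr an `ExprMatrix` of germ cells only.
#' @param params a [flood_params()].
#' @param k graph neighbours; default [knn_for_n()] of the cell count.
#' @param n_top,d HVG/PCA parameters.
#' @param cluster_k neighbours for the root-selection clustering
#'   (default 15).
#' @param fwd_marker,rev_markers forward root marker and ordered reverse
#'   fallback markers.
#' @param n_fwd,n_rev number of root clusters per direction.
#' @return a `PseudotimeTable` data.frame: `cell`, `pt_fwd`, `pt_rev`,
#'   `score`, `component`, `never_fwd`, `never_rev`; plus attributes
#'   `k`, `root_fwd`, `root_rev`, `rev_marker`.
#' @export
germ_pseudotime <- function(expr, params = flood_params(), k = NULL,
                            n_top = 2000, d = 20, cluster_k = 15,
                            fwd_marker = "ddx4",
                            rev_markers = c("tssk6", "ccnb3", "sycp3"),
                            n_fwd = 2, n_rev = 1) {
  stopifnot(inherits(expr, "ExprMatrix"))
  n <- ncol(expr$expr)
  hvg <- select_hvg(expr, n_top)
  emb <- embed_pca(expr, hvg, d = min(d, length(hvg) - 1, n - 1))
  # the germ continuum is one connected component; Leiden partitions it into
  # segments so that marker-ranked root clusters exist at both extremes
  labels <- cluster_cells(emb, k_neighbors = min(cluster_k, n - 1),
                          method = "leiden")
  graph <- build_germ_graph(emb, k = if (is.null(k)) knn_for_n(n) else k)

  fwd_roots <- select_root_clusters(expr, labels, fwd_marker,
                                    min(n_fwd, labels$n_clusters))
  rev_marker <- NULL
  for (mk in rev_markers) {
    row <- match(mk, expr$genes$symbol)
    if (!is.na(row) && Matrix::rowSums(expr$expr[row, , drop = FALSE] > 0) > 0) {
      rev_marker <- mk
      break
    }
  }
  if (is.null(rev_marker))
    stop("no reverse root marker (", paste(rev_markers, collapse = ", "),
         ") expressed in the object")
  rev_roots <- select_root_clusters(expr, labels, rev_marker,
                                    min(n_rev, labels$n_clusters))

  fwd <- flood_pseudotime(graph, fwd_roots$root_cells, params)
  rev_params <- params
  rev_params$seed <- params$seed + 1L
  rev <- flood_pseudotime(graph, rev_roots$root_cells, rev_params)
  score <- differentiation_score(fwd$pt, rev$pt)

  out <- data.frame(cell = graph$cells, pt_fwd = fwd$pt, pt_rev = rev$pt,
                    score = score, component = graph$component,
                    never_fwd = fwd$never_visited,
                    never_rev = rev$never_visited,
                    stringsAsFactors = FALSE)
  attr(out, "k") <- graph$k
  attr(out, "root_fwd") <- fwd_roots$root_clusters
  attr(out, "root_rev") <- rev_roots$root_clusters
  attr(out, "rev_marker") <- rev_marker
  attr(out, "labels") <- labels
  attr(out, "embedding") <- emb
  out
}

#' Align differentiation scores of a truncated object to a reference
#'
#' Cells of the incomplete object's most differentiated type (default
#' spermatocytes) are co-embedded with the reference germ cells by joint
#' standardization of the shared genes followed by projection on shared
#' principal axes; each matched cell adopts the mean reference
#' differentiation score of its `n_neighbors` nearest reference cells
#' (averaging over a small neighbourhood, as is standard in
#' nearest-neighbour label transfer, smooths the per-cell noise of the
#' flood scores). The scaling constant M is the maximum adopted score, and
#' every incomplete score is rescaled multiplicatively:
#' D_scaled = D_raw * M.
#'
#' @param incomplete list with `expr` (`ExprMatrix`), `pt` (a
#'   `PseudotimeTable` over the same cells) and `types` (per-cell type call).
#' @param reference list with `expr` and `pt` over the reference germ cells.
#' @param match_type cell type matched across objects (default
#'   `"spermatocytes"`).
#' @param d number of shared principal axes (default 20).
#' @param n_neighbors reference neighbours averaged per matched cell
#'   (default 15, capped at the reference size).
#' @return an `AlignmentResult`: list with `M`, `matched` (data.frame of
#'   matched cells, their nearest reference cell and adopted score) and
#'   `scaled` (data.frame `cell`, `score`, `scaled_score` for every
#'   incomplete cell).
#' @export
align_scores <- function(incomplete, reference, match_type = "spermatocytes",
                         d = 20, n_neighbors = 15) {
  stopifnot(inherits(incomplete$expr, "ExprMatrix"),
            inherits(reference$expr, "ExprMatrix"))
  sel <- incomplete$types == match_type
  if (!any(sel))
    stop("no cells of match type '", match_type, "' in the incomplete object")
  shared <- intersect(incomplete$expr$genes$symbol,
                      reference$expr$genes$symbol)
  if (length(shared) == 0) stop("no shared genes between objects")

  ref_m <- as.matrix(reference$expr$expr[
    match(shared, reference$expr$genes$symbol), , drop = FALSE])
  inc_m <- as.matrix(incomplete$expr$expr[
    match(shared, incomplete$expr$genes$symbol), sel, drop = FALSE])
  joint <- t(cbind(ref_m, inc_m))           # cells x shared genes
  mu <- colMeans(joint)
  sdev <- apply(joint, 2, stats::sd)
  sdev[sdev == 0] <- 1
  joint <- sweep(sweep(joint, 2, mu), 2, sdev, "/")
  d_use <- min(d, ncol(joint) - 1, nrow(joint) - 1)
  sv <- svd(joint, nu = 0, nv = d_use)
  coords <- joint %*% sv$v
  n_ref <- ncol(ref_m)
  ref_c <- coords[seq_len(n_ref), , drop = FALSE]
  inc_c <- coords[-seq_len(n_ref), , drop = FALSE]

  ref_score <- reference$pt$score
  sq_ref <- rowSums(ref_c^2)
  kk <- min(n_neighbors, nrow(ref_c))
  nn <- integer(nrow(inc_c))
  adopted <- numeric(nrow(inc_c))
  for (i in seq_len(nrow(inc_c))) {
    d2 <- sq_ref - 2 * as.vector(ref_c %*% inc_c[i, ])
    ord <- order(d2, seq_along(d2), method = "radix")[seq_len(kk)]
    nn[i] <- ord[1L]
    adopted[i] <- mean(ref_score[ord])
  }
  M <- max(adopted)

  scaled <- data.frame(cell = incomplete$pt$cell,
                       score = incomplete$pt$score,
                       scaled_score = incomplete$pt$score * M,
                       stringsAsFactors = FALSE)
  structure(list(
    M = M,
    matched = data.frame(cell = incomplete$pt$cell[sel],
                         ref_cell = reference$pt$cell[nn],
                         adopted_score = adopted,
                         stringsAsFactors = FALSE),
    scaled = scaled
  ), class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf("AlignmentResult: %d matched cells, M = %.3f\n",
              nrow(x$matched), x$M))
  invisible(x)
}
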