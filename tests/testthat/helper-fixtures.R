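# fixture builders shared across test files; heavier synthetic objects are
# memoized so several files can reuse one generation/scoring run

toy_counts <- function(mat, symbols = NULL, barcodes = NULL) {
  if (is.null(symbols)) symbols <- sprintf("g%02d", seq_len(nrow(mat)))
  if (is.null(barcodes)) barcodes <- sprintf("bc%03d", seq_len(ncol(mat)))
  count_matrix(mat, symbols, symbols, barcodes)
}

random_counts <- function(n_genes, n_cells, seed, n_mito = 2,
                          lambda = 3) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  symbols <- c(sprintf("mt-x%d", seq_len(n_mito)),
               sprintf("g%03d", seq_len(n_genes - n_mito)))
  count_matrix(m, symbols, symbols, sprintf("bc%04d", seq_len(n_cells)))
}

blob_embedding <- function(n_per = 100, centers = list(c(0, 0), c(10, 10)),
                           d = 5, seed = 7) {
  set.seed(seed)
  do.call(rbind, lapply(centers, function(ctr) {
    mu <- rep(0, d)
    mu[seq_along(ctr)] <- ctr
    matrix(rnorm(n_per * d), n_per, d) + rep(mu, each = n_per)
  }))
}

# ---- memoized heavy fixtures -------------------------------------------------

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, .fixture_env)) assign(key, builder(), .fixture_env)
  get(key, .fixture_env)
}

germ_expr_of <- function(ds, s) {
  m <- ds$matrices[[s]]
  fr <- filter_cells(m, compute_cell_qc(m),
                     filter_params(upper_rule = "tukey_fence"))
  e <- normalize_log(fr$matrix)
  tr <- ds$truth[ds$truth$sample == s, ]
  keep <- tr$compartment[match(colnames(e$expr), tr$barcode)] == "germ"
  structure(list(expr = e$expr[, keep, drop = FALSE], genes = e$genes,
                 scale = e$scale), class = "ExprMatrix")
}

# pure germ continuum (n = 2000, seed 1), scored bidirectionally
fixture_continuum <- function() memo("continuum", function() {
  spec <- synthetic_spec(germ_continuum_design(n_cells = 2000), seed = 1)
  ds <- generate_dataset(spec)
  expr <- germ_expr_of(ds, "germ1")
  pt <- germ_pseudotime(expr, flood_params(seed = 1))
  tr <- ds$truth
  latent <- tr$latent_time[match(pt$cell, tr$barcode)]
  list(ds = ds, expr = expr, pt = pt, latent = latent)
})

# complete (t_max = 1) + incomplete (t_max = 0.5) germ pair, scored + aligned
fixture_truncation_pair <- function() memo("trunc_pair", function() {
  des <- testis_design(n_cells = 2000)
  des$samples <- des$samples[c(2, 6), ]
  des$weights <- des$weights[c(2, 6), ]
  spec <- synthetic_spec(des, seed = 1)
  ds <- generate_dataset(spec)
  ref_expr <- germ_expr_of(ds, "s12")
  inc_expr <- germ_expr_of(ds, "s27i")
  pt_ref <- germ_pseudotime(ref_expr, flood_params(seed = 1))
  pt_inc <- germ_pseudotime(inc_expr, flood_params(seed = 1))
  types_inc <- score_cell_types(inc_expr, attr(pt_inc, "labels"))$cell_type
  stages <- intersect(c("spermatogonia", "spermatocytes", "spermatids",
                        "spermatozoa"), types_inc)
  al <- align_scores(list(expr = inc_expr, pt = pt_inc, types = types_inc),
                     list(expr = ref_expr, pt = pt_ref),
                     match_type = stages[length(stages)])
  tr12 <- ds$truth[ds$truth$sample == "s12", ]
  tri <- ds$truth[ds$truth$sample == "s27i", ]
  list(ds = ds, pt_ref = pt_ref, pt_inc = pt_inc, alignment = al,
       latent_ref = tr12$latent_time[match(pt_ref$cell, tr12$barcode)],
       latent_inc = tri$latent_time[match(al$scaled$cell, tri$barcode)])
})

# one incomplete sample with 40% immune cells, typed through the pipeline
fixture_incomplete_typed <- function() memo("inc_typed", function() {
  des <- testis_design(n_cells = 5000)
  des$samples <- des$samples[6, , drop = FALSE]
  des$weights <- des$weights[6, , drop = FALSE]
  ds <- generate_dataset(synthetic_spec(des, seed = 1))
  m <- ds$matrices[[1]]
  fr <- filter_cells(m, compute_cell_qc(m),
                     filter_params(upper_rule = "tukey_fence"))
  expr <- normalize_log(fr$matrix)
  emb <- embed_pca(expr, select_hvg(expr, 2000), d = 20)
  asg <- score_cell_types(expr, cluster_cells(emb, 15))
  truth_cat <- ds$truth$compartment[match(fr$matrix$barcodes,
                                          ds$truth$barcode)]
  list(ds = ds, assignment = asg, truth_cat = truth_cat)
})

# brute-force BFS hop distances, independent of the flood implementation
bfs_hops <- function(adj, roots) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  dist[roots] <- 0
  frontier <- roots
  h <- 0
  while (length(frontier) > 0) {
    h <- h + 1
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(adj[v, ] != 0)
      nb <- nb[dist[nb] == Inf]
      dist[nb] <- h
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  dist
}

# random connected graph: spanning tree over shuffled nodes + extra edges
random_connected_adj <- function(n, extra = n, seed) {
  set.seed(seed)
  ord <- sample(n)
  i <- ord[-1]
  j <- ord[vapply(2:n, function(k) sample(k - 1, 1), integer(1))]
  ei <- c(i, sample(n, extra, replace = TRUE))
  ej <- c(j, sample(n, extra, replace = TRUE))
  keep <- ei != ej
  a <- Matrix::sparseMatrix(i = c(ei[keep], ej[keep]),
                            j = c(ej[keep], ei[keep]), x = 1,
                            dims = c(n, n), use.last.ij = FALSE)
  a@x[] <- 1
  a
}
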