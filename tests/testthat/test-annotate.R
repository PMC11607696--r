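test_that("log-normalization rescales per cell and is depth-invariant", {
  x <- toy_counts(matrix(c(10, 90), 2, 1), symbols = c("g1", "g2"))
  e <- normalize_log(x, scale = 100)
  expect_equal(as.numeric(e$expr), c(log1p(10), log1p(90)))

  z <- toy_counts(matrix(c(0, 0, 1, 2), 2, 2))
  ez <- normalize_log(z)
  expect_equal(as.numeric(ez$expr[, 1]), c(0, 0))

  # doubling a cell's counts leaves its normalized vector unchanged
  a <- toy_counts(matrix(c(3, 7, 6, 14), 2, 2))
  ea <- normalize_log(a)
  expect_equal(as.numeric(ea$expr[, 1]), as.numeric(ea$expr[, 2]))
})

test_that("highly variable gene selection is variance-ranked with id tie-break", {
  m <- rbind(const = rep(5, 6), vary = c(0, 10, 0, 10, 0, 10),
             tie_b = c(1, 2, 1, 2, 1, 2), tie_a = c(2, 1, 2, 1, 2, 1))
  e <- structure(list(expr = Matrix::Matrix(m, sparse = TRUE),
                      genes = data.frame(id = rownames(m),
                                         symbol = rownames(m), mito = FALSE),
                      scale = 1), class = "ExprMatrix")
  expect_false("const" %in% select_hvg(e, 3))
  expect_equal(select_hvg(e, 4), c("vary", "tie_a", "tie_b", "const"))
  expect_length(select_hvg(e, 999), 4)
})

test_that("PCA embedding has the expected spectral behaviour", {
  # rank-1 data: first component explains ~all variance
  set.seed(3)
  t <- runif(80)
  line <- outer(seq(1, 3, length.out = 12), t) + 1
  e <- structure(list(expr = Matrix::Matrix(line, sparse = TRUE),
                      genes = data.frame(id = sprintf("g%02d", 1:12),
                                         symbol = sprintf("g%02d", 1:12),
                                         mito = FALSE),
                      scale = 1), class = "ExprMatrix")
  emb <- embed_pca(e, d = 3, scale_genes = FALSE)
  expect_gte(emb$var_explained[1] / sum(emb$var_explained), 0.99)

  # rotational invariance of the explained-variance spectrum
  set.seed(4)
  mat <- matrix(rpois(30 * 50, 4), 30, 50)
  q <- qr.Q(qr(matrix(rnorm(900), 30, 30)))
  e1 <- structure(list(expr = Matrix::Matrix(mat, sparse = TRUE),
                       genes = data.frame(id = as.character(1:30),
                                          symbol = as.character(1:30),
                                          mito = FALSE),
                       scale = 1), class = "ExprMatrix")
  e2 <- e1
  e2$expr <- Matrix::Matrix(q %*% mat, sparse = TRUE)
  s1 <- embed_pca(e1, d = 5, scale_genes = FALSE)$var_explained
  s2 <- embed_pca(e2, d = 5, scale_genes = FALSE)$var_explained
  expect_equal(s1, s2, tolerance = 1e-8)

  # duplicate cells embed identically
  dup <- toy_counts(cbind(matrix(rpois(20 * 10, 3), 20, 10)[, c(1:10, 1)]))
  ed <- normalize_log(dup)
  co <- embed_pca(ed, d = 3)$coords
  expect_equal(co[1, ], co[11, ], ignore_attr = TRUE)

  expect_error(embed_pca(ed, d = 50), "smaller")
})

test_that("label propagation resolves blobs and is permutation-invariant", {
  blobs <- blob_embedding(100, list(c(0, 0), c(10, 10)))
  cl <- cluster_cells(blobs, 15)
  expect_equal(cl$n_clusters, 2)
  expect_length(unique(cl$labels[1:100]), 1)
  expect_length(unique(cl$labels[101:200]), 1)

  single <- blob_embedding(100, list(c(0, 0)))
  expect_equal(cluster_cells(single, 15)$n_clusters, 1)

  set.seed(9)
  p <- sample(200)
  clp <- cluster_cells(blobs[p, ], 15)
  tab <- table(cl$labels[p], clp$labels)
  expect_true(all(tab %in% c(0, 100)))   # identical up to relabelling

  expect_error(cluster_cells(blobs[1:10, ], 15), "fewer cells")
})

test_that("leiden clustering is deterministic and splits a continuum", {
  cont <- fixture_continuum()
  emb <- attr(cont$pt, "embedding")
  l1 <- cluster_cells(emb, 15, method = "leiden")
  l2 <- cluster_cells(emb, 15, method = "leiden")
  expect_identical(l1$labels, l2$labels)
  expect_gte(l1$n_clusters, 3)
})

test_that("clusters are typed by their dominant marker", {
  # three clusters expressing exactly one panel marker each
  genes <- c("ddx4", "mpeg1.1", "gsdf", "hk1")
  m <- cbind(matrix(rep(c(50, 0, 0, 5), 20), 4),
             matrix(rep(c(0, 50, 0, 5), 20), 4),
             matrix(rep(c(0, 0, 50, 5), 20), 4))
  x <- count_matrix(m, genes, genes, sprintf("b%02d", 1:60))
  e <- normalize_log(x)
  labels <- rep(0:2, each = 20)
  asg <- suppressWarnings(score_cell_types(e, labels))
  expect_equal(asg$cluster_type$type[asg$cluster_type$cluster == 0],
               "spermatogonia")
  expect_equal(asg$cluster_type$type[asg$cluster_type$cluster == 1],
               "macrophage")
  expect_equal(asg$cluster_type$type[asg$cluster_type$cluster == 2],
               "sertoli")

  # identical clusters: degenerate z-scores give all-unknown
  same <- count_matrix(matrix(5, 4, 40), genes, genes, sprintf("c%02d", 1:40))
  es <- normalize_log(same)
  asg2 <- suppressWarnings(score_cell_types(es, rep(0:1, each = 20)))
  expect_true(all(asg2$cell_type == "unknown"))
})

test_that("marker panel lookups follow the canonical map", {
  panel <- default_marker_panel()
  expect_equal(panel_lookup(panel, "ddx4"), "spermatogonia")
  expect_equal(panel_lookup(panel, "tssk6"), "spermatozoa")
  expect_equal(panel_lookup(panel, "mpeg1.1"), "macrophage")
  expect_true(is.na(panel_lookup(panel, "not-a-gene")))
  expect_error(default_marker_panel(extra = c(ddx4 = "other")), "exactly one")
})

test_that("marker ranking finds exclusive genes and is calibrated under the null", {
  set.seed(12)
  n_per <- 30
  m <- matrix(rpois(20 * 2 * n_per, 3), 20)
  m[1, seq_len(n_per)] <- m[1, seq_len(n_per)] + 15   # gene 1 marks cluster 0
  x <- toy_counts(m)
  e <- normalize_log(x)
  lab <- rep(0:1, each = n_per)
  tab <- rank_markers(e, lab)
  top0 <- tab[tab$cluster == 0, ][1, ]
  expect_equal(top0$gene, "g01")
  expect_gt(top0$effect, 0)
  expect_lt(top0$p_adj, 0.01)

  # a gene constant across cells carries no signal: effect 0, p = 1
  ec <- structure(list(expr = Matrix::Matrix(rbind(4, c(rep(1, n_per),
                                                        rep(2, n_per))),
                                             sparse = TRUE),
                       genes = data.frame(id = c("flat", "real"),
                                          symbol = c("flat", "real"),
                                          mito = FALSE),
                       scale = 1), class = "ExprMatrix")
  tc <- rank_markers(ec, lab)
  cst <- tc[tc$gene == "flat" & tc$cluster == 0, ]
  expect_equal(cst$effect, 0)
  expect_equal(cst$p_adj, 1)

  # agreement with stats::wilcox.test as an independent oracle
  w <- suppressWarnings(wilcox.test(as.numeric(e$expr[1, lab == 0]),
                                    as.numeric(e$expr[1, lab == 1]),
                                    correct = TRUE))
  expect_equal(unname(top0$statistic), unname(w$statistic))

  # permuted labels: no significant marker in >= 95% of fixtures
  set.seed(77)
  null_ok <- 0
  for (i in 1:100) {
    perm <- sample(lab)
    tabp <- rank_markers(e, perm)
    if (min(tabp$p_adj) >= 0.05) null_ok <- null_ok + 1
  }
  expect_gte(null_ok, 95)

  expect_error(rank_markers(e, rep(0, 2 * n_per)), "at least 2")
  expect_warning(rank_markers(e, c(rep(0, 2 * n_per - 2), 1, 1)), "fewer")
})

test_that("subsetting and reclustering recovers a pure compartment", {
  inc <- fixture_incomplete_typed()
  sub <- subset_recluster(normalize_log(with(inc, {
    m <- ds$matrices[[1]]
    filter_cells(m, compute_cell_qc(m),
                 filter_params(upper_rule = "tukey_fence"))$matrix
  })), inc$assignment, "macrophage")
  truth <- inc$ds$truth
  comp <- truth$compartment[match(sub$cells, truth$barcode)]
  expect_gte(mean(comp == "macrophage"), 0.9)

  expect_error(subset_recluster(fixture_continuum()$expr, inc$assignment,
                                character(0)), "non-empty")
})
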