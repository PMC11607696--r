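test_that("square-root kNN rule reproduces the study's k choices", {
  expect_equal(knn_for_n(16), 4L)
  expect_equal(knn_for_n(7744), 88L)    # the incomplete-object k
  expect_equal(knn_for_n(40000), 200L)  # the atlas-scale k
  expect_equal(knn_for_n(1e6), 1000L)
  expect_equal(knn_for_n(5), 2L)        # floored
  expect_equal(knn_for_n(4), 2L)
  expect_error(knn_for_n(3), "at least 4")
})

test_that("germ graph symmetrizes neighbours and labels components", {
  # 3 collinear points, k = 1: middle connects to both ends after union
  pts <- cbind(c(0, 1, 2), 0)
  g <- build_germ_graph(pts, k = 1)
  expect_equal(as.numeric(g$adj[2, ]), c(1, 0, 1))
  expect_equal(max(g$component), 1)

  # duplicate points are mutual neighbours
  gd <- build_germ_graph(cbind(c(0, 0, 5), 0), k = 1)
  expect_equal(gd$adj[1, 2], 1)

  # two far blobs with small k: component count matches brute-force traversal
  blobs <- blob_embedding(50, list(c(0, 0), c(100, 100)), seed = 5)
  gb <- build_germ_graph(blobs, k = 5)
  hops <- bfs_hops(as.matrix(gb$adj), 1)
  expect_equal(max(gb$component), 2)
  expect_setequal(which(is.finite(hops)), which(gb$component == gb$component[1]))

  expect_error(build_germ_graph(pts, k = 3), "smaller")
})

test_that("root clusters are ranked by marker mean with id tie-break", {
  genes <- c("ddx4", "other")
  expr_mat <- rbind(ddx4 = c(rep(5, 10), rep(4, 10), rep(0, 10)),
                    other = 1)
  x <- count_matrix(round(expm1(expr_mat)), genes, genes,
                    sprintf("b%02d", 1:30))
  e <- normalize_log(x, scale = 1)
  e$expr <- Matrix::Matrix(expr_mat, sparse = TRUE)  # exact means
  lab <- rep(0:2, each = 10)
  sel <- select_root_clusters(e, lab, "ddx4", 2)
  expect_setequal(sel$root_clusters, c(0, 1))
  expect_setequal(sel$root_cells, 1:20)

  expect_length(select_root_clusters(e, lab, "ddx4", 3)$root_cells, 30)
  expect_error(select_root_clusters(e, lab, "nope", 1), "fallback")
  expect_error(select_root_clusters(e, lab, "ddx4", 4), "exceeds")

  # tie at the cutoff rank: smaller cluster id wins, reported
  expr_tie <- rbind(ddx4 = c(rep(5, 10), rep(5, 10), rep(0, 10)), other = 1)
  et <- e; et$expr <- Matrix::Matrix(expr_tie, sparse = TRUE)
  expect_message(st <- select_root_clusters(et, lab, "ddx4", 1), "tie")
  expect_equal(st$root_clusters, 0)
})

test_that("deterministic flood equals normalized BFS hop distance", {
  # path graph 0-1-2-3-4 from one end
  path_adj <- Matrix::bandSparse(5, k = c(-1, 1),
                                 diagonals = list(rep(1, 4), rep(1, 4)))
  g <- germ_graph_from_adjacency(path_adj)
  det_params <- flood_params(n_simulations = 1, cells_per_step_fraction = 1,
                             min_visited_neighbors = 1, seed = 1)
  res <- flood_pseudotime(g, 1, det_params)
  expect_equal(res$pt, c(0, 0.25, 0.5, 0.75, 1))

  # random connected graphs up to 500 nodes vs an independent BFS oracle
  for (seed in 1:6) {
    n <- c(50, 120, 200, 320, 430, 500)[seed]
    adj <- random_connected_adj(n, extra = n, seed = seed)
    gg <- germ_graph_from_adjacency(adj)
    roots <- seq_len(1 + seed %% 3)
    res <- flood_pseudotime(gg, roots, det_params)
    hops <- bfs_hops(as.matrix(adj), roots)
    expect_equal(res$pt, hops / max(hops))
  }
})

test_that("flood handles degenerate roots and is seed-deterministic", {
  adj <- random_connected_adj(60, extra = 60, seed = 2)
  g <- germ_graph_from_adjacency(adj)
  # all cells roots: all pseudotime zero
  expect_equal(flood_pseudotime(g, 1:60, flood_params(seed = 1))$pt,
               rep(0, 60))
  # on this sparse graph the visitation quorum strands many cells: they are
  # flagged (warning) and the run remains reproducible
  r1 <- suppressWarnings(flood_pseudotime(g, 1:3, flood_params(seed = 9)))
  r2 <- suppressWarnings(flood_pseudotime(g, 1:3, flood_params(seed = 9)))
  expect_identical(r1$pt, r2$pt)
  expect_error(flood_pseudotime(g, integer(0), flood_params()), "non-empty")
})

test_that("differentiation score averages and respects its boundaries", {
  expect_equal(differentiation_score(c(0, 1, 0.5), c(1, 0, 0.5)),
               c(0, 1, 0.5))
  expect_error(differentiation_score(c(0, 1), 1), "different cell sets")
})

test_that("differentiation score recovers latent time on a continuum", {
  cont <- fixture_continuum()
  expect_gte(cor(cont$pt$score, cont$latent, method = "spearman"), 0.9)
  expect_equal(range(cont$pt$score), c(0, 1))

  # swapping root definitions flips the score
  pt_sw <- germ_pseudotime(cont$expr, flood_params(seed = 1),
                           fwd_marker = "tssk6", rev_markers = "ddx4",
                           n_fwd = 1, n_rev = 2)
  expect_lt(mean(abs(cont$pt$score - (1 - pt_sw$score))), 0.05)
})

test_that("alignment scales scores by the matched maximum", {
  pair <- fixture_truncation_pair()
  al <- pair$alignment
  expect_true(al$M > 0 && al$M <= 1)
  expect_equal(al$scaled$scaled_score, al$scaled$score * al$M)
  expect_true(all(al$scaled$scaled_score <= al$M + 1e-12))

  # M close to the reference score at the truncation point (latent 0.5)
  ref05 <- mean(pair$pt_ref$score[abs(pair$latent_ref - 0.5) < 0.025])
  expect_lt(abs(al$M - ref05), 0.1)

  # truncated object ends where it should; reference does not
  expect_lt(mean(al$scaled$scaled_score > 0.7), 0.05)
  expect_gt(mean(pair$pt_ref$score > 0.7), 0.2)
})

test_that("self-alignment is the identity (M = 1)", {
  cont <- fixture_continuum()
  obj <- list(expr = cont$expr, pt = cont$pt,
              types = rep("spermatocytes", nrow(cont$pt)))
  al <- align_scores(obj, obj, match_type = "spermatocytes", n_neighbors = 1)
  expect_equal(al$M, 1)
  expect_equal(al$scaled$scaled_score, al$scaled$score)

  expect_error(align_scores(obj, obj, match_type = "spermatozoa"),
               "no cells of match type")
})
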