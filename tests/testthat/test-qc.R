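# independent percentile oracle: linear interpolation between order
# statistics at position 1 + p(n-1), coded from the definition
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- 1 + p * (length(s) - 1)
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

test_that("per-cell QC metrics follow their definitions", {
  x <- toy_counts(matrix(c(5, 95, 0, 0), 2, 2),
                  symbols = c("mt-co1", "ddx4"))
  qc <- compute_cell_qc(x)
  expect_equal(qc$pct_mito, c(5, 0))
  expect_equal(qc$n_genes, c(2L, 0L))
  expect_equal(qc$total_counts, c(100, 0))

  nomito <- toy_counts(matrix(1:4, 2, 2), symbols = c("a", "b"))
  expect_equal(compute_cell_qc(nomito)$pct_mito, c(0, 0))
})

test_that("IQR upper threshold matches an independent percentile oracle", {
  expect_equal(iqr_upper_threshold(1:8, "q3"), oracle_quantile(1:8, 0.75))
  q1 <- oracle_quantile(1:8, 0.25)
  q3 <- oracle_quantile(1:8, 0.75)
  expect_equal(iqr_upper_threshold(1:8, "tukey_fence"), q3 + 1.5 * (q3 - q1))

  set.seed(21)
  for (i in 1:50) {
    v <- sample(5000, sample(4:200, 1), replace = TRUE)
    q1 <- oracle_quantile(v, 0.25)
    q3 <- oracle_quantile(v, 0.75)
    expect_equal(iqr_upper_threshold(v, "q3"), q3)
    expect_equal(iqr_upper_threshold(v, "tukey_fence"), q3 + 1.5 * (q3 - q1))
  }

  # zero spread: Q3 and fence collapse to the common value
  expect_equal(iqr_upper_threshold(rep(7, 10), "q3"), 7)
  expect_equal(iqr_upper_threshold(rep(7, 10), "tukey_fence"), 7)

  expect_error(iqr_upper_threshold(1:3, "q3"), "at least 4")
  expect_error(iqr_upper_threshold(1:8, "fixed"), "fixed_upper")
  expect_equal(iqr_upper_threshold(1:8, "fixed", fixed_upper = 123), 123)
})

test_that("filter boundaries are strict as specified", {
  # 3 cells: pct_mito exactly 5 is kept; exactly 200 genes is removed
  n_genes <- 300
  mk_cell <- function(n_detected, mito_counts) {
    v <- numeric(n_genes)
    v[seq_len(n_detected)] <- 1
    total_rest <- sum(v)
    v[n_genes] <- mito_counts          # last gene is mito
    v
  }
  # cell 1: 285 expressed genes + 15 mito counts = exactly 5% mito
  m <- cbind(mk_cell(285, 15), mk_cell(250, 0), mk_cell(200, 0))
  symbols <- c(sprintf("g%03d", seq_len(n_genes - 1)), "mt-co1")
  x <- toy_counts(m, symbols = symbols)
  qc <- compute_cell_qc(x)
  expect_equal(qc$pct_mito[1], 5)
  res <- filter_cells(x, qc, filter_params(upper_rule = "fixed",
                                           fixed_upper = 1000))
  expect_true(res$keep[1])     # mito == 5% kept (only > 5% removed)
  expect_false(res$keep[3])    # exactly 200 genes removed (> 200 required)
})

test_that("six-cell worked example keeps exactly the four mid-range cells", {
  n_genes <- 5000
  det <- c(150, 201, 300, 400, 500, 5000)
  m <- vapply(det, function(k) { v <- numeric(n_genes); v[seq_len(k)] <- 1; v },
              numeric(n_genes))
  x <- toy_counts(m)
  qc <- compute_cell_qc(x)
  res <- filter_cells(x, qc, filter_params(upper_rule = "fixed",
                                           fixed_upper = 1000))
  expect_identical(which(res$keep), 2:5)
  expect_equal(res$report$cells_kept, 4)
})

test_that("filter agrees with an exhaustive per-cell oracle on random data", {
  for (seed in 1:20) {
    x <- random_counts(60, 200, seed = seed, n_mito = 3, lambda = 1)
    qc <- compute_cell_qc(x)
    params <- filter_params(min_genes = 30, upper_rule = "tukey_fence")
    res <- filter_cells(x, qc, params)
    thr <- iqr_upper_threshold(qc$n_genes, "tukey_fence")
    oracle <- vapply(seq_along(qc$cell), function(i) {
      qc$pct_mito[i] <= 5 && qc$n_genes[i] > 30 && qc$n_genes[i] < thr
    }, logical(1))
    expect_identical(res$keep, oracle)
    expect_identical(x$genes, res$matrix$genes)   # gene axis unchanged
  }
})

test_that("injected low-quality cells are removed and healthy cells kept", {
  spec <- synthetic_spec(germ_continuum_design(n_cells = 1500), seed = 3)
  ds <- generate_dataset(spec)
  m <- ds$matrices[[1]]
  qc <- compute_cell_qc(m)
  res <- filter_cells(m, qc, filter_params(upper_rule = "tukey_fence"))
  lowq <- ds$truth$is_lowq[match(m$barcodes, ds$truth$barcode)]
  expect_true(all(!res$keep[lowq]))
  expect_gte(mean(res$keep[!lowq]), 0.95)
})

test_that("filter report serializes to JSON with per-criterion counts", {
  x <- random_counts(30, 50, seed = 5)
  res <- filter_cells(x, compute_cell_qc(x),
                      filter_params(min_genes = 10, upper_rule = "q3"))
  path <- withr::local_tempfile(fileext = ".json")
  write_filter_report(res$report, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$cells_in, 50)
  expect_equal(parsed$rule, "q3")
  expect_true(all(c("removed_pct_mito", "removed_low_genes",
                    "removed_high_genes") %in% names(parsed)))
})
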