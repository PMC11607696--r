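#' Binned differentiation-score profiles
#'
#' Bins per-cell differentiation scores into `n_bins` equal half-open bins
#' [i/n, (i+1)/n) over [0, 1], the last bin closed at 1, and converts
#' per-sample counts to percentages (each sample sums to 100). When ages are
#' supplied, the per-age profile is the unweighted mean of that age's
#' per-sample profiles (replicates of the same age are averaged).
#'
#' @param scores numeric differentiation scores in [0, 1].
#' @param samples per-cell sample labels.
#' @param ages optional named vector mapping sample -> age (or per-cell
#'   ages).
#' @param n_bins number of bins (default 10, >= 2).
#' @return a `ScoreProfile`: list with `edges`, `by_sample` (data.frame:
#'   sample, bin, lower, upper, count, pct) and `by_age` (same per age, NULL
#'   when no ages given).
#' @export
binned_profile <- function(scores, samples, ages = NULL, n_bins = 10) {
  stopifnot(n_bins >= 2)
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  if (length(samples) != length(scores))
    stop("samples must match scores in length")
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(floor(scores * n_bins) + 1L, n_bins)   # score 1 -> last bin

  samp_levels <- unique(samples)
  by_sample <- do.call(rbind, lapply(samp_levels, function(s) {
    sel <- samples == s
    if (!any(sel)) stop("empty sample: ", s)
    cnt <- tabulate(bin[sel], nbins = n_bins)
    data.frame(sample = s, bin = seq_len(n_bins),
               lower = edges[-(n_bins + 1)], upper = edges[-1],
               count = cnt, pct = 100 * cnt / sum(cnt),
               stringsAsFactors = FALSE)
  }))

  by_age <- NULL
  if (!is.null(ages)) {
    age_of <- if (!is.null(names(ages))) ages[samp_levels]
              else vapply(samp_levels, function(s) ages[samples == s][1], numeric(1))
    by_age <- do.call(rbind, lapply(unique(age_of), function(a) {
      ss <- samp_levels[age_of == a]
      sub <- by_sample[by_sample$sample %in% ss, ]
      pct <- rowMeans(matrix(sub$pct[order(match(sub$sample, ss), sub$bin)],
                             nrow = n_bins))
      data.frame(age = a, bin = seq_len(n_bins),
                 lower = edges[-(n_bins + 1)], upper = edges[-1],
                 pct = pct, stringsAsFactors = FALSE)
    }))
  }
  structure(list(edges = edges, by_sample = by_sample, by_age = by_age),
            class = "ScoreProfile")
}

#' Default broad-category map for testis cell types
#'
#' Maps fine cell-type calls onto the broad categories used for
#' relative-abundance summaries: the four germ stages collapse to `germ`;
#' somatic types map to themselves.
#'
#' @return named character vector, type -> category.
#' @export
default_category_map <- function() {
  c(spermatogonia = "germ", spermatocytes = "germ", spermatids = "germ",
    spermatozoa = "germ", germ = "germ",
    sertoli = "sertoli", leydig = "leydig", smooth_muscle = "smooth_muscle",
    blood = "blood", macrophage = "macrophage", lymphocyte = "lymphocyte")
}

#' Relative abundance of cell categories per sample and per age
#'
#' Maps per-cell type calls to broad categories and tabulates counts and
#' percentages of total cells within each sample (and each age when given).
#' Types missing from the map are assigned `"other"` with a warning.
#'
#' @param types per-cell type calls (or a `TypeAssignment`).
#' @param samples per-cell sample labels.
#' @param ages optional per-cell ages (or named sample -> age vector).
#' @param category_map named vector type -> category (default
#'   [default_category_map()]).
#' @return a `CompositionTable`: list with `by_sample` and `by_age`
#'   data.frames (group, category, count, pct; percentages per group sum to
#'   100).
#' @export
composition_table <- function(types, samples, ages = NULL,
                              category_map = default_category_map()) {
  if (inherits(types, "TypeAssignment")) types <- types$cell_type
  stopifnot(length(types) == length(samples))
  cat_of <- unname(category_map[types])
  unmapped <- is.na(cat_of)
  if (any(unmapped)) {
    warning("unmapped cell types assigned 'other': ",
            paste(unique(types[unmapped]), collapse = ", "))
    cat_of[unmapped] <- "other"
  }
  tab_group <- function(groups) {
    do.call(rbind, lapply(unique(groups), function(g) {
      sel <- groups == g
      tt <- table(cat_of[sel])
      data.frame(group = g, category = names(tt),
                 count = as.integer(tt),
                 pct = 100 * as.integer(tt) / sum(sel),
                 stringsAsFactors = FALSE)
    }))
  }
  by_sample <- tab_group(samples)
  by_age <- NULL
  if (!is.null(ages)) {
    age_per_cell <- if (!is.null(names(ages))) unname(ages[samples]) else ages
    by_age <- tab_group(age_per_cell)
  }
  structure(list(by_sample = by_sample, by_age = by_age),
            class = "CompositionTable")
}

#' Dot-plot summary statistics
#'
#' For each (gene, group): the fraction of cells with expression > 0 and the
#' mean log-normalized expression among expressing cells. Genes absent from
#' the matrix are reported with `present = FALSE` rather than erroring;
#' groups with zero expressing cells report mean 0 with `no_expressing =
#' TRUE`; empty groups are skipped with a warning.
#'
#' @param expr an `ExprMatrix`.
#' @param groups per-cell group labels.
#' @param genes gene symbols to summarize.
#' @return data.frame: `gene`, `group`, `frac_expressing`, `mean_expressing`,
#'   `present`, `no_expressing`.
#' @export
dotplot_stats <- function(expr, groups, genes) {
  stopifnot(inherits(expr, "ExprMatrix"))
  stopifnot(length(groups) == ncol(expr$expr))
  glev <- unique(groups)
  empty <- vapply(glev, function(g) sum(groups == g) == 0, logical(1))
  if (any(empty)) {
    warning("empty groups skipped: ", paste(glev[empty], collapse = ", "))
    glev <- glev[!empty]
  }
  out <- expand.grid(gene = genes, group = glev, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$frac_expressing <- 0
  out$mean_expressing <- 0
  out$present <- out$gene %in% expr$genes$symbol
  out$no_expressing <- TRUE
  for (i in seq_len(nrow(out))) {
    if (!out$present[i]) next
    row <- match(out$gene[i], expr$genes$symbol)
    v <- expr$expr[row, groups == out$group[i]]
    pos <- v > 0
    out$frac_expressing[i] <- mean(pos)
    if (any(pos)) {
      out$mean_expressing[i] <- mean(v[pos])
      out$no_expressing[i] <- FALSE
    }
  }
  out
}
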