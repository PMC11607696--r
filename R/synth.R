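#' Default expression programs for the synthetic testis
#'
#' Expression along the germ continuum is modelled as Gaussian bumps in
#' latent differentiation time (bump width 0.15 latent-time units): the four
#' canonical stage markers ddx4, sycp3, ccnb3 and tssk6 peak in order at
#' 0.05, 0.35, 0.65 and 0.95, a set of filler germ genes with peaks tiling
#' [0,1] provides a smooth, recoverable manifold, and a few reportable
#' spermatogonial genes (e2f5, piwil1, sumo3b, ilf2, dmrt1) peak early.
#' Somatic compartments express constant programs around their canonical
#' markers (gsdf, star, tagln/acta2, hbba1, mpeg1.1, lck). Oogenesis and
#' pluripotency genes (zp3.2, nanos3, nanog, pou5f3) carry no program in
#' healthy samples; see [synthetic_spec()] for their aberrant activation in
#' incomplete samples.
#'
#' @param n_germ_filler number of filler germ-continuum genes (default 56).
#' @return data.frame with columns `gene`, `compartment`, `peak_time`
#'   (NA = constant program) and `peak_mean` (relative weight).
#' @export
default_marker_programs <- function(n_germ_filler = 56) {
  germ <- data.frame(
    gene = c("ddx4", "sycp3", "ccnb3", "tssk6",
             "e2f5", "piwil1", "sumo3b", "ilf2", "dmrt1"),
    compartment = "germ",
    peak_time = c(0.05, 0.35, 0.65, 0.95, 0.03, 0.06, 0.08, 0.15, 0.10),
    peak_mean = c(40, 40, 40, 40, 10, 12, 10, 8, 6),
    stringsAsFactors = FALSE)
  filler <- data.frame(
    gene = sprintf("germ.p%02d", seq_len(n_germ_filler)),
    compartment = "germ",
    peak_time = seq(0.01, 0.99, length.out = n_germ_filler),
    peak_mean = 15, stringsAsFactors = FALSE)
  som <- function(comp, markers, weights, n_fill, prefix) {
    data.frame(
      gene = c(markers, sprintf("%s.g%02d", prefix, seq_len(n_fill))),
      compartment = comp, peak_time = NA_real_,
      peak_mean = c(weights, rep(15, n_fill)), stringsAsFactors = FALSE)
  }
  rbind(germ, filler,
        som("sertoli", "gsdf", 40, 9, "srt"),
        som("leydig", "star", 40, 9, "ley"),
        som("smooth_muscle", c("tagln", "acta2"), c(40, 30), 8, "smc"),
        som("blood", "hbba1", 60, 9, "bld"),
        som("macrophage", "mpeg1.1", 40, 9, "mac"),
        som("lymphocyte", "lck", 40, 9, "lym"))
}

#' Default multi-sample study design
#'
#' Mirrors the study timeline: complete-spermatogenesis samples at 5, 12, 20
#' and 22 months plus a 27-month complete sample (full latent-time support
#' but a thinned post-meiotic tail) and a 27-month incomplete sample whose
#' germ continuum is truncated at latent time 0.5 and whose immune
#' compartments (macrophage + lymphocyte) make up 40% of cells. Complete
#' samples are 93% germ cells.
#'
#' @param n_cells cells per sample (default 1000).
#' @return list with `samples` (data.frame: sample, age_months, status,
#'   n_cells, t_max, latent_shape) and `weights` (data.frame of per-sample
#'   compartment fractions including `germ`).
#' @export
testis_design <- function(n_cells = 1000) {
  samples <- data.frame(
    sample = c("s05", "s12", "s20", "s22", "s27c", "s27i"),
    age_months = c(5, 12, 20, 22, 27, 27),
    status = c("complete", "complete", "complete", "complete",
               "complete", "incomplete"),
    n_cells = n_cells,
    t_max = c(1, 1, 1, 1, 1, 0.5),
    latent_shape = c(1, 1, 1, 1, 1.4, 1),
    stringsAsFactors = FALSE)
  cw <- c(sertoli = 0.015, leydig = 0.012, smooth_muscle = 0.012,
          blood = 0.011, macrophage = 0.012, lymphocyte = 0.008)
  weights <- as.data.frame(rbind(
    cbind(germ = 0.93, t(replicate(5, cw))),
    c(germ = 0.35, sertoli = 0.05, leydig = 0.04, smooth_muscle = 0.04,
      blood = 0.12, macrophage = 0.28, lymphocyte = 0.12)))
  rownames(weights) <- samples$sample
  list(samples = samples, weights = weights)
}

#' Specification of a synthetic testis scRNA-seq dataset
#'
#' Validates and assembles the full parameter set of the generator. Per
#' sample, `germ + sum(somatic weights)` must equal 1 within 1e-9 and all
#' truncation times must lie in (0, 1].
#'
#' @param design a [testis_design()] list (`samples` + `weights`), possibly
#'   edited.
#' @param programs expression programs from [default_marker_programs()].
#' @param n_genes total genes including mitochondrial and housekeeping
#'   filler (default 400; must exceed the program gene count + mito genes).
#' @param library_size_lognormal `c(meanlog, sdlog)` of per-cell library
#'   size (default `c(log(5000), 0.3)`).
#' @param nb_dispersion negative-binomial dispersion shared across genes
#'   (variance = mu + dispersion * mu^2; default 0.3).
#' @param dropout_rate probability each count entry is zeroed (default 0.1).
#' @param mito_gene_count number of mt- genes (default 10, capped at 13).
#' @param mito_beta `c(a, b)` Beta shape of the per-cell mitochondrial
#'   fraction of healthy cells (default `c(2, 150)`, mean ~1.3%).
#' @param lowq_fraction fraction of cells injected as low quality (default
#'   0.05): half get mito fraction in (0.10, 0.30), half get tiny libraries
#'   so they detect fewer than 200 genes.
#' @param aberrant_weight constant weight given to zp3.2, nanos3, nanog and
#'   pou5f3 in germ cells of incomplete samples, emulating their aberrant
#'   transcriptional state (default 10; 0 disables).
#' @param seed RNG seed (integer).
#' @return a validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(design = testis_design(),
                           programs = default_marker_programs(),
                           n_genes = 400,
                           library_size_lognormal = c(log(5000), 0.3),
                           nb_dispersion = 0.3,
                           dropout_rate = 0.1,
                           mito_gene_count = 10,
                           mito_beta = c(2, 150),
                           lowq_fraction = 0.05,
                           aberrant_weight = 10,
                           seed = 1) {
  samples <- design$samples
  weights <- design$weights
  stopifnot(is.data.frame(samples), nrow(samples) >= 1)
  if (any(samples$n_cells < 1)) stop("every sample needs at least one cell")
  somatic <- setdiff(colnames(weights), "germ")
  for (i in seq_len(nrow(samples))) {
    w <- weights[samples$sample[i], ]
    if (any(w < 0) || any(w > 1))
      stop("compartment fractions must lie in [0, 1] (sample ",
           samples$sample[i], ")")
    if (abs(sum(unlist(w)) - 1) > 1e-9)
      stop("germ fraction + somatic weights must sum to 1 (sample ",
           samples$sample[i], ", sum = ", sum(unlist(w)), ")")
  }
  if (any(samples$t_max <= 0 | samples$t_max > 1))
    stop("all t_max must lie in (0, 1]")
  stopifnot(nb_dispersion > 0, dropout_rate >= 0, dropout_rate < 1,
            lowq_fraction >= 0, lowq_fraction < 1,
            length(mito_beta) == 2, all(mito_beta > 0))
  mito_gene_count <- min(mito_gene_count, 13)
  n_prog <- length(unique(programs$gene))
  if (n_genes < n_prog + mito_gene_count)
    stop("n_genes (", n_genes, ") too small for ", n_prog,
         " program genes + ", mito_gene_count, " mito genes")
  structure(list(
    samples = samples, weights = weights, somatic = somatic,
    programs = programs, n_genes = n_genes,
    library_size_lognormal = library_size_lognormal,
    nb_dispersion = nb_dispersion, dropout_rate = dropout_rate,
    mito_gene_count = mito_gene_count, mito_beta = mito_beta,
    lowq_fraction = lowq_fraction, aberrant_weight = aberrant_weight,
    bump_width = 0.15, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

.mito_names <- function(n) {
  c("mt-co1", "mt-co2", "mt-co3", "mt-nd1", "mt-nd2", "mt-nd3", "mt-nd4",
    "mt-nd5", "mt-nd6", "mt-atp6", "mt-atp8", "mt-cytb", "mt-nd4l")[seq_len(n)]
}

#' Generate a synthetic multi-sample testis dataset
#'
#' Draws, per sample: compartments from the sample's weights; germ latent
#' times as `t_max * Beta(1, latent_shape)` (Uniform(0, t_max) at the
#' default shape of 1); per-cell expression weights as the sum of Gaussian
#' bumps (germ) or constant programs (somatic) over a housekeeping baseline;
#' counts as NegativeBinomial(mean = library size x normalized profile,
#' shared dispersion), thinned by Bernoulli dropout. Mitochondrial counts
#' are allocated so the true mito fraction of healthy cells follows the
#' spec's Beta law; injected low-quality cells instead get a mito fraction
#' above 5% or a library so small that fewer than 200 genes are detected.
#' Deterministic given the spec seed.
#'
#' @param spec a validated [synthetic_spec()].
#' @return list with `matrices` (named list of [count_matrix()], one per
#'   sample), `truth` (data.frame: cell, barcode, sample, age_months,
#'   compartment, latent_time, is_lowq — `cell` is the sample-prefixed
#'   barcode used after [merge_samples()]) and `metas` (per-sample metadata
#'   data.frame).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)

  mito_genes <- .mito_names(spec$mito_gene_count)
  prog_genes <- unique(spec$programs$gene)
  extra_genes <- c("zp3.2", "nanos3", "nanog", "pou5f3")
  n_hk <- spec$n_genes - length(prog_genes) - length(mito_genes) -
    length(extra_genes)
  if (n_hk < 0) stop("n_genes too small for program + aberrant + mito genes")
  hk_genes <- sprintf("hk.%03d", seq_len(n_hk))
  gene_symbols <- c(prog_genes, extra_genes, hk_genes, mito_genes)
  gene_ids <- gene_symbols
  n_nonmito <- length(gene_symbols) - length(mito_genes)

  matrices <- list()
  truth <- vector("list", nrow(spec$samples))
  metas <- spec$samples[, c("sample", "age_months", "status")]

  for (si in seq_len(nrow(spec$samples))) {
    srow <- spec$samples[si, ]
    n <- srow$n_cells
    w <- unlist(spec$weights[srow$sample, ])
    comp_names <- names(w)
    # largest-remainder apportionment: realized compartment counts match the
    # design weights exactly (to one cell), for any sample size and seed
    base <- floor(w * n)
    rem <- w * n - base
    extra <- order(-rem, seq_along(w))[seq_len(n - sum(base))]
    cnt <- base
    cnt[extra] <- cnt[extra] + 1
    comp <- rep(comp_names, cnt)
    latent <- rep(NA_real_, n)
    is_germ <- comp == "germ"
    latent[is_germ] <- srow$t_max * stats::rbeta(sum(is_germ), 1, srow$latent_shape)

    # low-quality injection: half high mito, half tiny library
    n_lowq <- round(spec$lowq_fraction * n)
    lowq <- rep(FALSE, n)
    if (n_lowq > 0) lowq[sample.int(n, n_lowq)] <- TRUE
    lowq_idx <- which(lowq)
    high_mito <- lowq_idx[seq_len(floor(length(lowq_idx) / 2))]
    tiny_lib <- setdiff(lowq_idx, high_mito)

    # per-cell non-mito expression weights
    W <- matrix(0, n_nonmito, n)
    rownames(W) <- gene_symbols[seq_len(n_nonmito)]
    hk_rows <- match(hk_genes, rownames(W))
    W[hk_rows, ] <- 1
    gprog <- spec$programs[spec$programs$compartment == "germ", ]
    if (any(is_germ)) {
      rows <- match(gprog$gene, rownames(W))
      t <- latent[is_germ]
      bump <- gprog$peak_mean *
        exp(-(outer(gprog$peak_time, t, "-"))^2 / (2 * spec$bump_width^2))
      W[rows, is_germ] <- bump
      if (srow$status == "incomplete" && spec$aberrant_weight > 0) {
        W[match(extra_genes, rownames(W)), is_germ] <- spec$aberrant_weight
      }
    }
    for (cn in spec$somatic) {
      in_c <- comp == cn
      if (!any(in_c)) next
      cprog <- spec$programs[spec$programs$compartment == cn, ]
      W[match(cprog$gene, rownames(W)), in_c] <- cprog$peak_mean
    }
    p <- sweep(W, 2, colSums(W), "/")

    # mito fraction and library size
    f <- stats::rbeta(n, spec$mito_beta[1], spec$mito_beta[2])
    f[high_mito] <- stats::runif(length(high_mito), 0.10, 0.30)
    lib <- stats::rlnorm(n, spec$library_size_lognormal[1],
                         spec$library_size_lognormal[2])
    lib[tiny_lib] <- stats::runif(length(tiny_lib), 80, 150)

    mu_nonmito <- sweep(p, 2, lib * (1 - f), "*")
    mu_mito <- matrix(rep(lib * f / length(mito_genes), each = length(mito_genes)),
                      length(mito_genes), n)
    mu <- rbind(mu_nonmito, mu_mito)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / spec$nb_dispersion),
                     nrow(mu), n)
    if (spec$dropout_rate > 0) {
      keep <- matrix(stats::runif(length(counts)) >= spec$dropout_rate,
                     nrow(counts), n)
      counts <- counts * keep
    }

    barcodes <- sprintf("cell%05d", seq_len(n))
    matrices[[srow$sample]] <- count_matrix(counts, gene_ids, gene_symbols,
                                            barcodes)
    truth[[si]] <- data.frame(
      cell = paste0(srow$sample, "_", barcodes),
      barcode = barcodes, sample = srow$sample,
      age_months = srow$age_months, compartment = comp,
      latent_time = latent, is_lowq = lowq, stringsAsFactors = FALSE)
  }
  list(matrices = matrices, truth = do.call(rbind, truth), metas = metas)
}

#' Simulate a dataset and write it as 10x-style directories
#'
#' One sub-directory per sample (matrix.mtx + features.tsv + barcodes.tsv),
#' the ground truth as `cell_truth.tsv` (columns cell, sample, age_months,
#' compartment, latent_time, is_lowq) and the sample metadata as
#' `samples.tsv`.
#'
#' @param spec a [synthetic_spec()].
#' @param path output directory.
#' @return invisibly, the [generate_dataset()] result.
#' @export
simulate_dataset <- function(spec, path) {
  ds <- generate_dataset(spec)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (s in names(ds$matrices))
    write_mtx_dir(ds$matrices[[s]], file.path(path, s))
  utils::write.table(
    ds$truth[, c("cell", "sample", "age_months", "compartment",
                 "latent_time", "is_lowq")],
    file.path(path, "cell_truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$metas, file.path(path, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ds)
}

#' Single-sample germ-continuum design
#'
#' A pure (or nearly pure) germ-cell sample used for pseudotime recovery
#' checks: one complete-spermatogenesis sample with configurable truncation.
#'
#' @param n_cells number of cells.
#' @param t_max latent-time truncation in (0, 1].
#' @param germ_fraction germ fraction (default 1: pure continuum; the
#'   remainder is split equally over the somatic compartments).
#' @param sample_id,age_months,status sample annotations.
#' @return a design list consumable by [synthetic_spec()].
#' @export
germ_continuum_design <- function(n_cells = 2000, t_max = 1,
                                  germ_fraction = 1, sample_id = "germ1",
                                  age_months = 12,
                                  status = if (t_max < 1) "incomplete" else "complete") {
  samples <- data.frame(sample = sample_id, age_months = age_months,
                        status = status, n_cells = n_cells, t_max = t_max,
                        latent_shape = 1, stringsAsFactors = FALSE)
  som <- c("sertoli", "leydig", "smooth_muscle", "blood", "macrophage",
           "lymphocyte")
  weights <- data.frame(germ = germ_fraction,
                        as.list(stats::setNames(rep((1 - germ_fraction) / 6, 6), som)),
                        check.names = FALSE)
  rownames(weights) <- sample_id
  list(samples = samples, weights = weights)
}
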