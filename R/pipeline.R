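#' Assemble a pipeline run configuration
#'
#' @param samples data.frame with one row per sample: `path` (10x-style
#'   directory), `sample`, `age_months`, `status` (complete / incomplete /
#'   unknown).
#' @param out_dir output directory for run artifacts.
#' @param filter a [filter_params()].
#' @param flood a [flood_params()] (its seed is overridden by `seed`).
#' @param n_bins score-profile bins (default 10).
#' @param z_threshold typing z-score threshold (default 1).
#' @param n_top,d,cluster_k HVG / PCA / clustering parameters.
#' @param panel a [default_marker_panel()].
#' @param category_map type -> category map for composition.
#' @param seed run seed, recorded in every output.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(samples, out_dir,
                            filter = filter_params(upper_rule = "tukey_fence"),
                            flood = flood_params(),
                            n_bins = 10, z_threshold = 1.0,
                            n_top = 2000, d = 20, cluster_k = 15,
                            panel = default_marker_panel(),
                            category_map = default_category_map(),
                            seed = 1) {
  stopifnot(is.data.frame(samples),
            all(c("path", "sample", "age_months", "status") %in% colnames(samples)))
  missing <- !dir.exists(samples$path)
  if (any(missing))
    stop("sample path(s) do not exist: ",
         paste(samples$path[missing], collapse = ", "))
  structure(list(samples = samples, out_dir = out_dir, filter = filter,
                 flood = flood, n_bins = n_bins, z_threshold = z_threshold,
                 n_top = n_top, d = d, cluster_k = cluster_k, panel = panel,
                 category_map = category_map, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys: `samples` (list of path/sample/age_months/status),
#' `out_dir`, `seed`, `n_bins`, `z_threshold`, `filter` (max_pct_mito,
#' min_genes, upper_rule, fixed_upper) and `flood` (n_simulations,
#' cells_per_step_fraction, min_visited_neighbors).
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  samples <- do.call(rbind, lapply(y$samples, function(s)
    data.frame(path = s$path, sample = s$sample,
               age_months = as.numeric(s$age_months),
               status = if (is.null(s$status)) "unknown" else s$status,
               stringsAsFactors = FALSE)))
  filter <- do.call(filter_params, c(y$filter))
  flood <- do.call(flood_params, c(y$flood))
  pipeline_config(samples, y$out_dir, filter = filter, flood = flood,
                  n_bins = if (is.null(y$n_bins)) 10 else y$n_bins,
                  z_threshold = if (is.null(y$z_threshold)) 1 else y$z_threshold,
                  seed = if (is.null(y$seed)) 1 else y$seed)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.germ_stage_types <- c("spermatogonia", "spermatocytes", "spermatids",
                       "spermatozoa")

#' Run the full analysis pipeline
#'
#' Executes read -> per-sample QC filter -> merge -> log-normalize -> HVG ->
#' PCA -> cluster -> marker typing -> germ-cell subset -> bidirectional
#' flood pseudotime (reference object: germ cells of complete samples;
#' separate runs for each incomplete sample, each with k = round(sqrt(n)))
#' -> score alignment of incomplete objects via matched spermatocytes ->
#' binned score profiles and composition tables. Every intermediate table is
#' written under `out_dir` along with a JSON manifest (parameters, seed,
#' config hash, package version) and a plain-text log; a failure aborts with
#' the stage name while retaining partial outputs.
#'
#' @param config a `run_config` from [pipeline_config()] or
#'   [read_run_config()].
#' @return invisibly, a list with the principal in-memory results
#'   (`assignment`, `pt_reference`, `alignments`, `profile`, `composition`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  logf <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- "init"
  on.exit(writeLines(log_lines, log_path), add = TRUE)
  fail <- function(e) stop("pipeline stage '", stage, "' failed: ",
                           conditionMessage(e), call. = FALSE)

  tryCatch({
    stage <- "read"
    mats <- lapply(seq_len(nrow(config$samples)), function(i)
      read_mtx_dir(config$samples$path[i]))
    names(mats) <- config$samples$sample
    logf("read %d samples (%s cells)", length(mats),
         paste(vapply(mats, function(m) ncol(m$counts), numeric(1)),
               collapse = "+"))

    stage <- "qc"
    reports <- list()
    for (s in names(mats)) {
      qc <- compute_cell_qc(mats[[s]])
      fr <- filter_cells(mats[[s]], qc, config$filter)
      mats[[s]] <- fr$matrix
      reports[[s]] <- unclass(fr$report)
      logf("sample %s: %d -> %d cells after QC (upper=%.1f)", s,
           fr$report$cells_in, fr$report$cells_kept,
           fr$report$upper_thresholds[["all"]])
    }
    jsonlite::write_json(reports, file.path(config$out_dir, "filter_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    stage <- "merge"
    metas <- config$samples[, c("sample", "age_months", "status")]
    merged <- merge_samples(mats, metas)
    cells <- merged$cells

    stage <- "normalize"
    expr <- normalize_log(merged$matrix)

    stage <- "cluster"
    hvg <- select_hvg(expr, config$n_top)
    emb <- embed_pca(expr, hvg,
                     d = min(config$d, length(hvg) - 1, ncol(expr$expr) - 1))
    labels <- cluster_cells(emb, k_neighbors = config$cluster_k)
    logf("clustering: %d clusters (k=%d)", labels$n_clusters, config$cluster_k)

    stage <- "type"
    assignment <- score_cell_types(expr, labels, config$panel,
                                   config$z_threshold)
    .write_tsv(data.frame(cell = cells$cell, sample = cells$sample,
                          cluster = assignment$cluster,
                          cell_type = assignment$cell_type),
               file.path(config$out_dir, "cell_types.tsv"))

    stage <- "germ_graph"
    is_germ <- assignment$cell_type %in% .germ_stage_types
    is_complete <- cells$status == "complete"
    sub_expr <- function(sel) structure(
      list(expr = expr$expr[, sel, drop = FALSE], genes = expr$genes,
           scale = expr$scale), class = "ExprMatrix")
    flood <- config$flood
    flood$seed <- config$seed

    stage <- "pseudotime_reference"
    ref_sel <- is_germ & is_complete
    if (sum(ref_sel) < 50)
      stop("too few germ cells in complete samples (", sum(ref_sel), ")")
    ref_expr <- sub_expr(ref_sel)
    pt_ref <- germ_pseudotime(ref_expr, params = flood, n_top = config$n_top,
                              d = config$d, cluster_k = config$cluster_k)
    logf("reference pseudotime: %d germ cells, k=%d, reverse marker=%s",
         sum(ref_sel), attr(pt_ref, "k"), attr(pt_ref, "rev_marker"))

    stage <- "pseudotime_incomplete"
    alignments <- list()
    pt_all <- data.frame(cell = pt_ref$cell, score = pt_ref$score,
                         scaled_score = pt_ref$score,
                         object = "reference", stringsAsFactors = FALSE)
    fwd_rev <- pt_ref[, c("cell", "pt_fwd", "pt_rev")]
    inc_samples <- unique(cells$sample[cells$status == "incomplete"])
    for (s in inc_samples) {
      sel <- is_germ & cells$sample == s
      if (sum(sel) < 50) {
        logf("skipping incomplete sample %s: only %d germ cells", s, sum(sel))
        next
      }
      inc_expr <- sub_expr(sel)
      pt_inc <- germ_pseudotime(inc_expr, params = flood,
                                n_top = config$n_top, d = config$d,
                                cluster_k = config$cluster_k)
      # type the incomplete object on its own clusters: its most
      # differentiated germ stage present is the match type
      types_inc <- score_cell_types(inc_expr, attr(pt_inc, "labels"),
                                    config$panel, config$z_threshold)$cell_type
      stages <- .germ_stage_types[.germ_stage_types %in% types_inc]
      if (length(stages) == 0)
        stop("no germ stage typed within incomplete sample ", s)
      match_type <- stages[length(stages)]
      al <- align_scores(list(expr = inc_expr, pt = pt_inc, types = types_inc),
                         list(expr = ref_expr, pt = pt_ref),
                         match_type = match_type, d = config$d)
      alignments[[s]] <- al
      logf("aligned %s via %s: M = %.3f (%d matched cells)", s, match_type,
           al$M, nrow(al$matched))
      pt_all <- rbind(pt_all,
                      data.frame(cell = al$scaled$cell, score = al$scaled$score,
                                 scaled_score = al$scaled$scaled_score,
                                 object = s, stringsAsFactors = FALSE))
      fwd_rev <- rbind(fwd_rev, pt_inc[, c("cell", "pt_fwd", "pt_rev")])
    }
    .write_tsv(merge(pt_all, fwd_rev, by = "cell", all.x = TRUE, sort = TRUE),
               file.path(config$out_dir, "pseudotime.tsv"))

    stage <- "profile"
    cell_idx <- match(pt_all$cell, cells$cell)
    prof <- binned_profile(pt_all$scaled_score,
                           cells$sample[cell_idx],
                           ages = stats::setNames(metas$age_months, metas$sample),
                           n_bins = config$n_bins)
    .write_tsv(prof$by_sample, file.path(config$out_dir, "score_profile_by_sample.tsv"))
    .write_tsv(prof$by_age, file.path(config$out_dir, "score_profile_by_age.tsv"))

    stage <- "composition"
    comp <- composition_table(assignment$cell_type, cells$sample,
                              ages = stats::setNames(metas$age_months, metas$sample),
                              category_map = config$category_map)
    .write_tsv(comp$by_sample, file.path(config$out_dir, "composition_by_sample.tsv"))
    .write_tsv(comp$by_age, file.path(config$out_dir, "composition_by_age.tsv"))

    stage <- "manifest"
    cfg_for_hash <- config
    cfg_for_hash$out_dir <- NULL
    cfg_json <- jsonlite::toJSON(
      lapply(unclass(cfg_for_hash), function(x)
        if (is.data.frame(x) || is.list(x)) unclass(x) else x),
      auto_unbox = TRUE, digits = NA, force = TRUE)
    tmp <- tempfile()
    writeLines(as.character(cfg_json), tmp)
    cfg_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
    manifest <- list(
      seed = config$seed,
      config_hash = cfg_hash,
      package_version = as.character(utils::packageVersion("germflow")),
      n_cells_post_filter = nrow(cells),
      n_clusters = labels$n_clusters,
      k_reference = attr(pt_ref, "k"),
      alignment_M = lapply(alignments, function(a) a$M))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(assignment = assignment, cells = cells,
                   pt_reference = pt_ref, alignments = alignments,
                   profile = prof, composition = comp, manifest = manifest))
  }, error = fail)
}
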