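## End-to-end workflow: ingest -> pseudobulk -> DDG detection -> trajectory
## fitting -> partial DTW -> stage correspondence, with a machine-readable
## provenance record.

PIPELINE_DEFAULTS <- list(
  r2_min = 0.3,
  scope = "either",
  significance_filter = TRUE,
  alpha = 0.05,
  degree = 3L,
  grid_size = 100L,
  dtw_mode = "partial",
  distance = "euclidean",
  mean_space = "log",
  min_features_ref = 0L,
  min_features_query = 0L,
  min_ddg_genes = 10L
)

#' Pipeline configuration
#'
#' All tunables of [run_pipeline()] with validated defaults. Unknown keys
#' are rejected. The QC thresholds default to 0 (no filtering); for the
#' real embryonic heart datasets the conventional values are 1000 detected
#' genes for human cells and 600 for mouse cells.
#'
#' @param ... named overrides of the defaults: `r2_min` (0.3), `scope`
#'   ("either"/"both"), `significance_filter` (TRUE), `alpha` (0.05),
#'   `degree` (3), `grid_size` (100), `dtw_mode` ("partial"/"full"),
#'   `distance` ("euclidean"/"correlation"), `mean_space` ("log"/"linear"),
#'   `min_features_ref` (0), `min_features_query` (0), `min_ddg_genes` (10).
#' @return a validated `pipeline_config` list.
#' @export
#' @examples
#' pipeline_config(r2_min = 0.5, grid_size = 50)
pipeline_config <- function(...) {
  overrides <- list(...)
  if (length(overrides) > 0L && (is.null(names(overrides)) || any(names(overrides) == ""))) {
    stop_cardalign("All configuration entries must be named.",
                   "cardalign_config_error")
  }
  unknown <- setdiff(names(overrides), names(PIPELINE_DEFAULTS))
  if (length(unknown) > 0L) {
    stop_cardalign(paste0("Unknown configuration key(s): ",
                          paste(unknown, collapse = ", ")),
                   "cardalign_config_error")
  }
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, overrides)
  ok <- function(test, msg) if (!isTRUE(test)) stop_cardalign(msg, "cardalign_config_error")
  ok(is.numeric(cfg$r2_min) && cfg$r2_min >= 0,
     "r2_min must be a non-negative number.")
  ok(cfg$scope %in% c("either", "both"), "scope must be 'either' or 'both'.")
  ok(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha <= 1,
     "alpha must lie in (0, 1].")
  ok(cfg$degree >= 1, "degree must be at least 1.")
  ok(cfg$grid_size >= 5, "grid_size must be at least 5.")
  ok(cfg$dtw_mode %in% c("partial", "full"), "dtw_mode must be 'partial' or 'full'.")
  ok(cfg$distance %in% c("euclidean", "correlation"),
     "distance must be 'euclidean' or 'correlation'.")
  ok(cfg$mean_space %in% c("log", "linear"), "mean_space must be 'log' or 'linear'.")
  ok(cfg$min_features_ref >= 0 && cfg$min_features_query >= 0,
     "QC thresholds must be non-negative.")
  ok(cfg$min_ddg_genes >= 1, "min_ddg_genes must be at least 1.")
  structure(cfg, class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    cls <- setdiff(class(e), c("rlang_error", "error", "condition"))
    abort(paste0("pipeline stage '", stage, "': ", conditionMessage(e)),
          class = c("cardalign_pipeline_error", cls), parent = e)
  })
}

#' Run the cross-species stage-alignment workflow
#'
#' Executes QC filtering, log transformation, pseudo-bulk aggregation,
#' 1:1 ortholog joining, dynamic-gene detection, standardized cubic curve
#' fitting and partial DTW alignment of the query species' stages onto the
#' reference species', for one cell type. If `out_dir` is given, every
#' intermediate table plus a YAML provenance record (thresholds, seeds,
#' package version) is written there; outputs produced before a failing
#' stage are preserved.
#'
#' @param ref,query `expr_mat` objects on the TPM (or already log) scale.
#' @param ref_cells,query_cells cell metadata tables.
#' @param orthologs two-column 1:1 ortholog map (ref gene, query gene).
#' @param cell_type cell type to align, e.g. `"CMs-A"`.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param verbose print stage progress messages.
#' @return list with `pseudobulk` (joined pair), `ddgs`, `trajectories`,
#'   `path`, `correspondence` and the provenance `log`.
#' @export
run_pipeline <- function(ref, ref_cells, query, query_cells, orthologs,
                         cell_type, config = pipeline_config(),
                         out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) inform(sprintf(...))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }

  say("[ingest] QC filtering (nFeature > %d ref, > %d query)",
      config$min_features_ref, config$min_features_query)
  prep <- function(m, cells, thr) with_stage("ingest", {
    qc <- qc_filter(m, thr)
    cells <- cell_table(cells)
    cells <- cells[cells$cell_id %in% cell_ids(qc$matrix), , drop = FALSE]
    m <- qc$matrix
    if (m$scale == "tpm") m <- log_transform(m)
    list(matrix = m, cells = cells, qc = qc$report)
  })
  r <- prep(ref, ref_cells, config$min_features_ref)
  q <- prep(query, query_cells, config$min_features_query)

  say("[pseudobulk] aggregating by species / cell type / stage")
  pb <- with_stage("pseudobulk", {
    pa <- aggregate_pseudobulk(r$matrix, r$cells, mean_space = config$mean_space)
    pbq <- aggregate_pseudobulk(q$matrix, q$cells, mean_space = config$mean_space)
    join_orthologs(pa, pbq, orthologs)
  })
  emit("pseudobulk_ref.tsv", function(f)
    write_pseudobulk(pb$a, f, sub("\\.tsv$", "_samples.tsv", f)))
  emit("pseudobulk_query.tsv", function(f)
    write_pseudobulk(pb$b, f, sub("\\.tsv$", "_samples.tsv", f)))

  say("[ddg] detecting developmentally dynamic genes (R^2 >= %.2f, scope %s)",
      config$r2_min, config$scope)
  ddgs <- with_stage("ddg", detect_ddgs(
    pb$a, pb$b, cell_type = cell_type, r2_min = config$r2_min,
    scope = config$scope, degree = config$degree,
    significance_filter = config$significance_filter, alpha = config$alpha))
  emit("ddg_fits.tsv", function(f) write_ddg_set(ddgs, f))
  if (length(ddgs$genes) < config$min_ddg_genes) {
    stop_cardalign(sprintf(
      "Only %d DDG(s) detected for %s (minimum %d); alignment refused. Lower r2_min, relax the significance filter, or check that the input spans enough stages.",
      length(ddgs$genes), cell_type, config$min_ddg_genes),
      "cardalign_argument_error")
  }

  say("[align] fitting standardized trajectories for %d DDGs", length(ddgs$genes))
  trajectories <- with_stage("align", {
    ct_a <- which(pb$a$samples$cell_type == cell_type)
    ct_b <- which(pb$b$samples$cell_type == cell_type)
    # per-sample median centering with the non-dynamic genes as controls
    # (their median estimates the compositional offset without being pulled
    # by the trends themselves), then restrict to the DDGs
    ctrl_a <- setdiff(rownames(pb$a$values), ddgs$genes)
    ctrl_b <- setdiff(rownames(pb$b$values), ddgs$genes_b)
    if (length(ctrl_a) < 0.1 * nrow(pb$a$values)) { ctrl_a <- NULL; ctrl_b <- NULL }
    cen <- if (is.null(ctrl_a)) "median" else "mean"
    va <- median_center_samples(pb$a$values[, ct_a, drop = FALSE], ctrl_a, cen)
    vb <- median_center_samples(pb$b$values[, ct_b, drop = FALSE], ctrl_b, cen)
    xa <- va[ddgs$genes, , drop = FALSE]
    xb <- vb[ddgs$genes_b, , drop = FALSE]
    rownames(xb) <- ddgs$genes
    # joint cross-species standardization: one affine transform per gene
    # over the union of both species' samples, so the two trajectory
    # families live on a common scale and subsequence matching stays
    # identifiable (per-species standardization would rescale each gene
    # differently over the two time windows)
    sj <- standardize_profiles(cbind(xa, xb))
    keep <- rownames(sj)
    sa <- sj[, seq_len(ncol(xa)), drop = FALSE]
    sb <- sj[, ncol(xa) + seq_len(ncol(xb)), drop = FALSE]
    ta <- fit_curve_grid(sa, pb$a$samples$time_days[ct_a],
                         grid_size = config$grid_size, degree = config$degree,
                         species = pb$a$samples$species[1])
    tb <- fit_curve_grid(sb, pb$b$samples$time_days[ct_b],
                         grid_size = config$grid_size, degree = config$degree,
                         species = pb$b$samples$species[1])
    list(ref = ta, query = tb)
  })

  say("[align] %s-mode DTW (%s distance)", config$dtw_mode, config$distance)
  path <- with_stage("align", dtw_align(
    trajectories$ref, trajectories$query,
    mode = config$dtw_mode, distance = config$distance))
  emit("alignment_path.tsv", function(f)
    readr::write_tsv(path$steps, f, progress = FALSE))

  corr <- with_stage("align", stage_correspondence(
    path, trajectories$ref, trajectories$query))
  emit("stage_correspondence.tsv", function(f) write_stage_correspondence(corr, f))
  emit("curves_long.tsv", function(f)
    readr::write_tsv(dplyr::bind_rows(tidy(trajectories$ref),
                                      tidy(trajectories$query)),
                     f, progress = FALSE))

  log <- list(
    package = "cardalign",
    version = as.character(utils::packageVersion("cardalign")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    cell_type = cell_type,
    config = unclass(config),
    n_cells = c(ref = nrow(r$cells), query = nrow(q$cells)),
    n_orthologs = nrow(pb$map),
    n_ddgs = length(ddgs$genes),
    n_aligned_genes = length(trajectories$ref$gene_ids),
    total_cost = path$total_cost)
  emit("run.yaml", function(f) yaml::write_yaml(log, f))

  say("[done] %d DDGs aligned; total path cost %.3f", log$n_aligned_genes,
      path$total_cost)
  list(pseudobulk = pb, ddgs = ddgs, trajectories = trajectories,
       path = path, correspondence = corr, qc = list(ref = r$qc, query = q$qc),
       log = log)
}

#' Write a simulated bundle to disk
#'
#' Emits, per species, an MTX expression bundle and a cell-table TSV, plus
#' the ortholog map, and the ground truth as a YAML header with TSV tables
#' — the same formats [read_expression_matrix()] and [read_cell_table()]
#' consume.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written paths.
#' @export
simulate_to_files <- function(cfg, dir) {
  sim <- simulate_species_pair(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list()
  for (side in c("ref", "query")) {
    stem <- file.path(dir, side)
    write_expression_matrix(sim[[side]]$matrix, stem, format = "mtx")
    readr::write_tsv(sim[[side]]$cells, paste0(stem, "_cells.tsv"), progress = FALSE)
    paths[[paste0(side, "_mtx")]] <- paste0(stem, ".mtx")
    paths[[paste0(side, "_cells")]] <- paste0(stem, "_cells.tsv")
  }
  readr::write_tsv(sim$orthologs, file.path(dir, "orthologs.tsv"), progress = FALSE)
  paths$orthologs <- file.path(dir, "orthologs.tsv")

  truth <- sim$truth
  yaml::write_yaml(list(
    warp = as.list(truth$warp), u_center = truth$u_center, u_half = truth$u_half,
    species = cfg$species, seed = cfg$seed,
    n_genes = cfg$n_genes, frac_ddg = cfg$frac_ddg,
    cell_types = cfg$cell_types), file.path(dir, "truth.yaml"))
  readr::write_tsv(tibble::tibble(
    gene_id = truth$gene_ids_ref,
    gene_id_query = truth$gene_ids_query,
    baseline = truth$baseline,
    c1 = truth$coefficients[, 1], c2 = truth$coefficients[, 2],
    c3 = truth$coefficients[, 3],
    is_ddg = rowSums(truth$ddg_flags) > 0),
    file.path(dir, "truth_genes.tsv"), progress = FALSE)
  paths$truth <- file.path(dir, "truth.yaml")

  inform(sprintf("Simulated %d genes (%d dynamic) x %d + %d cells; warp tau_ref = %.2f + %.2f * tau_query",
                 cfg$n_genes, sum(rowSums(truth$ddg_flags) > 0),
                 ncol(sim$ref$matrix$values), ncol(sim$query$matrix$values),
                 truth$warp["a"], truth$warp["b"]))
  invisible(paths)
}
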