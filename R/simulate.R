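## Two-species synthetic single-cell time courses with known dynamic genes
## and a known monotone inter-species time warp.

#' Simulation configuration
#'
#' Defines a two-species single-cell developmental time course. The
#' reference species is sampled at human-like stages (days 35-119, i.e.
#' gestational weeks 5-17) and the query species at mouse-like stages
#' (E9.5-E13.5). Underlying log2 expression programs of dynamic genes are
#' cubic in tau = log2(days) on the reference axis; the query species
#' expresses the same programs through a monotone affine time warp
#' `tau_ref = a + b * tau_query` (b > 0). Flat genes are constant. Per-cell
#' expression adds Gaussian noise of `noise_sd` (log2 units) to the gene
#' program, and counts are drawn per cell from `count_model` around
#' 2^mu scaled to `library_size`, then converted to TPM (all genes have
#' unit effective length, so TPM is counts per million).
#'
#' `cells_per_stage` defaults to 200, matching the order of cells per stage
#' and cell type that single-cell embryonic heart atlases provide after
#' lineage subsetting.
#'
#' @param n_genes number of genes (default 1000).
#' @param frac_ddg fraction of genes that are developmentally dynamic
#'   (default 0.3).
#' @param stages_ref reference stage times in days.
#' @param stages_query query stage times in days.
#' @param cells_per_stage cells per (stage, cell type) (default 200).
#' @param warp `c(a, b)` of the affine warp in tau, `b > 0`.
#' @param cell_types character vector of simulated cell types.
#' @param ddg_overlap fraction of dynamic genes shared between cell types.
#' @param noise_sd per-cell SD of the log2 expression program (default 0.2).
#' @param count_model `"poisson"` or `"negbin"`.
#' @param dispersion negative-binomial dispersion (1/size), used when
#'   `count_model = "negbin"`.
#' @param library_size expected total counts per cell (default 20000).
#' @param baseline_range uniform range of flat log2 baselines.
#' @param amplitude_range uniform range of dynamic-gene amplitudes (max -
#'   min of the cubic over the reference span, log2 units; minimum 0.8).
#' @param species names of the two species, reference first.
#' @param seed integer seed making the simulation fully reproducible.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000L, frac_ddg = 0.3,
                       stages_ref = c(35, 42, 49, 63, 70, 91, 105, 119),
                       stages_query = c(9.5, 10.5, 11.5, 12.5, 13.5),
                       cells_per_stage = 200L,
                       warp = c(a = 0.8, b = 1.4),
                       cell_types = "CMs-A", ddg_overlap = 1,
                       noise_sd = 0.2,
                       count_model = c("poisson", "negbin"), dispersion = 0.1,
                       library_size = 20000,
                       baseline_range = c(2, 6),
                       amplitude_range = c(0.8, 1.6),
                       species = c("human", "mouse"),
                       seed = 1L) {
  count_model <- match.arg(count_model)
  cfg <- list(n_genes = as.integer(n_genes), frac_ddg = frac_ddg,
              stages_ref = stages_ref, stages_query = stages_query,
              cells_per_stage = as.integer(cells_per_stage),
              warp = c(a = unname(warp[1]), b = unname(warp[2])),
              cell_types = cell_types, ddg_overlap = ddg_overlap,
              noise_sd = noise_sd, count_model = count_model,
              dispersion = dispersion, library_size = library_size,
              baseline_range = baseline_range,
              amplitude_range = amplitude_range,
              species = species, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 10L) {
    stop_cardalign("n_genes must be at least 10.", "cardalign_config_error")
  }
  if (cfg$frac_ddg < 0 || cfg$frac_ddg >= 1) {
    stop_cardalign("frac_ddg must lie in [0, 1).", "cardalign_config_error")
  }
  if (cfg$warp["b"] <= 0) {
    stop_cardalign("Warp slope b must be positive (monotone warp).",
                   "cardalign_config_error")
  }
  if (any(cfg$stages_ref <= 0) || any(cfg$stages_query <= 0)) {
    stop_cardalign("Stage times must be positive days.", "cardalign_config_error")
  }
  if (cfg$cells_per_stage < 1L || cfg$library_size <= 0 ||
      cfg$noise_sd < 0 || cfg$dispersion <= 0) {
    stop_cardalign("Count parameters must be positive.", "cardalign_config_error")
  }
  image <- cfg$warp["a"] + cfg$warp["b"] * range(log2(cfg$stages_query))
  ref_span <- range(log2(cfg$stages_ref))
  if (image[2] < ref_span[1] || image[1] > ref_span[2]) {
    stop_cardalign(sprintf(
      "Warp image [%.2f, %.2f] of the query tau range is disjoint from the reference span [%.2f, %.2f].",
      image[1], image[2], ref_span[1], ref_span[2]), "cardalign_config_error")
  }
  invisible(cfg)
}

## Evaluate the cubic programs of dynamic genes at reference-axis tau.
## Coefficients live on u = (tau - mid) / half, the reference span mapped
## to [-1, 1], which keeps the polynomial well conditioned.
eval_programs <- function(truth, tau_ref) {
  u <- (tau_ref - truth$u_center) / truth$u_half
  co <- truth$coefficients        # genes x 3 (c1, c2, c3), zero rows for flat genes
  co[, 1] %o% u + co[, 2] %o% u^2 + co[, 3] %o% u^3
}

simulate_cells_one_species <- function(cfg, truth, species, stages, tau_on_ref_axis,
                                       id_prefix, gene_names) {
  n_genes <- cfg$n_genes
  n_stage <- length(stages)
  mats <- vector("list", length(cfg$cell_types) * n_stage)
  cells <- vector("list", length(mats))
  idx <- 0L
  for (ct_i in seq_along(cfg$cell_types)) {
    ct <- cfg$cell_types[ct_i]
    ddg_flag <- truth$ddg_flags[, ct_i]
    for (s in seq_len(n_stage)) {
      idx <- idx + 1L
      mu0 <- truth$baseline +
        ddg_flag * eval_programs(truth, tau_on_ref_axis[s])[, 1]
      nc <- cfg$cells_per_stage
      mu <- matrix(mu0, n_genes, nc) +
        matrix(rnorm(n_genes * nc, sd = cfg$noise_sd), n_genes, nc)
      w <- 2^mu
      lambda <- sweep(w, 2L, colSums(w), "/") * cfg$library_size
      counts <- if (cfg$count_model == "poisson") {
        matrix(rpois(length(lambda), lambda), n_genes, nc)
      } else {
        matrix(rnbinom(length(lambda), mu = lambda, size = 1 / cfg$dispersion),
               n_genes, nc)
      }
      totals <- colSums(counts)
      totals[totals == 0] <- 1
      tpm <- sweep(counts, 2L, totals, "/") * 1e6
      cid <- sprintf("%s_%s_s%02d_c%03d", id_prefix, gsub("[^A-Za-z0-9]", "", ct),
                     s, seq_len(nc))
      colnames(tpm) <- cid
      rownames(tpm) <- gene_names
      mats[[idx]] <- tpm
      cells[[idx]] <- tibble::tibble(
        cell_id = cid, species = species, time_days = stages[s],
        cell_type = ct, dataset = "synthetic")
    }
  }
  list(matrix = expression_matrix(do.call(cbind, mats), scale = "tpm"),
       cells = dplyr::bind_rows(cells))
}

#' Simulate a two-species single-cell developmental dataset
#'
#' Generates, fully reproducibly from `cfg$seed`, single-cell TPM matrices
#' and cell tables for a reference and a query species whose dynamic-gene
#' programs are identical up to the configured monotone time warp, plus the
#' ground truth needed to score dynamic-gene detection and stage-alignment
#' recovery.
#'
#' @param cfg a [sim_config()].
#' @return list with `ref` and `query` (each: `matrix`, `cells`),
#'   `orthologs` (two-column tibble) and `truth` (a `sim_truth`).
#' @export
#' @examples
#' sim <- simulate_species_pair(sim_config(n_genes = 50, cells_per_stage = 5))
#' sim$ref$matrix
simulate_species_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  withr::with_seed(cfg$seed, {
    n <- cfg$n_genes
    n_ddg <- round(cfg$frac_ddg * n)
    gene_ref <- sprintf("GENE%04d", seq_len(n))
    gene_query <- sprintf("Gene%04d", seq_len(n))

    tau_ref_span <- range(log2(cfg$stages_ref))
    u_center <- mean(tau_ref_span)
    u_half <- diff(tau_ref_span) / 2

    ## dynamic genes per cell type: first type takes genes 1..n_ddg; further
    ## types share a ddg_overlap fraction and draw the rest from the pool
    ddg_flags <- matrix(FALSE, n, length(cfg$cell_types))
    if (n_ddg > 0L) {
      ddg_flags[seq_len(n_ddg), 1L] <- TRUE
      if (length(cfg$cell_types) > 1L) {
        for (k in 2:length(cfg$cell_types)) {
          n_shared <- round(cfg$ddg_overlap * n_ddg)
          shared <- seq_len(n_shared)
          pool <- setdiff(seq_len(n), shared)
          own <- sample(pool, n_ddg - n_shared)
          ddg_flags[c(shared, own), k] <- TRUE
        }
      }
    }
    any_ddg <- rowSums(ddg_flags) > 0

    baseline <- runif(n, cfg$baseline_range[1], cfg$baseline_range[2])
    co <- matrix(0, n, 3L, dimnames = list(gene_ref, c("c1", "c2", "c3")))
    if (any(any_ddg)) {
      idx <- which(any_ddg)
      raw <- matrix(runif(3L * length(idx), -1.5, 1.5), length(idx), 3L)
      # rescale each program so its amplitude (max - min over the reference
      # span) is a draw from amplitude_range
      u_fine <- seq(-1, 1, length.out = 201L)
      vals <- raw[, 1] %o% u_fine + raw[, 2] %o% u_fine^2 + raw[, 3] %o% u_fine^3
      amp <- apply(vals, 1L, function(v) diff(range(v)))
      amp[amp < 1e-6] <- 1e-6
      target <- runif(length(idx), cfg$amplitude_range[1], cfg$amplitude_range[2])
      co[idx, ] <- raw * (target / amp)
    }

    truth <- structure(list(
      ddg_flags = ddg_flags, baseline = baseline, coefficients = co,
      u_center = u_center, u_half = u_half,
      warp = cfg$warp, gene_ids_ref = gene_ref, gene_ids_query = gene_query,
      config = cfg
    ), class = "sim_truth")

    tau_ref_stages <- log2(cfg$stages_ref)
    tau_query_on_ref <- cfg$warp["a"] + cfg$warp["b"] * log2(cfg$stages_query)

    ref <- simulate_cells_one_species(cfg, truth, cfg$species[1],
                                      cfg$stages_ref, tau_ref_stages,
                                      "R", gene_ref)
    query <- simulate_cells_one_species(cfg, truth, cfg$species[2],
                                        cfg$stages_query, tau_query_on_ref,
                                        "Q", gene_query)
    list(ref = ref, query = query,
         orthologs = tibble::tibble(gene_a = gene_ref, gene_b = gene_query),
         truth = truth)
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d genes (%d dynamic), warp tau_ref = %.2f + %.2f * tau_query\n",
              length(x$baseline), sum(rowSums(x$ddg_flags) > 0),
              x$warp["a"], x$warp["b"]))
  invisible(x)
}

#' True mean expression program of the query species
#'
#' The query species' per-stage true mean log2 profile equals the reference
#' cubic evaluated at the warped tau. Exposed so tests can check the
#' generator analytically.
#'
#' @param truth a `sim_truth`.
#' @param stage_days stage times of the query species in days.
#' @return genes-by-stages matrix of mean log2 expression.
#' @export
true_query_means <- function(truth, stage_days) {
  tau <- truth$warp["a"] + truth$warp["b"] * log2(stage_days)
  progs <- eval_programs(truth, tau)
  ddg <- rowSums(truth$ddg_flags) > 0
  out <- truth$baseline + progs * ddg
  rownames(out) <- truth$gene_ids_ref
  out
}

#' Score recovered stage correspondences against the simulated warp
#'
#' For each query stage, the error is the distance in tau between the
#' midpoint of the recovered reference interval and the true warp image
#' `a + b * log2(stage days)`.
#'
#' @param correspondence a `stage_correspondence` computed from data
#'   generated with `truth`.
#' @param truth a `sim_truth`.
#' @return tibble with one row per stage (`query_days`, `true_ref_tau`,
#'   `est_ref_tau`, `abs_error_tau`) and attributes `mean_error` /
#'   `max_error`.
#' @export
truth_eval <- function(correspondence, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!all(c("query_days", "ref_tau_lo", "ref_tau_hi") %in% names(correspondence))) {
    stop_cardalign("`correspondence` is not a stage correspondence table.",
                   "cardalign_argument_error")
  }
  if (!all(correspondence$query_days %in% truth$config$stages_query)) {
    stop_cardalign("Correspondence stages do not match the simulated query stages.",
                   "cardalign_argument_error")
  }
  out <- tibble::tibble(
    query_days = correspondence$query_days,
    true_ref_tau = unname(truth$warp["a"] + truth$warp["b"] * log2(correspondence$query_days)),
    est_ref_tau = (correspondence$ref_tau_lo + correspondence$ref_tau_hi) / 2)
  out$abs_error_tau <- abs(out$est_ref_tau - out$true_ref_tau)
  gs <- attr(correspondence, "grid_spacing")
  if (!is.null(gs)) {
    # distance in grid positions between the recovered midpoint and the
    # grid point nearest the true warp image (the estimator lives on the
    # grid; the truth is continuous)
    out$grid_steps_off <- round(out$abs_error_tau / gs)
  }
  attr(out, "mean_error") <- mean(out$abs_error_tau)
  attr(out, "max_error") <- max(out$abs_error_tau)
  attr(out, "grid_spacing") <- gs
  out
}

#' Score a detected DDG set against the simulated truth
#'
#' @param ddgs a `ddg_set` (or character vector of reference-species gene
#'   ids).
#' @param truth a `sim_truth`.
#' @param cell_type cell type scored (default: first configured type).
#' @return one-row tibble with confusion counts, `sensitivity` and
#'   `false_selection_rate` (false positives / selections) plus the
#'   false-positive rate among truly flat genes.
#' @export
ddg_eval <- function(ddgs, truth, cell_type = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  genes <- if (inherits(ddgs, "ddg_set")) ddgs$genes else ddgs
  if (length(setdiff(genes, truth$gene_ids_ref)) > 0L) {
    stop_cardalign("Selected genes are not in the simulated reference namespace.",
                   "cardalign_argument_error")
  }
  ct_i <- if (is.null(cell_type)) 1L else match(cell_type, truth$config$cell_types)
  if (is.na(ct_i)) {
    stop_cardalign("Unknown cell type for this simulation.", "cardalign_argument_error")
  }
  is_true <- truth$ddg_flags[, ct_i]
  sel <- truth$gene_ids_ref %in% genes
  tp <- sum(sel & is_true); fp <- sum(sel & !is_true)
  fn <- sum(!sel & is_true); tn <- sum(!sel & !is_true)
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    false_selection_rate = if (tp + fp > 0) fp / (tp + fp) else 0,
    false_positive_rate = if (fp + tn > 0) fp / (fp + tn) else 0)
}
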