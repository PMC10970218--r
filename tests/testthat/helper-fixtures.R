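# Small fixture builders shared across the suite. Everything is generated
# in code; no files ship with the tests.

make_expr <- function(values, scale = "tpm",
                      genes = sprintf("g%d", seq_len(nrow(values))),
                      cells = sprintf("c%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, cells)
  expression_matrix(values, scale)
}

random_expr <- function(n_genes, n_cells, seed = 1, scale = "tpm", max = 100) {
  withr::with_seed(seed, {
    make_expr(matrix(runif(n_genes * n_cells, 0, max), n_genes, n_cells),
              scale = scale)
  })
}

make_cells <- function(m, species = "human", time_days = 35,
                       cell_type = "CMs-A") {
  n <- ncol(m$values)
  tibble::tibble(
    cell_id = cell_ids(m),
    species = rep_len(species, n),
    time_days = rep_len(time_days, n),
    cell_type = rep_len(cell_type, n))
}

# Minimal fitted_trajectory for tests that exercise the alignment geometry
# without the curve-fitting preamble.
make_trajectory <- function(curves, grid_tau, species = "x",
                            stage_times = 2^range(grid_tau)) {
  if (is.null(rownames(curves))) {
    rownames(curves) <- sprintf("g%d", seq_len(nrow(curves)))
  }
  structure(list(species = species, grid_tau = grid_tau, curves = curves,
                 gene_ids = rownames(curves),
                 stage_times_days = stage_times, degree = 3L),
            class = "fitted_trajectory")
}

# Exact hypergeometric upper-tail by exhaustive enumeration over all
# C(N, n) draws; independent of phyper().
enum_overlap_tail <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)       # set_a is the first K elements
  mean(hits >= k)
}

run_benchmark <- function(seed = 1, ...) {
  cfg <- sim_config(seed = seed, ...)
  sim <- simulate_species_pair(cfg)
  res <- run_pipeline(log_transform(sim$ref$matrix), sim$ref$cells,
                      log_transform(sim$query$matrix), sim$query$cells,
                      sim$orthologs, cell_type = cfg$cell_types[1],
                      verbose = FALSE)
  list(cfg = cfg, sim = sim, res = res)
}
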