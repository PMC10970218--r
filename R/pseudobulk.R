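## Pseudo-bulk construction, ortholog joining, normalization and sample QC.

#' Aggregate single cells into pseudo-bulk samples
#'
#' Cells sharing the grouping fields (by default species, cell type and
#' stage) are averaged on the log2(TPM + 1) scale; the group mean is then
#' added to 1, multiplied by 10,000 and rounded (half away from zero) to an
#' integer. Aggregating a single-cell group is therefore exactly
#' `round((v + 1) * 10000)` per gene, and all values are >= 10,000.
#'
#' The alternative averaging convention — de-log, average TPM, re-log —
#' is available via `mean_space = "linear"`.
#'
#' @param m an `expr_mat` on the `"log2p1"` scale.
#' @param cells cell metadata annotating every matrix cell.
#' @param group_cols metadata columns defining a pseudo-bulk sample.
#' @param mean_space `"log"` (default: average log2 values) or `"linear"`
#'   (average TPM, then re-log before the integerization).
#' @return a `pseudobulk` object: integer genes-by-samples `values` plus a
#'   `samples` tibble (sample_id, grouping fields, n_cells).
#' @export
#' @examples
#' m <- expression_matrix(matrix(c(1, 0, 3, 0), 2,
#'   dimnames = list(c("g1", "g2"), c("c1", "c2"))), scale = "log2p1")
#' cells <- tibble::tibble(cell_id = c("c1", "c2"), species = "human",
#'   time_days = 35, cell_type = "CMs-A")
#' aggregate_pseudobulk(m, cells)$values
aggregate_pseudobulk <- function(m, cells,
                                 group_cols = c("species", "cell_type", "time_days"),
                                 mean_space = c("log", "linear")) {
  stopifnot(inherits(m, "expr_mat"))
  mean_space <- match.arg(mean_space)
  if (m$scale != "log2p1") {
    stop_cardalign(
      "Pseudo-bulk aggregation expects log2(TPM + 1) values; run log_transform() first.",
      "cardalign_scale_error")
  }
  cells <- cell_table(cells)
  check_cells_annotated(m, cells)
  missing_cols <- setdiff(group_cols, names(cells))
  if (length(missing_cols) > 0L) {
    stop_cardalign(paste0("Grouping field(s) absent from cell table: ",
                          paste(missing_cols, collapse = ", ")),
                   "cardalign_schema_error")
  }
  cells <- cells[match(cell_ids(m), cells$cell_id), , drop = FALSE]
  key <- do.call(paste, c(lapply(group_cols, function(cl) cells[[cl]]), sep = "\r"))
  groups <- split(seq_along(key), factor(key, levels = unique(key)))

  vals <- vapply(groups, function(idx) {
    sub <- m$values[, idx, drop = FALSE]
    mu <- if (mean_space == "log") {
      rowMeans(sub)
    } else {
      log2(rowMeans(2^sub - 1) + 1)
    }
    round_half_up((mu + 1) * 10000)
  }, numeric(nrow(m$values)))
  vals <- matrix(vals, nrow = nrow(m$values),
                 dimnames = list(gene_ids(m), NULL))

  first_idx <- vapply(groups, `[[`, integer(1), 1L)
  samples <- cells[first_idx, group_cols, drop = FALSE]
  samples$n_cells <- unname(vapply(groups, length, integer(1)))
  samples$sample_id <- do.call(paste, c(lapply(group_cols, function(cl) samples[[cl]]),
                                        sep = "."))
  samples <- dplyr::relocate(samples, "sample_id")
  colnames(vals) <- samples$sample_id

  structure(list(values = vals, samples = tibble::as_tibble(samples)),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("<pseudobulk> %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$species), collapse = ", ")))
  invisible(x)
}

#' @export
dim.pseudobulk <- function(x) dim(x$values)

#' @export
tidy.pseudobulk <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id", values_to = "value") |>
    dplyr::left_join(x$samples, by = "sample_id")
}

subset_pseudobulk <- function(p, sample_idx = NULL, genes = NULL) {
  if (!is.null(sample_idx)) {
    p$values <- p$values[, sample_idx, drop = FALSE]
    p$samples <- p$samples[sample_idx, , drop = FALSE]
  }
  if (!is.null(genes)) {
    p$values <- p$values[genes, , drop = FALSE]
  }
  p
}

#' Read and validate a two-column 1:1 ortholog map
#'
#' @param path TSV with two columns: gene id in species A, gene id in
#'   species B.
#' @return a two-column tibble.
#' @export
read_ortholog_map <- function(path) {
  map <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(map) < 2L) {
    stop_cardalign("Ortholog map needs two columns.", "cardalign_schema_error")
  }
  map[, 1:2]
}

#' Join two pseudo-bulk matrices on 1:1 orthologs
#'
#' Restricts both matrices to ortholog pairs present in each, in identical
#' (paired) row order: row i of the first output corresponds to row i of
#' the second under the map. A gene appearing more than once on either side
#' of the map violates the 1:1 assumption and is an error.
#'
#' @param a,b `pseudobulk` objects for the two species.
#' @param map data frame whose first column holds gene ids of `a`, second of
#'   `b`.
#' @return list with the restricted `a`, `b` and the retained `map`.
#' @export
join_orthologs <- function(a, b, map) {
  stopifnot(inherits(a, "pseudobulk"), inherits(b, "pseudobulk"))
  map <- tibble::as_tibble(map)[, 1:2]
  names(map) <- c("gene_a", "gene_b")
  for (side in c("gene_a", "gene_b")) {
    dup <- unique(map[[side]][duplicated(map[[side]])])
    if (length(dup) > 0L) {
      stop_cardalign(paste0("Ortholog map is not 1:1; duplicated on ", side, ": ",
                            paste(head(dup, 5), collapse = ", ")),
                     "cardalign_integrity_error")
    }
  }
  keep <- map$gene_a %in% rownames(a$values) & map$gene_b %in% rownames(b$values)
  map <- map[keep, , drop = FALSE]
  list(a = subset_pseudobulk(a, genes = map$gene_a),
       b = subset_pseudobulk(b, genes = map$gene_b),
       map = map)
}

#' Variance-stabilizing normalization of pseudo-bulk counts
#'
#' Median-of-ratios size factors (as used for sequencing count data):
#' per sample, the size factor is the median over genes of
#' count / geometric-mean-across-samples of that gene, computed over genes
#' with no zero count; the output is log2(count / size_factor + 1). This is
#' a fully specified variance-stabilizing transform for PCA input; it does
#' not reproduce dispersion-based VST implementations bit-exactly.
#'
#' @param p a `pseudobulk` object or a positive genes-by-samples matrix.
#' @return normalized real matrix with a `size_factors` attribute.
#' @export
vst_normalize <- function(p) {
  counts <- if (inherits(p, "pseudobulk")) p$values else p
  if (!is.matrix(counts)) {
    stop_cardalign("`p` must be a pseudobulk object or a matrix.",
                   "cardalign_argument_error")
  }
  if (ncol(counts) < 2L) {
    stop_cardalign("Size factors are undefined for a single sample.",
                   "cardalign_argument_error")
  }
  usable <- rowSums(counts <= 0) == 0L
  if (!any(usable)) {
    stop_cardalign("No gene is positive in every sample; cannot compute size factors.",
                   "cardalign_argument_error")
  }
  log_geo <- rowMeans(log(counts[usable, , drop = FALSE]))
  sf <- apply(counts[usable, , drop = FALSE], 2L,
              function(cnt) median(cnt / exp(log_geo)))
  out <- log2(sweep(counts, 2L, sf, "/") + 1)
  attr(out, "size_factors") <- sf
  out
}

#' Principal component analysis of pseudo-bulk samples
#'
#' Genes are centered before the decomposition; samples are the
#' observations. Variance fractions are non-increasing and sum to at most 1.
#'
#' @param x real genes-by-samples matrix (e.g. [vst_normalize()] output).
#' @param n_components number of components to retain.
#' @return a `pb_pca` object with `scores` (samples x components tibble),
#'   `loadings` and `var_explained`.
#' @export
pseudobulk_pca <- function(x, n_components = 3L) {
  if (inherits(x, "pseudobulk")) x <- vst_normalize(x)
  if (!is.matrix(x) || ncol(x) < 2L) {
    stop_cardalign("PCA needs a matrix with at least 2 samples.",
                   "cardalign_argument_error")
  }
  max_k <- min(nrow(x), ncol(x) - 1L)
  if (n_components > max_k) {
    stop_cardalign(sprintf("n_components = %d exceeds min(genes, samples - 1) = %d.",
                           n_components, max_k), "cardalign_argument_error")
  }
  pr <- prcomp(t(x), center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  var_frac <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(
    scores = tibble::as_tibble(pr$x[, k, drop = FALSE], rownames = "sample_id"),
    loadings = pr$rotation[, k, drop = FALSE],
    var_explained = var_frac[k],
    prcomp = pr
  ), class = "pb_pca")
}

#' @export
print.pb_pca <- function(x, ...) {
  cat(sprintf("<pb_pca> %d components; variance explained: %s\n",
              length(x$var_explained),
              paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.pb_pca <- function(x, ...) x$scores

#' @export
glance.pb_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$var_explained),
                 var_explained = x$var_explained)
}

#' @export
autoplot.pb_pca <- function(object, mapping = NULL, ...) {
  df <- object$scores
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(...) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
}

#' Flag outlier pseudo-bulk samples by correlation
#'
#' Samples are clustered hierarchically (average linkage) on
#' 1 - Pearson correlation; a sample is flagged when its mean correlation to
#' all other samples falls more than `k` MADs below the cohort median (with
#' a small absolute floor so that numerically identical cohorts are never
#' flagged). Constant samples, whose correlation is undefined, are flagged
#' with reason `"zero variance"`. Flags are advisory: removal is left to the
#' caller.
#'
#' @param x real genes-by-samples matrix.
#' @param k MAD multiplier (default 3).
#' @param min_drop absolute minimum drop in mean correlation required to
#'   flag (default 0.01); guards against flagging within numerical jitter.
#' @return an `outlier_flags` object: `hclust` tree, `mean_cor`, and a
#'   `flagged` tibble (sample_id, mean_cor, reason).
#' @export
flag_outliers <- function(x, k = 3, min_drop = 0.01) {
  if (inherits(x, "pseudobulk")) x <- vst_normalize(x)
  if (!is.matrix(x) || ncol(x) < 3L) {
    stop_cardalign("Outlier flagging needs at least 3 samples.",
                   "cardalign_argument_error")
  }
  ids <- colnames(x) %||% paste0("S", seq_len(ncol(x)))
  colnames(x) <- ids
  sds <- apply(x, 2L, sd)
  constant <- sds == 0
  flagged <- tibble::tibble(sample_id = ids[constant],
                            mean_cor = NA_real_,
                            reason = rep("zero variance", sum(constant)))
  ok <- !constant
  hc <- NULL
  if (sum(ok) >= 2L) {
    cm <- cor(x[, ok, drop = FALSE])
    d <- as.dist(1 - cm)
    if (sum(ok) >= 3L) hc <- hclust(d, method = "average")
    mean_cor <- (rowSums(cm) - 1) / (sum(ok) - 1)
    med <- median(mean_cor)
    cut <- med - pmax(k * mad(mean_cor), min_drop)
    low <- mean_cor < cut
    flagged <- dplyr::bind_rows(flagged, tibble::tibble(
      sample_id = names(mean_cor)[low],
      mean_cor = unname(mean_cor[low]),
      reason = rep("low mean correlation", sum(low))))
  } else {
    mean_cor <- stats::setNames(numeric(0), character(0))
  }
  structure(list(hclust = hc, mean_cor = mean_cor, flagged = flagged,
                 k = k, min_drop = min_drop),
            class = "outlier_flags")
}

#' @export
print.outlier_flags <- function(x, ...) {
  cat(sprintf("<outlier_flags> %d flagged sample(s)\n", nrow(x$flagged)))
  if (nrow(x$flagged) > 0L) print(x$flagged)
  invisible(x)
}

#' @export
tidy.outlier_flags <- function(x, ...) x$flagged

#' Write a pseudo-bulk matrix and sample sheet to TSV
#'
#' @param p a `pseudobulk` object.
#' @param values_path TSV path for the genes-by-samples matrix.
#' @param samples_path TSV path for the sample sheet.
#' @return invisibly, the two paths.
#' @export
write_pseudobulk <- function(p, values_path, samples_path) {
  df <- data.frame(gene_id = rownames(p$values), p$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, values_path, sep = "\t", quote = FALSE, row.names = FALSE)
  readr::write_tsv(p$samples, samples_path, progress = FALSE)
  invisible(c(values_path, samples_path))
}
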