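## Reading, transforming and filtering single-cell expression matrices.

EXPR_SCALES <- c("tpm", "log2p1", "counts")

#' Construct an expression matrix
#'
#' A light container for a genes-by-cells expression matrix together with a
#' scale flag recording whether values are TPM, log2(TPM + 1) or raw counts.
#' Row names are gene identifiers, column names are cell identifiers; both
#' must be unique and values must be non-negative.
#'
#' @param values numeric matrix (genes x cells) with unique dimnames.
#' @param scale one of `"tpm"`, `"log2p1"`, `"counts"`.
#' @return an object of class `expr_mat`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(c(0, 1, 2, 3), 2,
#'   dimnames = list(c("g1", "g2"), c("c1", "c2"))))
#' m
expression_matrix <- function(values, scale = c("tpm", "log2p1", "counts")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_cardalign("`values` must be a numeric matrix.", "cardalign_argument_error")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_cardalign("`values` must carry gene (row) and cell (column) names.",
                   "cardalign_argument_error")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop_cardalign(
      paste0("Duplicate gene ids: ", paste(head(dup, 5), collapse = ", ")),
      "cardalign_integrity_error")
  }
  if (anyDuplicated(colnames(values))) {
    stop_cardalign("Duplicate cell ids in expression matrix.",
                   "cardalign_integrity_error")
  }
  if (any(values < 0)) {
    stop_cardalign("Expression values must be non-negative.",
                   "cardalign_integrity_error")
  }
  structure(list(values = values, scale = scale), class = "expr_mat")
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d genes x %d cells, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Gene and cell identifiers of an expression matrix
#' @param m an `expr_mat`.
#' @return character vector of ids.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname gene_ids
#' @export
cell_ids <- function(m) colnames(m$values)

#' @export
tidy.expr_mat <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "cell_id", values_to = "value") |>
    dplyr::mutate(scale = x$scale)
}

## Readers -----------------------------------------------------------------

sniff_delim <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

read_dense_matrix <- function(path, scale) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) {
    stop_cardalign(paste0("Empty expression file: ", path), "cardalign_parse_error")
  }
  sep <- sniff_delim(header)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  gids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    stop_cardalign(paste0("Non-numeric expression values in ", path),
                   "cardalign_parse_error")
  }
  rownames(vals) <- gids
  expression_matrix(vals, scale)
}

read_mtx_matrix <- function(path, scale, genes_file, cells_file) {
  genes_file <- genes_file %||% sub("\\.mtx$", ".genes.txt", path)
  cells_file <- cells_file %||% sub("\\.mtx$", ".cells.txt", path)
  for (f in c(path, genes_file, cells_file)) {
    if (!file.exists(f)) {
      stop_cardalign(paste0("Missing file: ", f), "cardalign_parse_error")
    }
  }
  lines <- readLines(path)
  body <- which(!startsWith(lines, "%"))
  if (length(body) < 1L) {
    stop_cardalign(paste0("No data lines in ", path), "cardalign_parse_error")
  }
  # validate triplet lines so malformed input is reported with its line number
  for (k in body[-1L]) {
    toks <- strsplit(trimws(lines[k]), "[ \t]+")[[1]]
    if (length(toks) != 3L || anyNA(suppressWarnings(as.numeric(toks)))) {
      stop_cardalign(sprintf("Malformed MatrixMarket triplet at line %d of %s", k, path),
                     "cardalign_parse_error")
    }
  }
  m <- tryCatch(
    Matrix::readMM(path),
    error = function(e) {
      stop_cardalign(paste0("Failed to parse ", path, ": ", conditionMessage(e)),
                     "cardalign_parse_error")
    })
  genes <- readLines(genes_file)
  cells <- readLines(cells_file)
  if (length(genes) != nrow(m)) {
    stop_cardalign(sprintf(
      "Gene sidecar %s has %d entries but matrix declares %d rows.",
      genes_file, length(genes), nrow(m)), "cardalign_parse_error")
  }
  if (length(cells) != ncol(m)) {
    stop_cardalign(sprintf(
      "Cell sidecar %s has %d entries but matrix declares %d columns.",
      cells_file, length(cells), ncol(m)), "cardalign_parse_error")
  }
  vals <- as.matrix(m)
  dimnames(vals) <- list(genes, cells)
  expression_matrix(vals, scale)
}

#' Read an expression matrix from disk
#'
#' Reads either a MatrixMarket triplet file (with gene/cell sidecar lists,
#' by default `<stem>.genes.txt` / `<stem>.cells.txt`) or a dense TSV/CSV
#' whose first column holds gene ids and whose header row holds cell ids.
#' The delimiter of dense files is sniffed from the header line.
#'
#' @param path file path (`.mtx` or dense table).
#' @param format `"auto"` (by extension), `"mtx"` or `"dense"`.
#' @param scale scale flag to record on the result (default `"tpm"`).
#' @param genes_file,cells_file optional sidecar paths for MTX input.
#' @return an [expression_matrix()] object.
#' @export
read_expression_matrix <- function(path, format = c("auto", "mtx", "dense"),
                                   scale = "tpm",
                                   genes_file = NULL, cells_file = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "dense"
  }
  switch(format,
    mtx = read_mtx_matrix(path, scale, genes_file, cells_file),
    dense = read_dense_matrix(path, scale))
}

#' Write an expression matrix to disk
#'
#' The MTX form writes `<stem>.mtx` plus `<stem>.genes.txt` and
#' `<stem>.cells.txt`; the dense form writes a single TSV with a `gene_id`
#' first column. Both round-trip through [read_expression_matrix()].
#'
#' @param m an `expr_mat`.
#' @param stem output path stem (MTX) or file path (dense).
#' @param format `"mtx"` or `"dense"`.
#' @return the main file path, invisibly.
#' @export
write_expression_matrix <- function(m, stem, format = c("mtx", "dense")) {
  format <- match.arg(format)
  if (format == "mtx") {
    path <- paste0(stem, ".mtx")
    Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE), path)
    writeLines(rownames(m$values), paste0(stem, ".genes.txt"))
    writeLines(colnames(m$values), paste0(stem, ".cells.txt"))
  } else {
    path <- stem
    df <- data.frame(gene_id = rownames(m$values), m$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

## Cell metadata -----------------------------------------------------------

CELL_TABLE_REQUIRED <- c("cell_id", "species", "time_days", "cell_type")

#' Validate a cell metadata table
#'
#' Cell metadata carries, per cell: id, species, gestational time in days
#' (human weeks are converted upstream as weeks x 7; mouse E-days are taken
#' as-is), cell type and optional chamber/dataset tags.
#'
#' @param cells data frame with at least columns `cell_id`, `species`,
#'   `time_days`, `cell_type`.
#' @return the table as a tibble, invisibly checked.
#' @export
cell_table <- function(cells) {
  cells <- tibble::as_tibble(cells)
  missing <- setdiff(CELL_TABLE_REQUIRED, names(cells))
  if (length(missing) > 0L) {
    stop_cardalign(paste0("Cell table is missing required column(s): ",
                          paste(missing, collapse = ", ")),
                   "cardalign_schema_error")
  }
  if (anyDuplicated(cells$cell_id)) {
    stop_cardalign("Duplicate cell_id in cell table.", "cardalign_integrity_error")
  }
  if (any(!is.finite(cells$time_days)) || any(cells$time_days <= 0)) {
    stop_cardalign("time_days must be finite and > 0.", "cardalign_integrity_error")
  }
  cells
}

#' Read a cell metadata table from TSV
#'
#' @param path TSV file with columns `cell_id`, `species`, `time_days`,
#'   `cell_type` (plus optional extras such as `chamber`, `dataset`).
#' @return a tibble.
#' @export
read_cell_table <- function(path) {
  cells <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  cell_table(cells)
}

check_cells_annotated <- function(m, cells) {
  missing <- setdiff(cell_ids(m), cells$cell_id)
  if (length(missing) > 0L) {
    stop_cardalign(paste0(
      length(missing), " matrix cell(s) absent from the cell table, e.g. ",
      paste(head(missing, 3), collapse = ", ")), "cardalign_integrity_error")
  }
  invisible(TRUE)
}

## Transforms and filters --------------------------------------------------

#' Log-transform a TPM matrix
#'
#' Replaces each value v by log2(v + 1) and updates the scale flag. Applying
#' it to a matrix that is already on the log scale is an error, preventing
#' accidental double transformation.
#'
#' @param m an `expr_mat` with scale `"tpm"` (or `"counts"`).
#' @return an `expr_mat` with scale `"log2p1"`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(c(0, 1, 3, 7), 2,
#'   dimnames = list(c("g1", "g2"), c("c1", "c2"))))
#' log_transform(m)$values
log_transform <- function(m) {
  stopifnot(inherits(m, "expr_mat"))
  if (m$scale == "log2p1") {
    stop_cardalign("Matrix is already on the log2(TPM + 1) scale.",
                   "cardalign_scale_error")
  }
  m$values <- log2(m$values + 1)
  m$scale <- "log2p1"
  m
}

#' Filter cells by number of detected genes
#'
#' A cell's nFeature is the number of genes with strictly positive
#' expression in that cell; cells are retained when nFeature is strictly
#' greater than `min_features`. The study-scale defaults for real data are
#' 1000 for human cells and 600 for mouse cells.
#'
#' @param m an `expr_mat`.
#' @param min_features non-negative integer threshold (strict `>`).
#' @return a list with elements `matrix` (filtered `expr_mat`) and `report`
#'   (a `qc_report` with in/out counts and per-cell nFeature).
#' @export
qc_filter <- function(m, min_features) {
  stopifnot(inherits(m, "expr_mat"))
  if (!is.numeric(min_features) || length(min_features) != 1L || min_features < 0) {
    stop_cardalign("`min_features` must be a single non-negative number.",
                   "cardalign_argument_error")
  }
  nfeat <- colSums(m$values > 0)
  keep <- nfeat > min_features
  if (!any(keep)) {
    warn(sprintf("qc_filter removed all %d cells at nFeature > %d.",
                 ncol(m$values), as.integer(min_features)))
  }
  out <- m
  out$values <- m$values[, keep, drop = FALSE]
  report <- structure(list(
    n_cells_in = ncol(m$values),
    n_cells_out = sum(keep),
    threshold = as.integer(min_features),
    per_cell_nfeature = tibble::tibble(
      cell_id = colnames(m$values),
      n_feature = as.integer(nfeat),
      retained = unname(keep))
  ), class = "qc_report")
  list(matrix = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> nFeature > %d: kept %d of %d cells\n",
              x$threshold, x$n_cells_out, x$n_cells_in))
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) x$per_cell_nfeature

#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(n_cells_in = x$n_cells_in, n_cells_out = x$n_cells_out,
                 threshold = x$threshold)
}

#' Subset cells by metadata predicates
#'
#' Filters the cell table with dplyr-style predicates and restricts the
#' matrix to the matching cells, preserving order. An empty predicate is the
#' identity.
#'
#' @param m an `expr_mat`.
#' @param cells cell metadata table annotating (at least) the matrix cells.
#' @param ... predicates on cell table columns, e.g. `cell_type == "CMs-A"`.
#' @return list with filtered `matrix` and `cells`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(1:4, 2,
#'   dimnames = list(c("g1", "g2"), c("c1", "c2"))))
#' cells <- tibble::tibble(cell_id = c("c1", "c2"), species = "human",
#'   time_days = c(35, 42), cell_type = c("CMs-A", "ECs"))
#' subset_cells(m, cells, cell_type == "CMs-A")$cells
subset_cells <- function(m, cells, ...) {
  stopifnot(inherits(m, "expr_mat"))
  cells <- cell_table(cells)
  check_cells_annotated(m, cells)
  quos <- rlang::quos(...)
  used <- unique(unlist(lapply(quos, function(q) all.vars(rlang::quo_get_expr(q)))))
  in_env <- vapply(used, function(v) {
    any(vapply(quos, function(q) {
      env <- rlang::quo_get_env(q)
      !identical(env, rlang::empty_env()) && rlang::env_has(env, v, inherit = TRUE)
    }, logical(1)))
  }, logical(1))
  unknown <- used[!used %in% names(cells) & !in_env]
  if (length(unknown) > 0L) {
    stop_cardalign(paste0("Predicate references unknown metadata field(s): ",
                          paste(unknown, collapse = ", ")),
                   "cardalign_schema_error")
  }
  kept <- dplyr::filter(cells, !!!quos)
  keep_ids <- intersect(cell_ids(m), kept$cell_id)
  out <- m
  out$values <- m$values[, keep_ids, drop = FALSE]
  list(matrix = out,
       cells = kept[match(keep_ids, kept$cell_id), , drop = FALSE])
}
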