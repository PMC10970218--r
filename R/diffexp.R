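## Differential expression between species and chambers on pseudo-bulk
## samples: a normal-theory linear model on log2-normalized counts with
## Benjamini-Hochberg adjustment. This is a documented stand-in for
## negative-binomial count frameworks — the downstream claims rest on
## threshold mechanics and overlap statistics, not on count-model inference.

#' Differential expression on pseudo-bulk samples
#'
#' Fits, per gene, an additive linear model of log2-normalized expression
#' on the design factors and reports the coefficient of the contrast factor
#' as the log2 fold change, with a two-sided t-test p-value and BH-adjusted
#' p across genes. The full table is returned unfiltered; apply
#' [select_significant()] for the usual |log2FC| >= 0.5, adj. p <= 0.01
#' screen.
#'
#' @param p a `pseudobulk` object (normalized internally with
#'   [vst_normalize()]) or an already log-scale genes-by-samples matrix.
#' @param design data frame of per-sample factors (rows match samples).
#' @param contrast name of the design column to test; must have exactly two
#'   levels, each with at least two samples. Other columns are adjusted
#'   for additively.
#' @return a `de_results` tibble: `gene_id`, `log2_fc`, `p_value`, `adj_p`,
#'   `contrast`.
#' @export
differential_expression <- function(p, design, contrast) {
  y <- if (inherits(p, "pseudobulk")) vst_normalize(p) else p
  if (!is.matrix(y)) {
    stop_cardalign("`p` must be a pseudobulk object or a matrix.",
                   "cardalign_argument_error")
  }
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if (nrow(design) != ncol(y)) {
    stop_cardalign("Design rows must match the number of samples.",
                   "cardalign_design_error")
  }
  if (!contrast %in% names(design)) {
    stop_cardalign(paste0("Contrast factor '", contrast, "' absent from design."),
                   "cardalign_design_error")
  }
  design[] <- lapply(design, function(col) factor(as.character(col)))
  lv <- levels(design[[contrast]])
  if (length(lv) != 2L) {
    stop_cardalign("The contrast factor must have exactly two levels.",
                   "cardalign_design_error")
  }
  counts <- table(design[[contrast]])
  if (any(counts < 2L)) {
    stop_cardalign(sprintf(
      "Contrast level(s) with fewer than 2 samples: %s.",
      paste(names(counts)[counts < 2L], collapse = ", ")),
      "cardalign_design_error")
  }
  mm <- stats::model.matrix(~ ., data = design)
  coef_name <- paste0(contrast, lv[2L])
  ci <- match(coef_name, colnames(mm))
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    stop_cardalign("Design matrix is rank deficient (confounded factors).",
                   "cardalign_design_error")
  }
  n <- nrow(mm)
  df_res <- n - qr_mm$rank
  if (df_res < 1L) {
    stop_cardalign("No residual degrees of freedom in the design.",
                   "cardalign_design_error")
  }
  Y <- t(y)                                    # samples x genes
  beta <- qr.coef(qr_mm, Y)
  res <- Y - mm %*% beta
  sigma2 <- colSums(res^2) / df_res
  xtx_inv <- solve(crossprod(mm))
  se2 <- sigma2 * xtx_inv[ci, ci]
  fc <- beta[ci, ]
  tstat <- fc / sqrt(se2)
  pval <- 2 * pt(-abs(tstat), df_res)
  # degenerate genes: zero residual variance
  zero_var <- sigma2 <= .Machine$double.eps * 100
  pval[zero_var & abs(fc) <= 1e-12] <- 1
  pval[zero_var & abs(fc) > 1e-12] <- .Machine$double.xmin
  out <- tibble::tibble(
    gene_id = rownames(y),
    log2_fc = unname(fc),
    p_value = unname(pval),
    adj_p = p.adjust(unname(pval), method = "BH"),
    contrast = paste0(contrast, ":", lv[2L], "_vs_", lv[1L]))
  class(out) <- c("de_results", class(out))
  out
}

#' Select significant differentially expressed genes
#'
#' Keeps genes with |log2 fold change| >= `min_abs_log2fc` and adjusted
#' p <= `max_adj_p` (both boundaries inclusive), optionally intersected
#' with a transcription-factor list.
#'
#' @param results a [differential_expression()] table (must carry `adj_p`).
#' @param min_abs_log2fc minimum absolute log2 fold change (default 0.5).
#' @param max_adj_p maximum BH-adjusted p (default 0.01).
#' @param tf_list optional character vector of transcription-factor
#'   symbols; when given, an `is_tf` column is added and only TFs are kept.
#' @return filtered tibble (possibly empty).
#' @export
select_significant <- function(results, min_abs_log2fc = 0.5, max_adj_p = 0.01,
                               tf_list = NULL) {
  if (!all(c("gene_id", "log2_fc", "adj_p") %in% names(results))) {
    stop_cardalign("`results` must carry gene_id, log2_fc and adj_p.",
                   "cardalign_argument_error")
  }
  out <- dplyr::filter(results,
                       abs(.data$log2_fc) >= min_abs_log2fc,
                       .data$adj_p <= max_adj_p)
  if (!is.null(tf_list)) {
    out$is_tf <- out$gene_id %in% tf_list
    out <- dplyr::filter(out, .data$is_tf)
  }
  out
}

#' Read a transcription-factor list (one symbol per line)
#' @param path text file with one gene symbol per line.
#' @return character vector of unique symbols.
#' @export
read_tf_list <- function(path) unique(readLines(path))

#' @export
autoplot.de_results <- function(object, min_abs_log2fc = 0.5, max_adj_p = 0.01, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
    significant = abs(.data$log2_fc) >= min_abs_log2fc & .data$adj_p <= max_adj_p)
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_fc, -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, ...) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}
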