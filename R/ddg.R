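## Developmentally dynamic gene (DDG) detection, profile standardization,
## clustering and gene-set overlap statistics.

poly_design <- function(tau, degree) {
  X <- outer(tau, 0:degree, "^")
  colnames(X) <- paste0("tau", 0:degree)
  X
}

#' Remove per-sample median offsets
#'
#' Subtracts, per sample, the median expression across genes (optionally
#' across a subset of control genes). Pseudo-bulk values built from TPM
#' inherit a common per-stage offset from the within-cell normalization
#' (when dynamic genes rise, every other gene's TPM falls); because the
#' offset is shared by all genes it is estimated robustly by the per-sample
#' median and removed before regression, so that flat genes are not carried
#' over the significance threshold by composition alone.
#'
#' @param x genes-by-samples matrix.
#' @param control_genes optional gene ids (or logical/integer index) whose
#'   rows estimate the offset; defaults to all genes.
#' @param center `"median"` (default; robust when dynamic genes contaminate
#'   the estimate) or `"mean"` (exact removal of a shared offset once a
#'   clean control set is available).
#' @return matrix with the per-sample offsets subtracted.
#' @export
median_center_samples <- function(x, control_genes = NULL,
                                  center = c("median", "mean")) {
  center <- match.arg(center)
  rows <- if (is.null(control_genes)) x else x[control_genes, , drop = FALSE]
  offset <- if (center == "median") apply(rows, 2L, median) else colMeans(rows)
  sweep(x, 2L, offset)
}

## Vectorized OLS of many genes on powers of tau = log2(days).
## Returns one row per gene: coefficients, R^2, F-test p-value.
fit_trajectories <- function(mat, times_days, degree = 3L) {
  tau <- tau_days(times_days)
  n <- length(tau)
  if (ncol(mat) != n) {
    stop_cardalign("Number of samples does not match number of time points.",
                   "cardalign_argument_error")
  }
  if (length(unique(tau)) < degree + 2L) {
    stop_cardalign(sprintf(
      "Degree-%d fit needs at least %d distinct time points; got %d.",
      degree, degree + 2L, length(unique(tau))), "cardalign_insufficient_data_error")
  }
  X <- poly_design(tau, degree)
  qrX <- qr(X)
  Y <- t(mat)                                   # samples x genes
  beta <- qr.coef(qrX, Y)                       # (degree+1) x genes
  fitted <- X %*% beta
  res <- Y - fitted
  ss_res <- colSums(res^2)
  ss_tot <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  r2 <- ifelse(ss_tot > 0, pmax(0, pmin(1, 1 - ss_res / ss_tot)), 0)
  df1 <- degree
  df2 <- n - degree - 1L
  fstat <- (r2 / df1) / pmax((1 - r2) / df2, .Machine$double.eps)
  p <- pf(fstat, df1, df2, lower.tail = FALSE)
  p[ss_tot <= 0] <- 1                           # constant gene convention
  tibble::tibble(
    gene_id = rownames(mat),
    beta0 = beta[1L, ], beta1 = beta[2L, ],
    beta2 = beta[3L, ], beta3 = if (degree >= 3L) beta[4L, ] else NA_real_,
    r2 = unname(r2), p_value = unname(p), n_stages = length(unique(tau)))
}

#' Fit a polynomial trajectory for one gene
#'
#' Ordinary least squares of expression on powers of tau = log2(time in
#' days), degree 3 by default. R^2 is 1 - SSresid/SStotal; the p-value is
#' from the F test of the full model against the intercept with
#' (degree, n - degree - 1) degrees of freedom. A constant response is
#' assigned R^2 = 0 and p = 1 by convention.
#'
#' @param y per-sample expression values.
#' @param times_days per-sample gestational times in days (> 0).
#' @param degree polynomial degree (default 3).
#' @param gene_id optional gene identifier stored on the result.
#' @return a `trajectory_fit`: coefficients (beta0..beta_degree), `r2`,
#'   `p_value`, `n_stages`.
#' @export
#' @examples
#' t <- c(35, 42, 49, 63, 70, 91)
#' fit <- fit_polynomial_trajectory(2 + log2(t)^3, t)
#' fit$r2
fit_polynomial_trajectory <- function(y, times_days, degree = 3L, gene_id = NA_character_) {
  if (any(!is.finite(y))) {
    stop_cardalign("Expression values must be finite.", "cardalign_argument_error")
  }
  mat <- matrix(y, nrow = 1L, dimnames = list(gene_id, NULL))
  fit <- fit_trajectories(mat, times_days, degree)
  structure(list(
    gene_id = gene_id,
    coefficients = stats::setNames(
      unlist(fit[1L, paste0("beta", 0:degree)], use.names = FALSE),
      paste0("beta", 0:degree)),
    r2 = fit$r2[1L], p_value = fit$p_value[1L],
    n_stages = fit$n_stages[1L], degree = degree
  ), class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> degree %d, R^2 = %.3f, p = %.3g (%d stages)\n",
              x$degree, x$r2, x$p_value, x$n_stages))
  invisible(x)
}

#' @export
tidy.trajectory_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.trajectory_fit <- function(x, ...) {
  tibble::tibble(r2 = x$r2, p_value = x$p_value, n_stages = x$n_stages,
                 degree = x$degree)
}

#' Detect developmentally dynamic genes in two species
#'
#' For the chosen cell type, fits a cubic polynomial of pseudo-bulk
#' expression on log2 gestational days in each species, and selects genes
#' whose fit reaches `r2_min` (default 0.3) in at least one species
#' (`scope = "either"`) or in both (`scope = "both"`). A per-species
#' significance pre-filter (F-test p-values, Benjamini-Hochberg adjusted at
#' `alpha`) precedes the R^2 rule by default, mirroring the two-step model
#' selection of polynomial time-course screens: the significance step
#' controls the false selections that a scale-free R^2 threshold alone
#' cannot, and the R^2 threshold then enforces goodness of fit.
#'
#' @param a,b ortholog-joined `pseudobulk` objects (see [join_orthologs()]);
#'   rows paired.
#' @param cell_type cell type whose samples are used, e.g. `"CMs-A"`.
#' @param r2_min minimum R^2 (default 0.3).
#' @param scope `"either"` (default) or `"both"`.
#' @param degree polynomial degree (default 3).
#' @param significance_filter apply the BH-adjusted F-test pre-filter
#'   (default `TRUE`).
#' @param alpha adjusted-p cutoff for the pre-filter (default 0.05).
#' @param sample_center subtract per-sample median expression before
#'   fitting (default `TRUE`); see [median_center_samples()].
#' @return a `ddg_set`: the selected gene list (ids of `a`) plus the full
#'   per-gene fit table for both species.
#' @export
detect_ddgs <- function(a, b, cell_type, r2_min = 0.3,
                        scope = c("either", "both"), degree = 3L,
                        significance_filter = TRUE, alpha = 0.05,
                        sample_center = TRUE) {
  stopifnot(inherits(a, "pseudobulk"), inherits(b, "pseudobulk"))
  scope <- match.arg(scope)
  if (nrow(a$values) != nrow(b$values)) {
    stop_cardalign("Matrices are not ortholog-joined (gene counts differ).",
                   "cardalign_pairing_error")
  }
  take <- function(p, who) {
    idx <- which(p$samples$cell_type == cell_type)
    if (length(idx) == 0L) {
      stop_cardalign(sprintf("Cell type '%s' absent from %s matrix.", cell_type, who),
                     "cardalign_argument_error")
    }
    subset_pseudobulk(p, sample_idx = idx)
  }
  pa <- take(a, "first")
  pb <- take(b, "second")

  fit_one <- function(p, controls, center = "median") {
    v <- if (sample_center) {
      median_center_samples(p$values, controls, center)
    } else {
      p$values
    }
    f <- fit_trajectories(v, p$samples$time_days, degree)
    f$adj_p <- p.adjust(f$p_value, method = "BH")
    f
  }
  pass <- function(f) {
    f$r2 >= r2_min & (!significance_filter | f$adj_p <= alpha)
  }
  ## two-pass centering: the first-pass median is contaminated by the
  ## dynamic genes themselves, leaving a shared pseudo-trend in every flat
  ## gene; the second pass re-estimates the per-sample offset from
  ## non-selected (control) genes only, provided enough remain
  fa <- fit_one(pa, NULL)
  fb <- fit_one(pb, NULL)
  if (sample_center) {
    controls <- !(pass(fa) | pass(fb))
    if (mean(controls) >= 0.1) {
      fa <- fit_one(pa, controls, center = "mean")
      fb <- fit_one(pb, controls, center = "mean")
    }
  }
  sel_a <- pass(fa)
  sel_b <- pass(fb)
  selected <- if (scope == "either") sel_a | sel_b else sel_a & sel_b

  fits <- tibble::tibble(
    gene_a = fa$gene_id, gene_b = fb$gene_id,
    r2_a = fa$r2, p_a = fa$p_value, adj_p_a = fa$adj_p, selected_a = sel_a,
    r2_b = fb$r2, p_b = fb$p_value, adj_p_b = fb$adj_p, selected_b = sel_b,
    selected = selected)

  structure(list(
    cell_type = cell_type, scope = scope, r2_min = r2_min,
    significance_filter = significance_filter, alpha = alpha, degree = degree,
    species = c(a = pa$samples$species[1L], b = pb$samples$species[1L]),
    genes = fa$gene_id[selected], genes_b = fb$gene_id[selected],
    fits = fits
  ), class = "ddg_set")
}

#' @export
print.ddg_set <- function(x, ...) {
  cat(sprintf("<ddg_set> %s: %d of %d genes dynamic (R^2 >= %.2f, scope %s)\n",
              x$cell_type, length(x$genes), nrow(x$fits), x$r2_min, x$scope))
  invisible(x)
}

#' @export
tidy.ddg_set <- function(x, ...) x$fits

#' @export
glance.ddg_set <- function(x, ...) {
  tibble::tibble(cell_type = x$cell_type, n_genes = nrow(x$fits),
                 n_selected = length(x$genes), r2_min = x$r2_min,
                 scope = x$scope, significance_filter = x$significance_filter)
}

#' Set difference of two DDG sets
#'
#' Used when characterizing dynamic genes on a second dataset: genes already
#' present in the earlier set are removed.
#'
#' @param x,y `ddg_set` objects (or character vectors of gene ids).
#' @return character vector of gene ids in `x` but not `y`.
#' @export
ddg_difference <- function(x, y) {
  gx <- if (inherits(x, "ddg_set")) x$genes else x
  gy <- if (inherits(y, "ddg_set")) y$genes else y
  setdiff(gx, gy)
}

#' Write a DDG fit table to TSV
#' @param ddgs a `ddg_set`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_ddg_set <- function(ddgs, path) {
  readr::write_tsv(ddgs$fits, path, progress = FALSE)
  invisible(path)
}

#' Standardize expression profiles gene-wise
#'
#' Per gene: subtract the mean across samples and divide by the sample
#' standard deviation (n - 1 denominator), so each row has mean 0 and SD 1.
#' Zero-variance genes cannot be standardized; they are dropped with a
#' warning and listed in the `excluded_genes` attribute.
#'
#' @param x real genes-by-samples matrix.
#' @return same-shape (minus exclusions) standardized matrix.
#' @export
#' @examples
#' standardize_profiles(matrix(1:3, 1, dimnames = list("g1", NULL)))
standardize_profiles <- function(x) {
  if (inherits(x, "pseudobulk")) x <- x$values
  if (!is.matrix(x)) {
    stop_cardalign("`x` must be a matrix.", "cardalign_argument_error")
  }
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, sd)
  bad <- sdv == 0 | !is.finite(sdv)
  if (any(bad)) {
    warn(sprintf("Excluding %d zero-variance gene(s) from standardization.", sum(bad)))
  }
  out <- (x[!bad, , drop = FALSE] - mu[!bad]) / sdv[!bad]
  attr(out, "excluded_genes") <- rownames(x)[bad] %||% character(0)
  out
}

#' Cluster standardized expression profiles
#'
#' Agglomerative clustering with 1 - Pearson correlation distance and
#' average linkage; the tree is cut at `n_clusters`. Labels are contiguous
#' integers in order of first appearance along the input.
#'
#' @param x standardized genes-by-samples matrix (rows non-constant).
#' @param n_clusters number of clusters (>= 2).
#' @return named integer vector of cluster labels with the `hclust` tree as
#'   attribute.
#' @export
cluster_profiles <- function(x, n_clusters) {
  if (!is.matrix(x) || nrow(x) < 2L) {
    stop_cardalign("Clustering needs a matrix with at least 2 genes.",
                   "cardalign_argument_error")
  }
  if (n_clusters < 2L || n_clusters > nrow(x)) {
    stop_cardalign("`n_clusters` must be between 2 and the number of genes.",
                   "cardalign_argument_error")
  }
  d <- as.dist(1 - cor(t(x)))
  hc <- hclust(d, method = "average")
  labels <- cutree(hc, k = n_clusters)
  # relabel in order of first appearance so labels are deterministic
  labels <- match(labels, unique(labels))
  names(labels) <- rownames(x)
  attr(labels, "hclust") <- hc
  labels
}

#' Hypergeometric gene-set overlap test
#'
#' Tests whether two gene sets drawn from a common universe overlap more
#' than expected by chance: p = P(X >= observed overlap) with
#' X ~ Hypergeometric(N = |universe|, K = |a|, n = |b|); the expected
#' overlap is |a| |b| / N.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @return one-row tibble: `overlap`, `expected`, `p_value`, set sizes.
#' @export
#' @examples
#' overlap_test(letters[1:8], letters[5:14], letters[1:20])
overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  stray <- setdiff(union(set_a, set_b), universe)
  if (length(stray) > 0L) {
    stop_cardalign(paste0("Sets are not subsets of the universe: ",
                          paste(head(stray, 5), collapse = ", ")),
                   "cardalign_argument_error")
  }
  N <- length(universe); K <- length(set_a); n <- length(set_b)
  k <- length(intersect(set_a, set_b))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble::tibble(overlap = k, expected = K * n / N, p_value = p,
                 n_a = K, n_b = n, n_universe = N)
}
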