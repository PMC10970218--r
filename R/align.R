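## Trajectory curve fitting on a log2-day grid and partial dynamic time
## warping of one species' stages onto another's.

#' Fit per-gene cubic curves on a log2-time grid
#'
#' Fits, per gene, a degree-3 OLS polynomial of standardized expression on
#' tau = log2(days) and evaluates the fitted curves on a uniform grid of
#' `grid_size` points over `span`. By default the span is the observed tau
#' range; requesting a span beyond it is an extrapolation error unless
#' explicitly allowed.
#'
#' @param x standardized genes-by-samples matrix (see
#'   [standardize_profiles()]).
#' @param times_days per-sample stage times in days.
#' @param grid_size number of grid points (default 100).
#' @param span optional `c(tau_min, tau_max)` in log2 days.
#' @param degree polynomial degree (default 3).
#' @param species optional species label carried on the result.
#' @param allow_extrapolation permit a span beyond the observed range.
#' @return a `fitted_trajectory`: `grid_tau`, genes-by-grid `curves`,
#'   `gene_ids`, `species`, plus the stage times used.
#' @export
fit_curve_grid <- function(x, times_days, grid_size = 100L, span = NULL,
                           degree = 3L, species = NULL,
                           allow_extrapolation = FALSE) {
  if (!is.matrix(x) || nrow(x) < 1L) {
    stop_cardalign("Curve fitting needs a non-empty genes-by-samples matrix.",
                   "cardalign_argument_error")
  }
  if (grid_size < 2L) {
    stop_cardalign("`grid_size` must be at least 2.", "cardalign_argument_error")
  }
  tau <- tau_days(times_days)
  if (length(unique(tau)) < degree + 2L) {
    stop_cardalign(sprintf(
      "Degree-%d curve fit needs at least %d distinct stages.", degree, degree + 2L),
      "cardalign_insufficient_data_error")
  }
  obs <- range(tau)
  span <- span %||% obs
  eps <- 1e-8
  if (!allow_extrapolation && (span[1] < obs[1] - eps || span[2] > obs[2] + eps)) {
    stop_cardalign(sprintf(
      "Requested span [%.3f, %.3f] exceeds observed tau range [%.3f, %.3f]; set allow_extrapolation = TRUE to override.",
      span[1], span[2], obs[1], obs[2]), "cardalign_range_error")
  }
  fits <- fit_trajectories(x, times_days, degree)
  beta <- t(as.matrix(fits[, paste0("beta", 0:degree)]))   # (degree+1) x genes
  grid <- seq(span[1], span[2], length.out = grid_size)
  G <- poly_design(grid, degree)                           # grid x (degree+1)
  curves <- t(G %*% beta)                                  # genes x grid
  rownames(curves) <- rownames(x)
  structure(list(
    species = species %||% NA_character_,
    grid_tau = grid,
    curves = curves,
    gene_ids = rownames(x),
    stage_times_days = sort(unique(times_days)),
    degree = degree
  ), class = "fitted_trajectory")
}

#' @export
print.fitted_trajectory <- function(x, ...) {
  cat(sprintf("<fitted_trajectory> %s: %d genes on %d grid points, tau in [%.2f, %.2f]\n",
              x$species, length(x$gene_ids), length(x$grid_tau),
              min(x$grid_tau), max(x$grid_tau)))
  invisible(x)
}

#' @export
tidy.fitted_trajectory <- function(x, ...) {
  cv <- x$curves
  colnames(cv) <- as.character(seq_along(x$grid_tau))
  tibble::as_tibble(cv, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "grid_index",
                        values_to = "expression") |>
    dplyr::mutate(grid_index = as.integer(.data$grid_index),
                  tau = x$grid_tau[.data$grid_index],
                  species = x$species)
}

#' @export
autoplot.fitted_trajectory <- function(object, max_genes = 30L, ...) {
  df <- tidy(object)
  shown <- head(unique(df$gene_id), max_genes)
  ggplot2::ggplot(dplyr::filter(df, .data$gene_id %in% shown),
                  ggplot2::aes(.data$tau, .data$expression, group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.4, ...) +
    ggplot2::labs(x = "log2 gestational days", y = "standardized expression",
                  title = object$species) +
    ggplot2::theme_minimal()
}

## Local cost matrices -----------------------------------------------------

trajectory_cost_matrix <- function(ref, query, distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  A <- ref$curves; B <- query$curves
  if (!identical(ref$gene_ids, query$gene_ids)) {
    stop_cardalign("Gene sets of the two trajectories differ or are ordered differently.",
                   "cardalign_pairing_error")
  }
  if (distance == "euclidean") {
    d2 <- outer(colSums(A^2), colSums(B^2), "+") - 2 * crossprod(A, B)
    sqrt(pmax(d2, 0))
  } else {
    1 - cor(A, B)
  }
}

## Dynamic programming core ------------------------------------------------

#' Dynamic time warping over a local cost matrix
#'
#' Monotone dynamic program with steps (1,0), (0,1) and (1,1) over a
#' reference-by-query cost matrix. Full mode anchors both ends; partial
#' (subsequence) mode leaves the reference open at both ends: the path may
#' start at any `(s, 1)` and end at any `(e, Gq)` with `s <= e`, consuming
#' the query completely, and the start/end pair minimizing total path cost
#' is chosen. The total cost is the sum of local costs over path steps (no
#' path-length normalization). Ties in the recursion prefer the diagonal
#' step, then (0,1), then (1,0); tied open ends prefer the smallest
#' reference index.
#'
#' @param cost non-negative reference-by-query cost matrix.
#' @param mode `"partial"` (default) or `"full"`.
#' @return list with `steps` (two-column matrix of (ref, query) indices),
#'   `total_cost` and `mode`.
#' @export
dtw_path <- function(cost, mode = c("partial", "full")) {
  mode <- match.arg(mode)
  if (!is.matrix(cost) || nrow(cost) < 1L || ncol(cost) < 1L) {
    stop_cardalign("Cost matrix must be non-empty.", "cardalign_argument_error")
  }
  if (any(!is.finite(cost))) {
    stop_cardalign("Cost matrix must be finite.", "cardalign_argument_error")
  }
  Gr <- nrow(cost); Gq <- ncol(cost)
  D <- matrix(Inf, Gr, Gq)
  P <- matrix(0L, Gr, Gq)      # 1 diag, 2 query-only (0,1), 3 ref-only (1,0), 0 path start
  if (mode == "full") {
    D[1L, 1L] <- cost[1L, 1L]
    if (Gr > 1L) for (i in 2:Gr) { D[i, 1L] <- D[i - 1L, 1L] + cost[i, 1L]; P[i, 1L] <- 3L }
  } else {
    D[, 1L] <- cost[, 1L]
  }
  if (Gq > 1L) {
    for (j in 2:Gq) {
      D[1L, j] <- D[1L, j - 1L] + cost[1L, j]
      P[1L, j] <- 2L
      if (Gr > 1L) {
        for (i in 2:Gr) {
          cand <- c(D[i - 1L, j - 1L], D[i, j - 1L], D[i - 1L, j])
          b <- which.min(cand)   # first minimum: diagonal, then (0,1), then (1,0)
          D[i, j] <- cand[b] + cost[i, j]
          P[i, j] <- b
        }
      }
    }
  }
  end_i <- if (mode == "full") Gr else which.min(D[, Gq])
  total <- D[end_i, Gq]
  # backtrack
  steps <- matrix(0L, Gr + Gq, 2L)
  n_steps <- 0L
  i <- end_i; j <- Gq
  repeat {
    n_steps <- n_steps + 1L
    steps[n_steps, ] <- c(i, j)
    move <- P[i, j]
    if (move == 0L) {
      if (mode == "full" && !(i == 1L && j == 1L)) {
        stop_cardalign("Internal DTW backtrack error.", "cardalign_error")
      }
      break
    }
    if (move == 1L) { i <- i - 1L; j <- j - 1L }
    else if (move == 2L) j <- j - 1L
    else i <- i - 1L
  }
  steps <- steps[n_steps:1L, , drop = FALSE]
  colnames(steps) <- c("ref_index", "query_index")
  list(steps = steps, total_cost = unname(total), mode = mode)
}

#' Exhaustive-path alignment oracle
#'
#' Enumerates every admissible monotone step path for the given mode and
#' returns the minimum-cost one. Exponential in the grid size, so it
#' refuses grids larger than 8 x 8; it exists to validate [dtw_path()] /
#' [dtw_align()] on small instances.
#'
#' @inheritParams dtw_path
#' @return same structure as [dtw_path()].
#' @export
brute_force_path <- function(cost, mode = c("partial", "full")) {
  mode <- match.arg(mode)
  Gr <- nrow(cost); Gq <- ncol(cost)
  if (Gr > 8L || Gq > 8L) {
    stop_cardalign("brute_force_path() refuses grids larger than 8 x 8.",
                   "cardalign_argument_error")
  }
  best <- new.env(parent = emptyenv())
  best$cost <- Inf
  best$path <- NULL
  cur <- matrix(0L, Gr + Gq, 2L)

  recurse <- function(i, j, acc, depth) {
    acc <- acc + cost[i, j]
    if (acc > best$cost) return(invisible(NULL))
    cur[depth, ] <<- c(i, j)
    if (j == Gq && (mode == "partial" || i == Gr)) {
      if (acc < best$cost) {
        best$cost <- acc
        best$path <- cur[seq_len(depth), , drop = FALSE]
      }
    }
    if (i < Gr && j < Gq) recurse(i + 1L, j + 1L, acc, depth + 1L)
    if (j < Gq) recurse(i, j + 1L, acc, depth + 1L)
    if (i < Gr) recurse(i + 1L, j, acc, depth + 1L)
    invisible(NULL)
  }

  starts <- if (mode == "full") 1L else seq_len(Gr)
  for (s in starts) recurse(s, 1L, 0, 1L)
  path <- best$path
  colnames(path) <- c("ref_index", "query_index")
  list(steps = path, total_cost = best$cost, mode = mode)
}

as_alignment_path <- function(res, ref = NULL, query = NULL, distance = NULL) {
  structure(list(
    steps = tibble::as_tibble(res$steps),
    total_cost = res$total_cost,
    mode = res$mode,
    dims = c(ref = if (is.null(ref)) max(res$steps[, 1]) else length(ref$grid_tau),
             query = if (is.null(query)) max(res$steps[, 2]) else length(query$grid_tau)),
    distance = distance,
    ref_species = if (is.null(ref)) NA_character_ else ref$species,
    query_species = if (is.null(query)) NA_character_ else query$species
  ), class = "alignment_path")
}

#' Align a query trajectory onto a reference by DTW
#'
#' The local cost between reference grid column i and query grid column j
#' is the Euclidean distance across genes (or 1 - Pearson correlation with
#' `distance = "correlation"`). Partial mode (default) matches the full
#' query time range onto a contiguous sub-range of the reference — the
#' setting for aligning one species' observed window into another species'
#' wider developmental span. Age order is preserved: both index sequences
#' along the path are non-decreasing.
#'
#' @param ref,query `fitted_trajectory` objects with identical, identically
#'   ordered gene sets.
#' @param mode `"partial"` (default) or `"full"`.
#' @param distance `"euclidean"` (default) or `"correlation"`.
#' @return an `alignment_path`: `steps` tibble of (ref_index, query_index),
#'   `total_cost`, `mode`.
#' @export
dtw_align <- function(ref, query, mode = c("partial", "full"),
                      distance = c("euclidean", "correlation")) {
  stopifnot(inherits(ref, "fitted_trajectory"), inherits(query, "fitted_trajectory"))
  mode <- match.arg(mode)
  distance <- match.arg(distance)
  if (length(ref$gene_ids) == 0L) {
    stop_cardalign("No genes to align: the DDG set is empty.",
                   "cardalign_argument_error")
  }
  cost <- trajectory_cost_matrix(ref, query, distance)
  as_alignment_path(dtw_path(cost, mode), ref, query, distance)
}

#' Exhaustive alignment of two trajectories (oracle)
#'
#' @inheritParams dtw_align
#' @return an `alignment_path`; see [brute_force_path()].
#' @export
brute_force_align <- function(ref, query, mode = c("partial", "full"),
                              distance = c("euclidean", "correlation")) {
  mode <- match.arg(mode)
  distance <- match.arg(distance)
  cost <- trajectory_cost_matrix(ref, query, distance)
  as_alignment_path(brute_force_path(cost, mode), ref, query, distance)
}

#' @export
print.alignment_path <- function(x, ...) {
  cat(sprintf("<alignment_path> %s mode, %d steps, total cost %.4f (ref %d x query %d)\n",
              x$mode, nrow(x$steps), x$total_cost, x$dims["ref"], x$dims["query"]))
  invisible(x)
}

#' @export
tidy.alignment_path <- function(x, ...) x$steps

#' @export
glance.alignment_path <- function(x, ...) {
  tibble::tibble(mode = x$mode, total_cost = x$total_cost,
                 n_steps = nrow(x$steps),
                 ref_size = unname(x$dims["ref"]),
                 query_size = unname(x$dims["query"]))
}

#' @export
autoplot.alignment_path <- function(object, ...) {
  ggplot2::ggplot(object$steps,
                  ggplot2::aes(.data$query_index, .data$ref_index)) +
    ggplot2::geom_step(...) +
    ggplot2::labs(x = "query grid index", y = "reference grid index") +
    ggplot2::theme_minimal()
}

#' Stage-to-stage correspondence from an alignment path
#'
#' Each query stage time is mapped to its nearest query grid index and then
#' through the warping path to the matched reference grid indices, reported
#' as the `[lo, hi]` interval in reference tau (log2 days), days (2^tau)
#' and weeks (days / 7). Grid resolution is the precision of these
#' intervals.
#'
#' @param path an `alignment_path` from [dtw_align()].
#' @param ref,query the `fitted_trajectory` objects that were aligned.
#' @param query_stage_times query stage times in days; each must lie within
#'   the query grid span.
#' @return a `stage_correspondence` tibble with one row per query stage.
#' @export
stage_correspondence <- function(path, ref, query,
                                 query_stage_times = query$stage_times_days) {
  stopifnot(inherits(path, "alignment_path"),
            inherits(ref, "fitted_trajectory"),
            inherits(query, "fitted_trajectory"))
  ts <- sort(unique(query_stage_times))
  tau_q <- tau_days(ts)
  gq <- query$grid_tau
  eps <- 1e-8
  out_of_range <- tau_q < min(gq) - eps | tau_q > max(gq) + eps
  if (any(out_of_range)) {
    stop_cardalign(sprintf(
      "Query stage time(s) outside the query grid span: %s days.",
      paste(ts[out_of_range], collapse = ", ")), "cardalign_range_error")
  }
  steps <- path$steps
  rows <- lapply(seq_along(ts), function(k) {
    j_star <- which.min(abs(gq - tau_q[k]))
    refs <- steps$ref_index[steps$query_index == j_star]
    lo <- min(refs); hi <- max(refs)
    tibble::tibble(
      query_days = ts[k], query_tau = tau_q[k], query_grid_index = j_star,
      ref_index_lo = lo, ref_index_hi = hi,
      ref_tau_lo = ref$grid_tau[lo], ref_tau_hi = ref$grid_tau[hi])
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      ref_days_lo = 2^.data$ref_tau_lo, ref_days_hi = 2^.data$ref_tau_hi,
      ref_weeks_lo = .data$ref_days_lo / 7, ref_weeks_hi = .data$ref_days_hi / 7)
  class(out) <- c("stage_correspondence", class(out))
  attr(out, "ref_species") <- ref$species
  attr(out, "query_species") <- query$species
  attr(out, "grid_spacing") <- diff(ref$grid_tau[1:2])
  out
}

#' @export
autoplot.stage_correspondence <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$query_tau)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ref_tau_lo, ymax = .data$ref_tau_hi),
      width = 0.02, ...) +
    ggplot2::geom_point(ggplot2::aes(
      y = (.data$ref_tau_lo + .data$ref_tau_hi) / 2)) +
    ggplot2::labs(x = "query stage (log2 days)",
                  y = "matched reference interval (log2 days)") +
    ggplot2::theme_minimal()
}

#' Write a stage correspondence table to TSV
#' @param corr a `stage_correspondence`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_stage_correspondence <- function(corr, path) {
  readr::write_tsv(tibble::as_tibble(corr), path, progress = FALSE)
  invisible(path)
}
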