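test_that("fit_polynomial_trajectory recovers noiseless cubics and handles constants", {
  t6 <- c(35, 42, 49, 63, 70, 91)
  y <- 2 + log2(t6)^3
  fit <- fit_polynomial_trajectory(y, t6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients), c(2, 0, 0, 1), tolerance = 1e-6)

  const <- fit_polynomial_trajectory(rep(5, 6), t6)
  expect_identical(const$r2, 0)
  expect_identical(const$p_value, 1)

  expect_error(fit_polynomial_trajectory(1:4, c(1, 2, 4, 8)),
               class = "cardalign_insufficient_data_error")
})

test_that("trajectory fits match an independent lm() solve", {
  t8 <- c(35, 42, 49, 56, 63, 77, 91, 105)
  tau <- log2(t8)
  y <- withr::with_seed(19, 1 + 0.5 * tau - 0.2 * tau^2 + rnorm(8, sd = 0.3))
  fit <- fit_polynomial_trajectory(y, t8)
  ref <- lm(y ~ tau + I(tau^2) + I(tau^3))
  s <- summary(ref)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(fit$r2, s$r.squared, tolerance = 1e-8)
  expect_equal(fit$p_value,
               pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3], lower.tail = FALSE),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("R^2 is invariant under affine transforms of the response", {
  t8 <- c(30, 40, 50, 60, 75, 90, 110, 130)
  withr::with_seed(23, {
    for (rep in 1:10) {
      y <- rnorm(8)
      base <- fit_polynomial_trajectory(y, t8)
      tr <- fit_polynomial_trajectory(3.7 * y - 11, t8)
      expect_equal(tr$r2, base$r2, tolerance = 1e-9)
      expect_equal(tr$p_value, base$p_value, tolerance = 1e-9)
    }
  })
})

make_joined_pair <- function(vals_a, vals_b, times_a, times_b) {
  n <- nrow(vals_a)
  ga <- sprintf("GENE%03d", 1:n); gb <- sprintf("Gene%03d", 1:n)
  dimnames(vals_a) <- list(ga, paste0("ha", seq_along(times_a)))
  dimnames(vals_b) <- list(gb, paste0("mb", seq_along(times_b)))
  a <- structure(list(values = vals_a, samples = tibble::tibble(
    sample_id = colnames(vals_a), species = "human", cell_type = "CMs-A",
    time_days = times_a, n_cells = 10L)), class = "pseudobulk")
  b <- structure(list(values = vals_b, samples = tibble::tibble(
    sample_id = colnames(vals_b), species = "mouse", cell_type = "CMs-A",
    time_days = times_b, n_cells = 10L)), class = "pseudobulk")
  list(a = a, b = b)
}

test_that("detect_ddgs selects constructed dynamic genes and obeys scope and monotonicity", {
  times_a <- c(35, 42, 49, 63, 70, 91, 105, 119)
  times_b <- c(9.5, 10.5, 11.5, 12.5, 13.5)
  tau_a <- log2(times_a); tau_b <- log2(times_b)
  n_dyn <- 30; n_flat <- 40
  withr::with_seed(7, {
    dyn_a <- t(sapply(1:n_dyn, function(i) 3e4 + 1e4 * scale(tau_a^((i %% 3) + 1))[, 1]))
    dyn_b <- t(sapply(1:n_dyn, function(i) 3e4 + 1e4 * scale(tau_b^((i %% 3) + 1))[, 1]))
    flat_a <- matrix(3e4, n_flat, length(times_a))
    flat_b <- matrix(3e4, n_flat, length(times_b))
  })
  pair <- make_joined_pair(rbind(dyn_a, flat_a), rbind(dyn_b, flat_b),
                           times_a, times_b)
  dd <- detect_ddgs(pair$a, pair$b, "CMs-A", sample_center = FALSE)
  expect_identical(sort(dd$genes), sort(sprintf("GENE%03d", 1:n_dyn)))

  # all-constant input selects nothing
  flat_pair <- make_joined_pair(matrix(3e4, 20, 8), matrix(3e4, 20, 5),
                                times_a, times_b)
  expect_length(detect_ddgs(flat_pair$a, flat_pair$b, "CMs-A")$genes, 0)

  # raising r2_min never adds genes
  lo <- detect_ddgs(pair$a, pair$b, "CMs-A", r2_min = 0.3, sample_center = FALSE)
  hi <- detect_ddgs(pair$a, pair$b, "CMs-A", r2_min = 0.9, sample_center = FALSE)
  expect_true(all(hi$genes %in% lo$genes))

  # scope = both is at most scope = either
  both <- detect_ddgs(pair$a, pair$b, "CMs-A", scope = "both", sample_center = FALSE)
  expect_true(all(both$genes %in% lo$genes))

  expect_error(detect_ddgs(pair$a, pair$b, "ECs"),
               class = "cardalign_argument_error")
})

test_that("detect_ddgs is invariant to gene order and within-species sample order", {
  bench <- run_benchmark(seed = 3, n_genes = 120, cells_per_stage = 20)
  pbj <- bench$res$pseudobulk
  base <- detect_ddgs(pbj$a, pbj$b, "CMs-A")
  perm_g <- withr::with_seed(1, sample(nrow(pbj$a$values)))
  perm_s <- withr::with_seed(2, sample(ncol(pbj$a$values)))
  a2 <- pbj$a; a2$values <- a2$values[perm_g, perm_s]
  a2$samples <- a2$samples[perm_s, ]
  b2 <- pbj$b; b2$values <- b2$values[perm_g, ]
  shuf <- detect_ddgs(a2, b2, "CMs-A")
  expect_identical(sort(base$genes), sort(shuf$genes))
})

test_that("standardize_profiles yields exact mean 0 / SD 1 rows and drops constants", {
  expect_equal(unname(standardize_profiles(matrix(1:3, 1, dimnames = list("g", NULL)))),
               matrix(c(-1, 0, 1), 1), ignore_attr = TRUE)
  x <- withr::with_seed(8, matrix(rnorm(1000, 5, 3), 100,
                                  dimnames = list(paste0("g", 1:100), NULL)))
  s <- standardize_profiles(x)
  expect_true(all(abs(rowMeans(s)) < 1e-10))
  expect_true(all(abs(apply(s, 1, sd) - 1) < 1e-10))
  # idempotence
  expect_equal(standardize_profiles(s), s, tolerance = 1e-12, ignore_attr = TRUE)
  # zero-variance row excluded with warning
  x[3, ] <- 7
  expect_warning(s2 <- standardize_profiles(x), "zero-variance")
  expect_identical(attr(s2, "excluded_genes"), "g3")
  expect_identical(nrow(s2), 99L)
})

test_that("cluster_profiles separates constructed profile families", {
  n <- 10
  base <- sin(seq(0, 2 * pi, length.out = n))
  up <- t(sapply(1:10, function(i) base))
  down <- -up
  x <- standardize_profiles(rbind(up, down) +
    withr::with_seed(4, matrix(rnorm(20 * n, sd = 1e-3), 20, n)))
  cl <- cluster_profiles(x, 2)
  expect_identical(length(unique(cl[1:10])), 1L)
  expect_identical(length(unique(cl[11:20])), 1L)
  expect_false(cl[1] == cl[11])

  # as many clusters as genes: singletons
  expect_identical(sort(unname(cluster_profiles(x, nrow(x)))), 1:nrow(x))
  expect_error(cluster_profiles(x, 1), class = "cardalign_argument_error")

  # three noisy families recovered with high agreement
  skip_if_not_installed("mclust")
  withr::with_seed(12, {
    protos <- rbind(cos(seq(0, pi, length.out = 12)),
                    seq(-1, 1, length.out = 12),
                    sin(seq(0, 3 * pi, length.out = 12)))
    fam <- rep(1:3, each = 30)
    noisy <- protos[fam, ] + matrix(rnorm(90 * 12, sd = 0.15), 90, 12)
    rownames(noisy) <- paste0("g", 1:90)
  })
  cl3 <- cluster_profiles(standardize_profiles(noisy), 3)
  expect_gte(mclust::adjustedRandIndex(cl3, fam), 0.9)
})

test_that("overlap_test matches exhaustive enumeration and handles edge cases", {
  # a near-total overlap: N = 20, |a| = 8, |b| = 10, overlap 8
  universe <- sprintf("u%02d", 1:20)
  a <- universe[1:8]
  b <- universe[c(1:8, 15, 20)]
  res <- overlap_test(a, b, universe)
  expect_identical(res$overlap, 8L)
  expect_equal(res$expected, 8 * 10 / 20)
  expect_equal(res$p_value, enum_overlap_tail(20, 8, 10, 8), tolerance = 1e-12)

  # zero observed overlap has p = 1
  expect_equal(overlap_test(universe[1:5], universe[6:10], universe)$p_value, 1)
  # forced complete overlap has p = 1
  expect_equal(overlap_test(universe, universe, universe)$p_value, 1)

  expect_error(overlap_test(c(a, "zzz"), b, universe),
               class = "cardalign_argument_error")

  # random spot checks across the N <= 12 space
  withr::with_seed(33, {
    for (i in 1:25) {
      N <- sample(2:12, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
      uu <- sprintf("x%02d", 1:N)
      aa <- uu[seq_len(K)]
      bb <- sample(uu, n)
      got <- overlap_test(aa, bb, uu)
      expect_equal(got$p_value,
                   enum_overlap_tail(N, K, n, got$overlap), tolerance = 1e-12)
    }
  })
})

test_that("ddg_difference removes genes already present in an earlier set", {
  expect_identical(ddg_difference(c("a", "b", "c"), c("b")), c("a", "c"))
})
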