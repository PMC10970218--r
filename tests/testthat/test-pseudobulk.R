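test_that("aggregate_pseudobulk applies round((mean + 1) * 10000) per group", {
  vals <- matrix(c(1, 0, 0.5,
                   3, 0, 2.5), 3, dimnames = list(c("gA", "gB", "gC"),
                                                  c("c1", "c2")))
  m <- expression_matrix(vals, scale = "log2p1")
  cells <- tibble::tibble(cell_id = c("c1", "c2"), species = "human",
                          time_days = 35, cell_type = "CMs-A")
  pb <- aggregate_pseudobulk(m, cells)
  expect_identical(unname(pb$values[, 1]), c(30000, 10000, 25000))
  expect_identical(pb$samples$n_cells, 2L)

  # half-way values round up (half away from zero), not to even
  tie <- expression_matrix(matrix(c(1.0001, 1.0000), 1,
                                  dimnames = list("g", c("c1", "c2"))),
                           scale = "log2p1")
  pt <- aggregate_pseudobulk(tie, tibble::tibble(
    cell_id = c("c1", "c2"), species = "h", time_days = 1, cell_type = "x"))
  expect_identical(unname(pt$values[1, 1]), 20001)

  # aggregation of a single-cell group is the transform itself
  single <- expression_matrix(matrix(c(0.2, 1.7), 2,
                                     dimnames = list(c("g1", "g2"), "c1")),
                              scale = "log2p1")
  ps <- aggregate_pseudobulk(single, tibble::tibble(
    cell_id = "c1", species = "h", time_days = 2, cell_type = "x"))
  expect_identical(unname(ps$values[, 1]), floor((c(0.2, 1.7) + 1) * 10000 + 0.5))

  expect_error(aggregate_pseudobulk(make_expr(matrix(1, 1, 1)), NULL),
               class = "cardalign_scale_error")
})

test_that("aggregate_pseudobulk matches an independent recomputation and is cell-order invariant", {
  m <- log_transform(random_expr(40, 30, seed = 13))
  cells <- make_cells(m,
                      species = rep(c("human", "mouse"), 15),
                      time_days = rep(c(35, 42, 49, 9.5, 10.5), 6),
                      cell_type = rep(c("CMs-A", "ECs", "CMs-A"), 10))
  pb <- aggregate_pseudobulk(m, cells)
  for (j in seq_len(ncol(pb$values))) {
    key <- pb$samples[j, ]
    idx <- cells$species == key$species & cells$cell_type == key$cell_type &
      cells$time_days == key$time_days
    expect_equal(unname(pb$values[, j]),
                 unname(sapply(seq_len(nrow(m$values)), function(g)
                   floor((mean(m$values[g, idx]) + 1) * 1e4 + 0.5))))
  }
  # permutation invariance in cell order
  perm <- withr::with_seed(5, sample(ncol(m$values)))
  m2 <- m; m2$values <- m$values[, perm]
  pb2 <- aggregate_pseudobulk(m2, cells[perm, ])
  expect_identical(pb$values[, sort(colnames(pb$values))],
                   pb2$values[, sort(colnames(pb2$values))])
  # all values >= 10000
  expect_true(all(pb$values >= 10000))
})

test_that("join_orthologs pairs rows, drops unmapped genes and rejects duplicates", {
  a <- aggregate_pseudobulk(log_transform(random_expr(6, 4, seed = 1)),
                            make_cells(random_expr(6, 4, seed = 1)))
  b <- aggregate_pseudobulk(log_transform(random_expr(6, 4, seed = 2)),
                            make_cells(random_expr(6, 4, seed = 2), species = "mouse"))
  rownames(b$values) <- paste0("m", 1:6)
  # identity-style map: both unchanged except row order
  map <- tibble::tibble(gene_a = paste0("g", 6:1), gene_b = paste0("m", 6:1))
  j <- join_orthologs(a, b, map)
  expect_identical(rownames(j$a$values), paste0("g", 6:1))
  expect_identical(rownames(j$b$values), paste0("m", 6:1))
  expect_identical(j$a$values, a$values[paste0("g", 6:1), , drop = FALSE])

  # pairs absent from one side are dropped
  map3 <- tibble::tibble(gene_a = c("g1", "g2", "g3"),
                         gene_b = c("m1", "m2", "zzz"))
  expect_identical(nrow(join_orthologs(a, b, map3)$a$values), 2L)

  dup <- tibble::tibble(gene_a = c("g1", "g1"), gene_b = c("m1", "m2"))
  expect_error(join_orthologs(a, b, dup), "g1",
               class = "cardalign_integrity_error")

  # random map: retained rows equal a brute-force intersection count
  withr::with_seed(31, {
    map_r <- tibble::tibble(gene_a = sample(sprintf("g%d", 1:12), 8),
                            gene_b = sample(sprintf("m%d", 1:12), 8))
  })
  expected <- sum(map_r$gene_a %in% rownames(a$values) &
                    map_r$gene_b %in% rownames(b$values))
  expect_identical(nrow(join_orthologs(a, b, map_r)$a$values), as.integer(expected))
})

test_that("vst_normalize reproduces median-of-ratios size factors", {
  # all samples identical: size factors 1, output log2(count + 1)
  cnt <- matrix(rep(c(3, 8, 20), 3), 3, dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  v <- vst_normalize(cnt)
  expect_equal(unname(attr(v, "size_factors")), rep(1, 3))
  expect_equal(unname(v[, 1]), log2(c(3, 8, 20) + 1))

  # doubling one sample doubles its size factor; normalized columns agree
  cnt2 <- cbind(s1 = c(4, 10, 40), s2 = c(8, 20, 80))
  rownames(cnt2) <- paste0("g", 1:3)
  v2 <- vst_normalize(cnt2)
  sf <- attr(v2, "size_factors")
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(v2[, 1], v2[, 2], tolerance = 1e-9, ignore_attr = TRUE)

  # seeded Poisson matrix: match a literal median-of-ratios recomputation
  cnt3 <- withr::with_seed(17, matrix(rpois(200, 50) + 1L, 20,
                                      dimnames = list(paste0("g", 1:20), paste0("s", 1:10))))
  sf3 <- attr(vst_normalize(cnt3), "size_factors")
  geo <- exp(rowMeans(log(cnt3)))
  manual <- apply(cnt3, 2L, function(col) median(col / geo))
  expect_equal(unname(sf3), unname(manual), tolerance = 1e-12)

  expect_error(vst_normalize(cnt3[, 1, drop = FALSE]),
               class = "cardalign_argument_error")
})

test_that("vst_normalize size factors agree with DESeq2's median-of-ratios", {
  skip_if_not_installed("DESeq2")
  # odd gene count: the two implementations' median conventions coincide
  cnt <- withr::with_seed(29, matrix(rpois(310, 80) + 1L, 31,
                                     dimnames = list(paste0("g", 1:31), paste0("s", 1:10))))
  ours <- attr(vst_normalize(cnt), "size_factors")
  theirs <- DESeq2::estimateSizeFactorsForMatrix(cnt)
  # same estimator up to the overall scale convention
  expect_equal(unname(ours / ours[1]), unname(theirs / theirs[1]), tolerance = 1e-10)
})

test_that("pseudobulk_pca centers genes and reports non-increasing variance fractions", {
  x2 <- matrix(c(1, 5, 2, 9), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  p2 <- pseudobulk_pca(x2, 1)
  expect_equal(p2$var_explained[1], 1)

  x <- withr::with_seed(3, matrix(rnorm(60), 10,
                                  dimnames = list(paste0("g", 1:10), paste0("s", 1:6))))
  p <- pseudobulk_pca(x, 5)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-12)
  # full-rank reconstruction
  pr <- p$prcomp
  recon <- t(pr$x %*% t(pr$rotation)) + rowMeans(x)
  expect_equal(unname(recon), unname(x), tolerance = 1e-8)

  # duplicated samples receive identical scores
  xd <- cbind(x, x); colnames(xd) <- paste0("s", 1:12)
  pd <- pseudobulk_pca(xd, 3)
  expect_equal(as.matrix(pd$scores[1:6, -1]), as.matrix(pd$scores[7:12, -1]),
               tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(pseudobulk_pca(x, 6), class = "cardalign_argument_error")
})

test_that("flag_outliers flags uncorrelated and constant samples but not jitter", {
  withr::with_seed(41, {
    base <- rnorm(200)
    good <- sapply(1:5, function(i) base + rnorm(200, sd = 0.05))
    noise <- rnorm(200)
    x <- cbind(good, noise)
    colnames(x) <- paste0("s", 1:6); rownames(x) <- paste0("g", 1:200)
  })
  fl <- flag_outliers(x)
  expect_identical(fl$flagged$sample_id, "s6")

  withr::with_seed(42, {
    xx <- matrix(rep(rnorm(100), 5), 100) + matrix(rnorm(500, sd = 1e-6), 100)
    colnames(xx) <- paste0("s", 1:5); rownames(xx) <- paste0("g", 1:100)
  })
  expect_identical(nrow(flag_outliers(xx)$flagged), 0L)

  y <- cbind(s1 = rnorm(50), s2 = rnorm(50), s3 = rep(1, 50))
  rownames(y) <- paste0("g", 1:50)
  fy <- flag_outliers(y)
  expect_true("s3" %in% fy$flagged$sample_id)
  expect_identical(fy$flagged$reason[fy$flagged$sample_id == "s3"], "zero variance")
})
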