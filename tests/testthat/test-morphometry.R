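write_tmp_tps <- function(lines) {
  f <- tempfile(fileext = ".tps")
  writeLines(lines, f)
  f
}

test_that("read_tps handles the LM/ID/IMAGE/SCALE dialect", {
  f <- write_tmp_tps(c("LM=3", "0 0", "1 0", "0 1", "ID=s1"))
  cfg <- read_tps(f)
  expect_named(cfg, "s1")
  expect_equal(cfg$s1, matrix(c(0, 1, 0, 0, 0, 1), 3, 2))

  # SCALE multiplies coordinates
  f2 <- write_tmp_tps(c("LM=3", "2 0", "0 2", "2 2", "SCALE=0.5", "ID=s2"))
  expect_equal(read_tps(f2)$s2, matrix(c(1, 0, 1, 0, 1, 1), 3, 2))

  # IMAGE= fallback id and 0-based index fallback
  f3 <- write_tmp_tps(c("LM=3", "0 0", "1 0", "0 1", "IMAGE=img.jpg",
                        "LM=3", "0 0", "2 0", "0 2"))
  expect_named(read_tps(f3), c("img.jpg", "1"))

  expect_error(read_tps(write_tmp_tps(c("LM=3", "0 0", "1 0", "ID=s1"))),
               "only 2 coordinate")
  expect_error(read_tps(write_tmp_tps(
    c("LM=3", "0 0", "1 0", "0 1", "LM=4", "0 0", "1 0", "0 1", "1 1"))),
    "must match")
})

test_that("TPS writing round-trips through the reader", {
  configs <- list(a = matrix(rnorm(10), 5, 2), b = matrix(rnorm(10), 5, 2))
  f <- tempfile(fileext = ".tps")
  write_tps(configs, f)
  back <- read_tps(f)
  expect_equal(back, configs, tolerance = 1e-8)
})

test_that("centroid size is the root summed squared centroid distance", {
  square <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  expect_equal(centroid_size(square), sqrt(2))
  expect_equal(centroid_size(3.7 * square), 3.7 * sqrt(2))
  expect_equal(centroid_size(matrix(1, 4, 2)), 0)
  expect_error(centroid_size(matrix(c(1, 2), 1, 2)), "at least 2")
})

test_that("GPA removes position, scale and orientation", {
  tri <- matrix(c(0, 0, 3, 0, 0, 4), 3, 2, byrow = TRUE)
  rot90 <- matrix(c(0, -1, 1, 0), 2, 2)
  moved <- 3 * tri %*% rot90 + matrix(c(10, -5), 3, 2, byrow = TRUE)
  fit <- gpa(list(a = tri, b = moved))
  expect_true(fit$converged)
  expect_lt(sum((fit$aligned[1, , ] - fit$aligned[2, , ])^2), 1e-16)

  # identical configurations align exactly
  fit2 <- gpa(list(a = tri, b = tri, c = tri))
  expect_lt(sum((fit2$aligned[1, , ] - fit2$aligned[3, , ])^2), 1e-16)

  # centroid sizes recorded from the raw configurations
  expect_equal(unname(fit$centroid_sizes),
               c(centroid_size(tri), centroid_size(moved)))

  # every aligned configuration: centroid at origin, unit centroid size
  for (i in 1:2) {
    A <- fit$aligned[i, , ]
    expect_lt(max(abs(colMeans(A))), 1e-8)
    expect_equal(centroid_size(A), 1, tolerance = 1e-8)
  }
  expect_equal(fit$mean_shape, (fit$aligned[1, , ] + fit$aligned[2, , ]) / 2,
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(gpa(list(a = tri, b = matrix(1, 3, 2))), "degenerate")
})

test_that("pairwise Procrustes residual matches a rotation-grid oracle", {
  set.seed(31)
  y1 <- matrix(rnorm(12), 6, 2)
  y2 <- matrix(rnorm(12), 6, 2)
  norm2 <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  a <- norm2(y1)
  b <- norm2(y2)
  fit <- gpa(list(a = y1, b = y2))
  resid <- sqrt(sum((fit$aligned[1, , ] - fit$aligned[2, , ])^2))
  # brute-force minimum over rotations of b onto a (two-config GPA aligns
  # both to their mean, which attains the same pairwise minimum)
  thetas <- seq(0, 2 * pi, by = 1e-4)
  dists <- vapply(thetas, function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sqrt(sum((b %*% R - a)^2))
  }, numeric(1))
  expect_equal(resid, min(dists), tolerance = 1e-6)
})

test_that("GPA is idempotent on its own output", {
  set.seed(17)
  tr <- simulate_tree(8)
  configs <- simulate_landmarks(tr, base_pentagon(), sigma = 0.05)
  fit <- gpa(configs)
  aligned_list <- lapply(seq_len(8), function(i) fit$aligned[i, , ])
  names(aligned_list) <- dimnames(fit$aligned)[[1]]
  fit2 <- gpa(aligned_list)
  for (i in 1:8)
    expect_lt(max(abs(fit2$aligned[i, , ] - fit$aligned[i, , ])), 1e-6)
})

test_that("shape PCA accounts for superimposition degrees of freedom and reconstructs", {
  set.seed(5)
  tr <- simulate_tree(12)
  configs <- simulate_landmarks(tr, base_pentagon(), sigma = 0.02)
  fit <- gpa(configs)
  pca <- shape_pca(fit)
  expect_equal(sum(pca$explained_fraction), 1, tolerance = 1e-10)
  expect_true(all(diff(pca$explained_fraction) <= 1e-12))
  expect_lt(max(abs(colMeans(pca$scores))), 1e-10)
  # 2 translations + 1 scale are removed exactly (machine zero); the
  # rotation constraint is nonlinear, so its direction keeps second-order
  # (sigma^2-scale) crumbs -- still orders of magnitude below any real
  # shape dimension
  ev <- sort(pca$explained_fraction)
  expect_gte(sum(ev < 1e-12), 3L)
  expect_lt(ev[4] / ev[5], 1e-2)
  # scores + loadings reconstruct the flattened aligned coordinates
  flat <- matrix(fit$aligned, nrow = 12)
  recon <- sweep(pca$scores %*% t(pca$loadings), 2, pca$center, `+`)
  expect_lt(max(abs(recon - flat)), 1e-8)
  expect_error(shape_pca(gpa(configs[1:2])), "at least 3 specimens")
})

test_that("species aggregation averages specimens onto tips", {
  vals <- matrix(c(1, 3, 10, 2, 4, 20), 3, 2,
                 dimnames = list(c("s1", "s2", "s3"), c("PC1", "PC2")))
  sp <- c(s1 = "A", s2 = "A", s3 = "B")
  agg <- aggregate_by_species(vals, sp)
  expect_equal(agg["A", "PC1"], 2)
  expect_equal(agg["B", "PC2"], 20)
  expect_error(aggregate_by_species(vals, sp[1:2]), "no species mapping")
})
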