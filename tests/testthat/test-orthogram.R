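test_that("orthobasis matches the hand-derived columns on a balanced quartet", {
  tr <- read_topology("((A,B),(C,D));")
  b <- build_orthobasis(tr)
  B <- b$vectors
  expect_equal(dim(B), c(4L, 3L))
  # root column opposes the two cherries with entries of magnitude 1/2
  root_col <- B[, 1]
  expect_equal(abs(unname(root_col)), rep(0.5, 4))
  expect_equal(root_col[["A"]], root_col[["B"]])
  expect_equal(root_col[["C"]], root_col[["D"]])
  # a cherry column is +-1/sqrt(2) on its two tips, zero elsewhere
  ab_col <- B[, which(b$np_of_column == 2)[1]]
  expect_equal(sort(abs(unname(ab_col))), c(0, 0, 1 / sqrt(2), 1 / sqrt(2)))
  expect_equal(sum(ab_col), 0)
})

test_that("orthobasis is orthonormal and centered on arbitrary trees", {
  for (seed in 1:6) {
    tr <- simulate_tree_polytomous(sample(4:20, 1), seed = seed)
    B <- build_orthobasis(tr)$vectors
    n <- nrow(B)
    expect_equal(ncol(B), n - 1L)
    expect_lt(max(abs(crossprod(B) - diag(n - 1L))), 1e-10)
    expect_lt(max(abs(colSums(B))), 1e-10)
  }
  expect_error(build_orthobasis(read_topology("(A,B);")), "at least 3 tips")
})

test_that("trait decomposition is a complete Parseval decomposition", {
  tr <- read_topology("((A,B),(C,D));")
  b <- build_orthobasis(tr)
  r2 <- decompose_trait(c(A = 1, B = 1, C = -1, D = -1), b)
  expect_equal(r2, c(1, 0, 0))

  expect_error(decompose_trait(c(A = 2, B = 2, C = 2, D = 2), b), "constant")
  expect_error(decompose_trait(c(A = 1, B = 2, C = 3), b), "length")
  expect_error(decompose_trait(c(A = 1, B = 2, C = 3, Z = 4), b), "names")

  set.seed(7)
  for (i in 1:5) {
    tr <- simulate_tree_polytomous(12, seed = i)
    b <- build_orthobasis(tr)
    x <- stats::setNames(rnorm(12), tr$tip.label)
    r2 <- decompose_trait(x, b)
    expect_equal(sum(r2), 1, tolerance = 1e-12)
    expect_true(all(r2 >= 0))
    # completeness: the basis reconstructs the standardized trait exactly
    z <- x[rownames(b$vectors)] - mean(x)
    zs <- z / sqrt(sum(z^2))
    recon <- b$vectors %*% crossprod(b$vectors, zs)
    expect_lt(max(abs(recon - zs)), 1e-10)
  }
})

test_that("per-node variance shares are invariant to the within-node contrast choice", {
  # for a polytomy the individual columns are convention; any orthonormal
  # rotation of a node's column block must leave the node's R2 sum unchanged
  tr <- read_topology("((A,B,C,D),(E,F),G);")
  b <- build_orthobasis(tr)
  set.seed(11)
  x <- stats::setNames(rnorm(7), tr$tip.label)
  r2 <- decompose_trait(x, b)
  by_node <- tapply(r2, b$node_of_column, sum)
  B2 <- b$vectors
  for (v in unique(b$node_of_column)) {
    cols <- which(b$node_of_column == v)
    if (length(cols) > 1L) {
      Q <- qr.Q(qr(matrix(rnorm(length(cols)^2), length(cols))))
      B2[, cols] <- B2[, cols] %*% Q
    }
  }
  b2 <- b
  b2$vectors <- B2
  r2b <- decompose_trait(x, b2)
  by_node2 <- tapply(r2b, b$node_of_column, sum)
  expect_equal(by_node, by_node2, tolerance = 1e-12)
})

test_that("orthogram statistics match hand arithmetic and stay in range", {
  s <- orthogram_statistics(c(1, 0, 0))
  expect_equal(s$R2Max, 1)
  expect_equal(s$SkR2k, 1)
  expect_equal(s$Dmax, 2 / 3)
  expect_equal(s$SCE, 5 / 9)

  expect_equal(orthogram_statistics(rep(1 / 3, 3))$Dmax, 0)
  expect_equal(orthogram_statistics(rep(1 / 3, 3))$SCE, 0)
  expect_equal(orthogram_statistics(c(0.5, 0.3, 0.2))$R2Max, 0.5)
  expect_error(orthogram_statistics(c(0.5, 0.2)), "sum to 1")

  set.seed(3)
  for (i in 1:10) {
    B <- sample(3:40, 1)
    r2 <- as.vector(stats::rexp(B))
    r2 <- r2 / sum(r2)
    s <- orthogram_statistics(r2)
    expect_gte(s$SkR2k, 1)
    expect_lte(s$SkR2k, B)
    expect_gte(s$Dmax, 0)
    expect_lt(s$Dmax, 1)
    expect_gte(s$SCE, 0)
  }
})

test_that("orthogram test is reproducible, valid, and relabeling-invariant", {
  tr <- simulate_tree(16, seed = 5)
  x <- simulate_trait(tr, "brownian", seed = 6)
  a <- orthogram_test(x, tr, n_perm = 199, seed = 99)
  b <- orthogram_test(x, tr, n_perm = 199, seed = 99)
  expect_identical(a$pvalues, b$pvalues)
  expect_identical(a$r2, b$r2)
  pv <- unlist(a$pvalues)
  expect_true(all(pv > 0 & pv <= 1))
  expect_equal(sum(a$r2), 1, tolerance = 1e-12)
  expect_equal(a$cumulative[length(a$cumulative)], 1, tolerance = 1e-12)
  expect_true(all(diff(a$cumulative) >= -1e-15))

  # relabel tips together with the trait: p-values must not move
  perm <- sample(ape::Ntip(tr))
  tr2 <- tr
  tr2$tip.label <- paste0("x", perm)
  x2 <- stats::setNames(x, paste0("x", perm))
  c2 <- orthogram_test(x2, tr2, n_perm = 199, seed = 99)
  expect_equal(unlist(c2$pvalues), unlist(a$pvalues))

  expect_error(orthogram_test(x, tr, n_perm = 50), "at least 99")
})

test_that("significant nodes are the bars above the envelope, basal under BM", {
  # all variance on the root contrast; with 8 tips the chance of a random
  # permutation reproducing the perfect clade split is 2/70 < 5%, so the
  # pointwise envelope at the root position sits strictly below the
  # observed bar
  tr <- read_topology("(((A,B),(C,D)),((E,F),(G,H)));")
  x <- stats::setNames(c(1, 1, 1, 1, -1, -1, -1, -1), tr$tip.label)
  og <- orthogram_test(x, tr, n_perm = 499, seed = 1)
  expect_equal(og$r2[1], 1, tolerance = 1e-12)
  sig <- significant_nodes(og)
  expect_true(nrow(sig) >= 1L)
  expect_equal(sig$node[1], 9L)       # the root carries all the variance
  expect_equal(sig$r2[1], 1)

  # under strong BM signal, flagged columns should lean basal (high np)
  set.seed(21)
  flagged_np <- c()
  all_np <- c()
  for (i in 1:20) {
    tr <- simulate_tree(24)
    x <- simulate_trait(tr, "brownian", sigma = 1)
    og <- orthogram_test(x, tr, n_perm = 199)
    s <- significant_nodes(og)
    flagged_np <- c(flagged_np, s$np)
    all_np <- c(all_np, og$np_of_column)
  }
  expect_gt(mean(flagged_np), mean(all_np))
})
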