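cfg1d <- function(v) matrix(c(v, 0), 1, 2)

test_that("squared-change reconstruction matches the closed-form small cases", {
  # 3-tip star, values (0, 0, 3): root at the mean, score 1 + 1 + 4
  star <- read_topology("(A,B,C);")
  anc <- reconstruct_landmarks(star, list(A = cfg1d(0), B = cfg1d(0),
                                          C = cfg1d(3)))
  expect_equal(anc$node_configs[["4"]][1, 1], 1)
  expect_equal(anc$tree_score, 6)

  # ((A,B),C) with (0, 0, 3): inner 0.6, root 1.8, score 3.6
  tr <- read_topology("((A,B),C);")
  anc2 <- reconstruct_landmarks(tr, list(A = cfg1d(0), B = cfg1d(0),
                                         C = cfg1d(3)))
  expect_equal(anc2$node_configs[["4"]][1, 1], 1.8)
  expect_equal(anc2$node_configs[["5"]][1, 1], 0.6)
  expect_equal(anc2$tree_score, 3.6)
  expect_equal(anc2$criterion, "squared")

  # identical tips: every node identical, zero score, under both criteria
  same <- base_pentagon()
  tips <- list(A = same, B = same, C = same)
  for (crit in c("squared", "linear")) {
    anc3 <- reconstruct_landmarks(tr, tips, criterion = crit)
    expect_equal(anc3$tree_score, 0, tolerance = 1e-10)
    for (cfg in anc3$node_configs) expect_equal(cfg, same, tolerance = 1e-8)
  }

  expect_error(reconstruct_landmarks(tr, list(A = cfg1d(0), B = cfg1d(0))),
               "no configuration for tip")
  expect_error(
    reconstruct_landmarks(tr, list(A = cfg1d(0), B = cfg1d(0),
                                   C = matrix(0, 2, 2))),
    "same landmark dimensions")
})

test_that("squared-change optimum matches grid refinement on random topologies", {
  set.seed(13)
  topos <- enumerate_topology_newicks(c("A", "B", "C", "D"))
  for (nwk in topos) {
    tr <- read_topology(nwk)
    vals <- stats::setNames(rnorm(4, sd = 2), tr$tip.label)
    tips <- lapply(vals, cfg1d)
    anc <- reconstruct_landmarks(tr, tips)
    oracle <- grid_min_squared(tr, vals)
    got <- vapply(anc$node_configs, function(m) m[1, 1], numeric(1))
    expect_equal(unname(got), unname(oracle$values), tolerance = 1e-4)
    expect_equal(anc$tree_score, oracle$score, tolerance = 1e-4)
  }
})

test_that("tree score is invariant under joint rotation and translation", {
  set.seed(23)
  tr <- simulate_tree(9)
  tips <- simulate_landmarks(tr, base_pentagon(), sigma = 0.2)
  anc <- reconstruct_landmarks(tr, tips)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shifted <- lapply(tips, function(m) m %*% R + matrix(c(2, -1), nrow(m), 2,
                                                       byrow = TRUE))
  anc2 <- reconstruct_landmarks(tr, shifted)
  expect_equal(anc2$tree_score, anc$tree_score, tolerance = 1e-10)
})

test_that("linear criterion lowers the linear score relative to the squared optimum", {
  set.seed(29)
  tr <- simulate_tree(10)
  tips <- simulate_landmarks(tr, base_pentagon(), sigma = 0.3)
  sq <- reconstruct_landmarks(tr, tips, criterion = "squared")
  li <- reconstruct_landmarks(tr, tips, criterion = "linear")
  linear_score <- function(anc) {
    n <- ape::Ntip(tr)
    val <- function(v) if (v > n) anc$node_configs[[as.character(v)]] else
      tips[[tr$tip.label[v]]]
    sum(apply(tr$edge, 1, function(e) sqrt(sum((val(e[1]) - val(e[2]))^2))))
  }
  expect_lte(li$tree_score, linear_score(sq) + 1e-10)
  expect_equal(li$tree_score, linear_score(li), tolerance = 1e-8)
  expect_gt(li$iterations, 0L)
})

test_that("Fitch parsimony reproduces the textbook counts and assignments", {
  q <- read_topology("((A,B),(C,D));")
  expect_equal(fitch_optimize(q, c(A = 0, B = 0, C = 0, D = 0))$steps, 0L)
  expect_equal(fitch_optimize(q, c(A = 0, B = 0, C = 1, D = 1))$steps, 1L)
  expect_equal(fitch_optimize(q, c(A = 0, B = 1, C = 0, D = 1))$steps, 2L)

  f <- fitch_optimize(q, c(A = 0, B = 0, C = 1, D = 1))
  # the realized assignment must attain the optimal step count
  steps_realized <- sum(f$assignment[q$edge[, 1]] != f$assignment[q$edge[, 2]])
  expect_equal(steps_realized, f$steps)

  expect_error(fitch_optimize(q, c(A = 0, B = 0, C = 1)), "no state for tip")
  expect_error(fitch_optimize(q, c(A = 0, B = 1, C = 2, D = 3)), "binary")
})

test_that("Fitch step counts match exhaustive enumeration on small topologies", {
  set.seed(37)
  for (labels in list(c("A", "B", "C", "D"), c("A", "B", "C", "D", "E"))) {
    topos <- enumerate_topology_newicks(labels)
    for (nwk in topos) {
      tr <- read_topology(nwk)
      states <- stats::setNames(sample(0:1, length(labels), replace = TRUE),
                                tr$tip.label)
      f <- fitch_optimize(tr, states)
      expect_equal(f$steps, bf_fitch_steps(tr, states))
      realized <- sum(f$assignment[tr$edge[, 1]] != f$assignment[tr$edge[, 2]])
      expect_equal(realized, f$steps)
    }
  }
})
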