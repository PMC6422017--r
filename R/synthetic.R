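#' Simulate a rooted binary topology under the Yule process
#'
#' Starting from a two-tip tree, a uniformly chosen extant tip is split into
#' two until the requested tip count is reached. Only the topology is
#' produced (no branch lengths), matching the topology-only analysis regime;
#' tips are labelled `t1..tn`.
#'
#' @param n_tips number of tips (>= 3).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a rooted binary `phylo` object with `n_tips - 1` internal nodes.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 3L) stop("n_tips must be at least 3")
  if (!is.null(seed)) set.seed(seed)
  # children[[i]]: NULL for a tip, two node indices for an internal node
  children <- vector("list", 2L * n_tips - 1L)
  children[[1]] <- c(2L, 3L)
  tips <- c(2L, 3L)
  nxt <- 4L
  while (length(tips) < n_tips) {
    u <- tips[sample.int(length(tips), 1L)]
    children[[u]] <- c(nxt, nxt + 1L)
    tips <- c(setdiff(tips, u), nxt, nxt + 1L)
    nxt <- nxt + 2L
  }
  # labels are exchangeable: a random assignment makes labeled shapes follow
  # the Yule topology law (uniform over the 3 labeled shapes at n = 3)
  lab <- character(length(children))
  lab[sort(tips)] <- paste0("t", sample.int(n_tips))
  newick_of <- function(v) {
    if (is.null(children[[v]])) return(lab[v])
    paste0("(", paste(vapply(children[[v]], newick_of, character(1)),
                      collapse = ","), ")")
  }
  tree <- ape::read.tree(text = paste0(newick_of(1L), ";"))
  validate_topology(tree)
  tree
}

#' Simulate a random rooted topology with polytomies
#'
#' Builds a Yule topology and then collapses each internal edge independently
#' with the given probability, yielding multifurcating test trees. Intended
#' for exercising polytomy handling; the Yule generator itself stays binary.
#'
#' @param n_tips number of tips (>= 3).
#' @param collapse_prob probability that an internal edge is collapsed.
#' @param seed integer seed, or `NULL`.
#' @return a rooted `phylo` object, possibly multifurcating.
#' @export
simulate_tree_polytomous <- function(n_tips, collapse_prob = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- simulate_tree(n_tips)
  n <- ape::Ntip(tree)
  internal_edges <- which(tree$edge[, 2] > n)
  if (length(internal_edges)) {
    drop <- internal_edges[stats::runif(length(internal_edges)) < collapse_prob]
    if (length(drop)) {
      tree$edge.length <- rep(1, nrow(tree$edge))
      tree$edge.length[drop] <- 0
      tree <- ape::di2multi(tree, tol = 1e-8)
      tree$edge.length <- NULL
    }
  }
  validate_topology(tree)
  tree
}

#' Simulate a tip trait on a tree
#'
#' Two generative regimes bracket the signal question the package's tests
#' answer:
#' \describe{
#'   \item{`brownian`}{value 0 at the root; every branch adds an independent
#'     Normal(0, sigma^2) step (all edges have implicit length 1). Tips in
#'     the same clade share ancestral steps, so the trait carries strong
#'     phylogenetic signal.}
#'   \item{`white_noise`}{i.i.d. Normal(0, sigma^2) per tip: no signal, the
#'     exchangeable null of the permutation tests.}
#' }
#'
#' @param tree a validated `phylo` object.
#' @param model `"brownian"` or `"white_noise"`.
#' @param sigma step (brownian) or marginal (white noise) standard deviation.
#' @param seed integer seed, or `NULL`.
#' @return named numeric vector over tips, in tip-label order.
#' @export
simulate_trait <- function(tree, model = c("brownian", "white_noise"),
                           sigma = 1, seed = NULL) {
  model <- match.arg(model)
  validate_topology(tree)
  if (sigma < 0) stop("sigma must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  if (model == "white_noise") {
    x <- stats::rnorm(n, 0, sigma)
  } else {
    val <- numeric(n + tree$Nnode)
    # preorder: reversed postorder assigns parents before children
    for (e in rev(ape::postorder(tree))) {
      p <- tree$edge[e, 1]
      ch <- tree$edge[e, 2]
      val[ch] <- val[p] + stats::rnorm(1, 0, sigma)
    }
    x <- val[seq_len(n)]
  }
  names(x) <- tree$tip.label
  x
}

#' Simulate landmark configurations evolving on a tree
#'
#' Under the `brownian` model every coordinate of every landmark evolves as
#' an independent Brownian motion (unit-length edges, step sd `sigma`) from a
#' shared base shape at the root, so related tips share shape deviations;
#' under `white_noise` each tip is the base shape plus i.i.d. Normal(0,
#' sigma^2) coordinate noise, carrying no phylogenetic structure. Tip
#' configurations can optionally be written to a TPS file with tip labels as
#' record IDs, in the dialect [read_tps()] accepts.
#'
#' @param tree a validated `phylo` object.
#' @param base_shape k x 2 matrix, k >= 3, landmarks not all collinear.
#' @param sigma per-edge step (brownian) or per-tip marginal (white noise)
#'   standard deviation.
#' @param model `"brownian"` (default) or `"white_noise"`.
#' @param seed integer seed, or `NULL`.
#' @param tps_path optional output path for a TPS file of the tip shapes.
#' @return named list of k x 2 matrices, one per tip.
#' @export
simulate_landmarks <- function(tree, base_shape, sigma = 0.05,
                               model = c("brownian", "white_noise"),
                               seed = NULL, tps_path = NULL) {
  model <- match.arg(model)
  validate_topology(tree)
  base_shape <- as.matrix(base_shape)
  if (nrow(base_shape) < 3L || ncol(base_shape) != 2L)
    stop("base_shape must be a k x 2 matrix with k >= 3")
  centered <- sweep(base_shape, 2, colMeans(base_shape))
  if (qr(centered)$rank < 2L)
    stop("base_shape is degenerate (collinear or coincident landmarks)")
  if (sigma < 0) stop("sigma must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  k <- nrow(base_shape)
  if (model == "white_noise") {
    configs <- lapply(seq_len(n), function(i) {
      base_shape + matrix(stats::rnorm(2L * k, 0, sigma), k, 2)
    })
  } else {
    val <- vector("list", n + tree$Nnode)
    val[[n + 1L]] <- base_shape
    for (e in rev(ape::postorder(tree))) {
      p <- tree$edge[e, 1]
      ch <- tree$edge[e, 2]
      val[[ch]] <- val[[p]] + matrix(stats::rnorm(2L * k, 0, sigma), k, 2)
    }
    configs <- val[seq_len(n)]
  }
  names(configs) <- tree$tip.label
  if (!is.null(tps_path)) write_tps(configs, tps_path)
  configs
}

#' Simulate specimen-level skull measurements by subfamily
#'
#' Generates a measurement table in the shape [compute_ratios()] expects:
#' specimens nested in species nested in named groups, with group-specific
#' mean ratios, lognormal skull lengths and Gaussian specimen noise on the
#' ratio. A fraction of specimens gets a missing total length, emulating
#' incomplete fossils.
#'
#' @param group_means named numeric vector: subfamily -> mean bsL/stL ratio.
#' @param species_per_group species count per subfamily.
#' @param specimens_per_species specimen count per species.
#' @param ratio_sd specimen-level sd of the ratio.
#' @param missing_frac fraction of specimens with stL set to NA.
#' @param seed integer seed, or `NULL`.
#' @return data.frame with columns `specimen_id`, `species`, `subfamily`,
#'   `bsL`, `stL`.
#' @export
simulate_measurements <- function(group_means,
                                  species_per_group = 4L,
                                  specimens_per_species = 6L,
                                  ratio_sd = 0.015,
                                  missing_frac = 0.05,
                                  seed = NULL) {
  if (is.null(names(group_means)) || any(!nzchar(names(group_means))))
    stop("group_means must be named by subfamily")
  if (any(group_means <= 0 | group_means >= 1))
    stop("group mean ratios must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (g in names(group_means)) {
    for (s in seq_len(species_per_group)) {
      sp <- sprintf("%s_sp%d", g, s)
      for (i in seq_len(specimens_per_species)) {
        stL <- stats::rlnorm(1, meanlog = log(300), sdlog = 0.15)
        ratio <- min(0.95, max(0.02,
          stats::rnorm(1, group_means[[g]], ratio_sd)))
        rows[[length(rows) + 1L]] <- data.frame(
          specimen_id = sprintf("%s_%02d", sp, i),
          species = sp, subfamily = g,
          bsL = ratio * stL, stL = stL)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (missing_frac > 0) {
    miss <- stats::runif(nrow(out)) < missing_frac
    out$stL[miss] <- NA_real_
  }
  out
}
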