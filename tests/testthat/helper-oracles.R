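# Independent oracles used to cross-check the package implementations.
# Everything here is deliberately brute-force and shares no code with R/.

# All rooted (possibly multifurcating) tree topologies over a label set,
# as Newick strings. A tree is a leaf, or an unordered set of >= 2 subtrees
# whose label sets partition the labels; the root-child partition identifies
# the tree uniquely.
enumerate_topologies <- function(labels) {
  n <- length(labels)
  if (n == 1L) return(labels)
  out <- character(0)
  for (part in set_partitions(labels)) {
    if (length(part) < 2L) next
    # cartesian product of subtree choices per block
    block_trees <- lapply(part, enumerate_topologies)
    combos <- expand.grid(block_trees, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(nrow(combos))) {
      kids <- sort(unlist(combos[r, ], use.names = FALSE))
      out <- c(out, paste0("(", paste(kids, collapse = ","), ")"))
    }
  }
  unique(out)
}

enumerate_topology_newicks <- function(labels) {
  paste0(enumerate_topologies(labels), ";")
}

# all set partitions of a character vector (each partition: list of blocks)
set_partitions <- function(x) {
  if (length(x) == 1L) return(list(list(x)))
  first <- x[1]
  rest <- set_partitions(x[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(first, q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(first), p)
  }
  out
}

# BFS shortest path between two nodes in the undirected tree graph
bf_path_nodes <- function(tree, from, to) {
  nn <- ape::Ntip(tree) + tree$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  prev <- integer(nn)
  seen <- logical(nn)
  seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) break
    for (u in adj[[v]]) {
      if (!seen[u]) {
        seen[u] <- TRUE
        prev[u] <- v
        queue <- c(queue, u)
      }
    }
  }
  path <- to
  while (path[1] != from) path <- c(prev[path[1]], path)
  path
}

# brute-force Abouheif proximity from BFS paths and child counts
bf_proximity <- function(tree) {
  n <- ape::Ntip(tree)
  dd <- tabulate(tree$edge[, 1], nbins = n + tree$Nnode)
  W <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      path <- bf_path_nodes(tree, i, j)
      internals <- path[path > n]
      W[i, j] <- W[j, i] <- prod(1 / dd[internals])
    }
  }
  diag(W) <- 1 - rowSums(W)
  W
}

# minimum Fitch steps by exhaustive enumeration of internal-state assignments
bf_fitch_steps <- function(tree, states01) {
  n <- ape::Ntip(tree)
  s <- states01[tree$tip.label]
  N <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(0:1), N)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    full <- c(s, grid[r, ])
    steps <- sum(full[tree$edge[, 1]] != full[tree$edge[, 2]])
    best <- min(best, steps)
  }
  best
}

# brute-force squared-change minimizer: coordinate-wise grid refinement over
# the internal-node values of a single 1-D character
grid_min_squared <- function(tree, tipvals) {
  n <- ape::Ntip(tree)
  N <- tree$Nnode
  vals <- c(tipvals[tree$tip.label], rep(mean(tipvals), N))
  score <- function(v) sum((v[tree$edge[, 1]] - v[tree$edge[, 2]])^2)
  width <- diff(range(tipvals)) + 1
  for (round in 1:30) {
    for (v in (n + 1L):(n + N)) {
      grid <- vals[v] + seq(-width, width, length.out = 41)
      sc <- vapply(grid, function(g) {
        vv <- vals; vv[v] <- g; score(vv)
      }, numeric(1))
      vals[v] <- grid[which.min(sc)]
    }
    width <- width / 2
  }
  list(values = vals[(n + 1L):(n + N)], score = score(vals))
}

# fixed non-degenerate base shape used across landmark tests
base_pentagon <- function() {
  theta <- 2 * pi * (0:4) / 5
  cbind(cos(theta), sin(theta))
}
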