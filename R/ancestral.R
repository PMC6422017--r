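#' Ancestral landmark configurations minimizing total shape change
#'
#' Assigns a landmark configuration to every internal node of a rooted tree
#' so that the differences between ancestor and descendant shapes, summed
#' over all branches, are minimal; the minimized sum is the tree score. All
#' branches are weighted equally (the tree carries topology only). Two
#' criteria are available:
#' \describe{
#'   \item{`squared`}{minimize the sum over branches of the squared Frobenius
#'     distance. The optimum is unique and solves a linear system in which
#'     each internal node is the average of its tree neighbours (squared-change
#'     parsimony); it is also the best linear predictor of ancestral states
#'     under Brownian motion with unit-length edges.}
#'   \item{`linear`}{minimize the sum of (unsquared) Frobenius distances, by
#'     Weiszfeld-style iterations started from the squared solution. Closer
#'     in spirit to spatial parsimony scores; the optimum need not be unique.}
#' }
#'
#' Input configurations must already be superimposed (e.g. [gpa()] output):
#' the reconstruction operates on the coordinates as given.
#'
#' @param tree a validated `phylo` object.
#' @param tip_configs named list of k x 2 matrices covering every tip label.
#' @param criterion `"squared"` (default) or `"linear"`.
#' @param tol score-change convergence tolerance for the linear criterion.
#' @param max_iter iteration cap for the linear criterion.
#' @return an object of class `ancestral_shapes`: list with `node_configs`
#'   (named by internal node id), `tree_score`, `criterion`, `iterations`.
#' @export
reconstruct_landmarks <- function(tree, tip_configs,
                                  criterion = c("squared", "linear"),
                                  tol = 1e-10, max_iter = 1000L) {
  criterion <- match.arg(criterion)
  validate_topology(tree)
  n <- ape::Ntip(tree)
  missing <- setdiff(tree$tip.label, names(tip_configs))
  if (length(missing))
    stop(sprintf("no configuration for tip(s): %s",
                 paste(missing, collapse = ", ")))
  mats <- lapply(tree$tip.label, function(l) as.matrix(tip_configs[[l]]))
  ks <- vapply(mats, nrow, integer(1))
  if (length(unique(ks)) != 1L ||
      length(unique(vapply(mats, ncol, integer(1)))) != 1L)
    stop("all tip configurations must share the same landmark dimensions")
  k <- ks[1]
  d <- ncol(mats[[1]])
  tipX <- t(vapply(mats, as.vector, numeric(k * d)))  # n x (k*d)

  N <- tree$Nnode
  internal <- (n + 1L):(n + N)
  idx <- function(v) v - n
  # each branch connects parent (always internal) to child (tip or internal);
  # the quadratic objective yields a Laplacian system over internal nodes
  L <- matrix(0, N, N)
  R <- matrix(0, N, k * d)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    L[idx(p), idx(p)] <- L[idx(p), idx(p)] + 1
    if (ch > n) {
      L[idx(ch), idx(ch)] <- L[idx(ch), idx(ch)] + 1
      L[idx(p), idx(ch)] <- L[idx(p), idx(ch)] - 1
      L[idx(ch), idx(p)] <- L[idx(ch), idx(p)] - 1
    } else {
      R[idx(p), ] <- R[idx(p), ] + tipX[ch, ]
    }
  }
  A <- solve(L, R)   # N x (k*d) squared-change optimum
  iterations <- 0L

  score_of <- function(Amat, squared) {
    s <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]
      ch <- tree$edge[e, 2]
      xv <- if (ch > n) Amat[idx(ch), ] else tipX[ch, ]
      d2 <- sum((Amat[idx(p), ] - xv)^2)
      s <- s + if (squared) d2 else sqrt(d2)
    }
    s
  }

  if (criterion == "linear") {
    # Weiszfeld updates: each internal node moves to the inverse-distance
    # weighted mean of its neighbours; nodes at distance ~0 from a neighbour
    # are guarded with a small floor
    nb <- vector("list", N)
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]
      ch <- tree$edge[e, 2]
      nb[[idx(p)]] <- c(nb[[idx(p)]], ch)
      if (ch > n) nb[[idx(ch)]] <- c(nb[[idx(ch)]], p)
    }
    val_of <- function(v) if (v > n) A[idx(v), ] else tipX[v, ]
    old_score <- score_of(A, squared = FALSE)
    repeat {
      iterations <- iterations + 1L
      for (v in internal) {
        num <- 0
        den <- 0
        for (u in nb[[idx(v)]]) {
          xu <- val_of(u)
          dist <- sqrt(sum((A[idx(v), ] - xu)^2))
          wgt <- 1 / max(dist, 1e-12)
          num <- num + wgt * xu
          den <- den + wgt
        }
        A[idx(v), ] <- num / den
      }
      new_score <- score_of(A, squared = FALSE)
      if (old_score - new_score < tol || iterations >= max_iter) break
      old_score <- new_score
    }
    tree_score <- new_score
  } else {
    tree_score <- score_of(A, squared = TRUE)
  }

  node_configs <- lapply(seq_len(N), function(i) {
    matrix(A[i, ], nrow = k, ncol = d)
  })
  names(node_configs) <- as.character(internal)
  structure(list(node_configs = node_configs,
                 tree_score = tree_score,
                 criterion = criterion,
                 iterations = iterations),
            class = "ancestral_shapes")
}

#' @export
print.ancestral_shapes <- function(x, ...) {
  cat(sprintf("Ancestral shape reconstruction (%s-change): %d internal nodes, tree score %.6g\n",
              x$criterion, length(x$node_configs), x$tree_score))
  invisible(x)
}

#' Fitch parsimony optimization of a binary character
#'
#' Two-pass parsimony on a rooted tree, using Hartigan-style majority
#' counting at each node so polytomies are scored exactly: the bottom-up
#' pass computes per-node state sets and the minimum number of state
#' changes; the top-down pass extracts
#' one most-parsimonious assignment, preferring the parent's state whenever a
#' node's set is ambiguous.
#'
#' @param tree a validated `phylo` object.
#' @param states named vector (by tip label) with values 0/1 (or a factor /
#'   character with exactly two levels).
#' @return an object of class `fitch_fit`: list with `steps`, `state_sets`
#'   (list per node of the possible states), `assignment` (named integer
#'   vector over all nodes), `levels` (the original two labels).
#' @export
fitch_optimize <- function(tree, states) {
  validate_topology(tree)
  n <- ape::Ntip(tree)
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing))
    stop(sprintf("no state for tip(s): %s", paste(missing, collapse = ", ")))
  s <- states[tree$tip.label]
  lv <- sort(unique(as.character(s)))
  if (length(lv) > 2L)
    stop("character must be binary (at most two states)")
  if (length(lv) == 1L) lv <- c(lv, NA_character_)
  code <- match(as.character(s), lv) - 1L   # 0/1

  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- code[i]
  steps <- 0L
  post <- ape::postorder(tree)
  children <- children_list(tree)
  # increasing np guarantees every internal child is folded before its parent
  np <- node_complexity(tree)
  internal_bottom_up <- ((n + 1L):(n + tree$Nnode))[order(np[(n + 1L):(n + tree$Nnode)])]
  # Hartigan-style majority counting: exact on polytomies, where naive
  # pairwise intersection/union folding undercounts. For each candidate
  # state, count the children whose sets contain it; the node keeps the
  # majority states and pays one step per child outside the majority.
  for (v in internal_bottom_up) {
    ch <- children[[v]]
    k <- vapply(0:1, function(s) {
      sum(vapply(ch, function(u) s %in% sets[[u]], logical(1)))
    }, integer(1))
    K <- max(k)
    sets[[v]] <- (0:1)[k == K]
    steps <- steps + length(ch) - K
  }

  root <- n + 1L
  assignment <- integer(n + tree$Nnode)
  assignment[root] <- sets[[root]][1]
  pre <- rev(post)
  for (e in pre) {
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    if (assignment[p] %in% sets[[ch]]) {
      assignment[ch] <- assignment[p]
    } else {
      assignment[ch] <- sets[[ch]][1]
    }
  }
  names(assignment) <- c(tree$tip.label, as.character((n + 1L):(n + tree$Nnode)))
  structure(list(steps = steps, state_sets = sets, assignment = assignment,
                 levels = lv),
            class = "fitch_fit")
}

#' @export
print.fitch_fit <- function(x, ...) {
  cat(sprintf("Fitch parsimony: %d step(s); states %s\n", x$steps,
              paste(sprintf("%d=%s", seq_along(x$levels) - 1L, x$levels),
                    collapse = ", ")))
  invisible(x)
}
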