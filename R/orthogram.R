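#' Orthonormal topological basis of a rooted tree
#'
#' Builds the n-1 orthonormal contrast vectors that encode the topology of a
#' rooted tree over its n tips. Each internal node with m children
#' contributes m-1 Helmert-style columns: column j (j = 2..m) opposes the
#' tips of the first j-1 child clades (value a) to the tips of the j-th child
#' clade (value b), zero elsewhere, with a and b fixed by centering and unit
#' norm. Columns from different nodes are orthogonal by construction, so the
#' full matrix B satisfies t(B) %*% B = I and t(B) %*% 1 = 0: together with
#' the constant vector it is an orthonormal basis of trait space.
#'
#' Columns are ordered by the canonical node order (decreasing descendant-tip
#' count np, preorder tie-break), then by j within a node.
#'
#' @param tree a validated `phylo` object with at least 3 tips.
#' @return an object of class `orthobasis_topo`: a list with `vectors`
#'   (n x (n-1) matrix, rows named by tip label), `node_of_column` (integer
#'   internal-node id per column) and `np_of_column` (descendant tip count of
#'   that node).
#' @export
build_orthobasis <- function(tree) {
  validate_topology(tree)
  n <- ape::Ntip(tree)
  if (n < 3L)
    stop("orthonormal decomposition requires at least 3 tips")
  nodes <- internal_node_order(tree)
  children <- children_list(tree)
  tipsets <- descendant_tip_sets(tree)
  tipset_of <- function(v) {
    if (v <= n) v else tipsets[[as.character(v)]]
  }
  B <- matrix(0, n, n - 1L)
  node_of <- integer(n - 1L)
  col <- 0L
  for (v in nodes) {
    ch <- children[[v]]
    left <- integer(0)
    for (j in seq_along(ch)) {
      tips_j <- tipset_of(ch[j])
      if (j > 1L) {
        n1 <- length(left)
        n2 <- length(tips_j)
        a <- sqrt(n2 / (n1 * (n1 + n2)))
        b <- -sqrt(n1 / (n2 * (n1 + n2)))
        col <- col + 1L
        B[left, col] <- a
        B[tips_j, col] <- b
        node_of[col] <- v
      }
      left <- c(left, tips_j)
    }
  }
  rownames(B) <- tree$tip.label
  np <- node_complexity(tree)
  structure(list(vectors = B,
                 node_of_column = node_of,
                 np_of_column = np[node_of]),
            class = "orthobasis_topo")
}

#' Decompose a tip trait onto a topological orthobasis
#'
#' The trait is centered and scaled to unit Euclidean norm; the squared
#' projection onto each basis column gives the fraction of trait variance
#' carried by that column. The fractions sum to one (Parseval: the basis is
#' complete for the centered subspace).
#'
#' @param x numeric tip trait, aligned with the basis tip order; if named,
#'   names are checked against the basis row names.
#' @param basis an `orthobasis_topo` from [build_orthobasis()].
#' @return numeric vector of squared coefficients R2_k, length n-1.
#' @export
decompose_trait <- function(x, basis) {
  stopifnot(inherits(basis, "orthobasis_topo"))
  B <- basis$vectors
  if (length(x) != nrow(B))
    stop(sprintf("trait has length %d but the tree has %d tips",
                 length(x), nrow(B)))
  if (!is.null(names(x))) {
    if (!setequal(names(x), rownames(B)))
      stop("trait names do not match the tree's tip labels")
    x <- x[rownames(B)]
  }
  if (anyNA(x)) stop("trait contains missing values")
  z <- x - mean(x)
  s <- sqrt(sum(z^2))
  if (s < .Machine$double.eps^0.5 * max(1, abs(mean(x))) || s == 0)
    stop("trait is constant across tips: no variance to decompose")
  r2 <- as.vector(crossprod(B, z / s))^2
  r2
}

#' The four orthogram summary statistics
#'
#' Given the ordered squared coefficients R2_k (k = 1..B along the canonical
#' root-to-tips node order), computes:
#' \describe{
#'   \item{R2Max}{`max(R2)` -- large when dependence concentrates at one node.}
#'   \item{SkR2k}{`sum(k * R2)` -- skewness of variance toward the root (small)
#'     or the tips (large).}
#'   \item{Dmax}{Kolmogorov-Smirnov style maximal absolute deviation of the
#'     cumulative decomposition from the uniform line m/B.}
#'   \item{SCE}{sum of squared cumulative deviations (averaged variation).}
#' }
#'
#' @param r2 squared coefficients summing to 1.
#' @return named list with elements `R2Max`, `SkR2k`, `Dmax`, `SCE`.
#' @export
orthogram_statistics <- function(r2) {
  if (abs(sum(r2) - 1) > 1e-8)
    stop("r2 must sum to 1 (standardized decomposition)")
  B <- length(r2)
  cum <- cumsum(r2)
  unif <- seq_len(B) / B
  list(R2Max = max(r2),
       SkR2k = sum(seq_len(B) * r2),
       Dmax  = max(abs(cum - unif)),
       SCE   = sum((cum - unif)^2))
}

# Columnwise statistics for a matrix of permuted decompositions (B x nperm).
# Returns a list of 4 numeric vectors; kept internal and vectorized because
# the permutation test calls it on ~1000 columns at once.
orthogram_statistics_matrix <- function(R2) {
  B <- nrow(R2)
  k <- seq_len(B)
  cum <- apply(R2, 2, cumsum)
  if (B == 1L) cum <- matrix(cum, nrow = 1L)
  dev <- cum - k / B
  list(R2Max = apply(R2, 2, max),
       SkR2k = colSums(k * R2),
       Dmax  = apply(abs(dev), 2, max),
       SCE   = colSums(dev^2))
}

#' Orthogram permutation test of phylogenetic signal
#'
#' Decomposes a standardized tip trait on the topological orthobasis and
#' tests the four summary statistics against a null distribution obtained by
#' randomly permuting trait values across tips. R2Max, Dmax and SCE are
#' upper-tailed (signal concentrates or distorts the decomposition upward);
#' SkR2k is two-tailed, since variance may skew toward the root or toward the
#' tips. P-values use the add-one convention
#' p = (1 + #\{perm >= obs\}) / (n_perm + 1). Pointwise permutation envelopes
#' are returned for the per-node bars (upper 1-alpha quantile) and the
#' cumulative curve (alpha/2 and 1-alpha/2 quantiles).
#'
#' @param x numeric tip trait (named by tip label, or aligned with tip order).
#' @param tree a validated `phylo` object.
#' @param n_perm number of Monte Carlo permutations (>= 99; default 999).
#' @param seed integer seed for reproducibility, or `NULL` to use the current
#'   RNG state.
#' @param alpha envelope level (default 0.05).
#' @return an object of class `orthogram` with elements `r2`, `cumulative`,
#'   `stats`, `pvalues`, `r2_upper_envelope`, `cumulative_envelope` (2-row
#'   matrix), `node_of_column`, `np_of_column`, `n_perm`, `alpha`, `seed`,
#'   `tails`.
#' @export
orthogram_test <- function(x, tree, n_perm = 999L, seed = NULL, alpha = 0.05) {
  if (n_perm < 99L) stop("n_perm must be at least 99")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  basis <- build_orthobasis(tree)
  r2 <- decompose_trait(x, basis)
  obs <- orthogram_statistics(r2)

  n <- nrow(basis$vectors)
  if (!is.null(names(x))) x <- x[rownames(basis$vectors)]
  z <- x - mean(x)
  zs <- z / sqrt(sum(z^2))
  if (!is.null(seed)) set.seed(seed)
  # standardization is permutation-invariant, so permute the standardized trait
  P <- vapply(seq_len(n_perm), function(i) zs[sample.int(n)], numeric(n))
  R2p <- crossprod(basis$vectors, P)^2
  null <- orthogram_statistics_matrix(R2p)

  pv <- vapply(c("R2Max", "Dmax", "SCE"), function(s) {
    (1 + sum(null[[s]] >= obs[[s]])) / (n_perm + 1)
  }, numeric(1))
  up <- (1 + sum(null$SkR2k >= obs$SkR2k)) / (n_perm + 1)
  lo <- (1 + sum(null$SkR2k <= obs$SkR2k)) / (n_perm + 1)
  pv <- c(pv, SkR2k = min(1, 2 * min(up, lo)))
  pv <- pv[c("R2Max", "SkR2k", "Dmax", "SCE")]

  cum_perm <- apply(R2p, 2, cumsum)
  if (nrow(R2p) == 1L) cum_perm <- matrix(cum_perm, nrow = 1L)
  structure(list(
    r2 = r2,
    cumulative = cumsum(r2),
    stats = obs,
    pvalues = as.list(pv),
    r2_upper_envelope = apply(R2p, 1, stats::quantile, probs = 1 - alpha,
                              names = FALSE),
    cumulative_envelope = apply(cum_perm, 1, stats::quantile,
                                probs = c(alpha / 2, 1 - alpha / 2),
                                names = FALSE),
    node_of_column = basis$node_of_column,
    np_of_column = basis$np_of_column,
    n_perm = as.integer(n_perm),
    alpha = alpha,
    seed = seed,
    tails = c(R2Max = "upper", SkR2k = "two-sided", Dmax = "upper",
              SCE = "upper")
  ), class = "orthogram")
}

#' @export
print.orthogram <- function(x, ...) {
  cat("Orthonormal decomposition of trait variance (topology-only)\n")
  cat(sprintf("  %d tips, %d basis columns, %d permutations%s\n",
              length(x$r2) + 1L, length(x$r2), x$n_perm,
              if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  st <- x$stats
  pv <- x$pvalues
  for (s in c("R2Max", "SkR2k", "Dmax", "SCE")) {
    cat(sprintf("  %-6s = %8.4f   p = %.4f (%s)\n", s, st[[s]], pv[[s]],
                x$tails[[s]]))
  }
  sig <- significant_nodes(x)
  if (nrow(sig)) {
    cat("  nodes above the upper envelope:",
        paste(sprintf("%d (np=%d, R2=%.3f)", sig$node, sig$np, sig$r2),
              collapse = ", "), "\n")
  } else cat("  no node exceeds the upper envelope\n")
  invisible(x)
}

#' Nodes whose variance share exceeds the permutation envelope
#'
#' @param result an `orthogram` object from [orthogram_test()].
#' @return a data.frame with columns `column`, `node`, `np`, `r2`, sorted by
#'   decreasing `r2`; zero rows when no bar exceeds its pointwise upper
#'   envelope.
#' @export
significant_nodes <- function(result) {
  stopifnot(inherits(result, "orthogram"))
  hit <- which(result$r2 > result$r2_upper_envelope)
  out <- data.frame(column = hit,
                    node = result$node_of_column[hit],
                    np = result$np_of_column[hit],
                    r2 = result$r2[hit])
  out[order(-out$r2), , drop = FALSE]
}
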