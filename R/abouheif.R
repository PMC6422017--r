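#' Abouheif phylogenetic proximity matrix
#'
#' Builds the tips-by-tips proximity matrix that encodes a rooted cladogram's
#' topology for autocorrelation testing. For distinct tips i and j the
#' proximity is the product, over every internal node v on the tree path
#' between them (their most recent common ancestor included), of one over the
#' number of direct descendants of v. The diagonal is filled so every row
#' sums to one exactly; since the matrix is symmetric it is bistochastic.
#' Sister tips under a bifurcation get proximity 1/2; tips separated by many
#' or highly multifurcating nodes get proximities shrinking geometrically.
#'
#' @param tree a validated `phylo` object with at least 3 tips.
#' @return square numeric matrix with rows/columns named by tip label.
#' @examples
#' w <- abouheif_proximity(read_topology("((A,B),C);"))
#' w["A", "B"]   # 1/2
#' @export
abouheif_proximity <- function(tree) {
  validate_topology(tree)
  n <- ape::Ntip(tree)
  if (n < 3L) stop("proximity matrix requires at least 3 tips")
  dd <- vapply(seq_len(tree$Nnode) + n,
               function(v) sum(tree$edge[, 1] == v), integer(1))
  names(dd) <- as.character(seq_len(tree$Nnode) + n)
  W <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      path <- tip_path_internal_nodes(tree, i, j)
      w <- prod(1 / dd[as.character(path)])
      W[i, j] <- W[j, i] <- w
    }
  }
  diag(W) <- 1 - rowSums(W)
  if (any(diag(W) < -1e-12))
    stop("internal error: negative diagonal in proximity matrix")
  W
}

#' Abouheif's C-mean autocorrelation statistic
#'
#' A Moran-type autocorrelation of a tip trait under the Abouheif proximity
#' weighting: with z the centered trait, C = (z' W z) / (z' z). Zero expected
#' under no phylogenetic structure; positive when proximate tips have similar
#' values. Invariant to shifting and positive rescaling of the trait.
#'
#' @param x numeric tip trait (named by tip label, or aligned with the matrix
#'   row order).
#' @param w proximity matrix from [abouheif_proximity()].
#' @return scalar C-mean value.
#' @export
c_mean <- function(x, w) {
  if (length(x) != nrow(w))
    stop(sprintf("trait has length %d but the proximity matrix has %d tips",
                 length(x), nrow(w)))
  if (!is.null(names(x))) {
    if (!setequal(names(x), rownames(w)))
      stop("trait names do not match the proximity matrix tip labels")
    x <- x[rownames(w)]
  }
  if (anyNA(x)) stop("trait contains missing values")
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom == 0) stop("trait is constant across tips")
  as.numeric(crossprod(z, w %*% z)) / denom
}

#' Permutation test of Abouheif's C-mean
#'
#' Tests the null hypothesis of no phylogenetic autocorrelation (C-mean equal
#' to zero) by permuting the trait across tips. The test is upper-tailed:
#' phylogenetic signal manifests as positive autocorrelation.
#'
#' @param x numeric tip trait.
#' @param tree a validated `phylo` object.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed, or `NULL`.
#' @return an object of class `cmean_test` with elements `c_mean`, `pvalue`,
#'   `n_perm`, `seed`, and `perm_summary` (mean, sd and quantiles of the null
#'   distribution).
#' @export
c_mean_test <- function(x, tree, n_perm = 999L, seed = NULL) {
  if (n_perm < 99L) stop("n_perm must be at least 99")
  w <- abouheif_proximity(tree)
  obs <- c_mean(x, w)
  if (!is.null(names(x))) x <- x[rownames(w)]
  z <- x - mean(x)
  if (!is.null(seed)) set.seed(seed)
  n <- length(z)
  Z <- vapply(seq_len(n_perm), function(i) z[sample.int(n)], numeric(n))
  null <- colSums(Z * (w %*% Z)) / sum(z^2)
  p <- (1 + sum(null >= obs)) / (n_perm + 1)
  structure(list(
    c_mean = obs,
    pvalue = p,
    n_perm = as.integer(n_perm),
    seed = seed,
    perm_summary = c(mean = mean(null), sd = stats::sd(null),
                     stats::quantile(null, c(0.025, 0.5, 0.975)))
  ), class = "cmean_test")
}

#' @export
print.cmean_test <- function(x, ...) {
  cat(sprintf("Abouheif C-mean = %.4f, p = %.4f (%d permutations, upper tail)\n",
              x$c_mean, x$pvalue, x$n_perm))
  invisible(x)
}
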