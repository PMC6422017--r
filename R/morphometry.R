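#' Read two-dimensional landmark configurations from a TPS file
#'
#' Parses the plain-text TPS dialect used by landmark digitizing software:
#' each record starts with `LM=k`, followed by k lines of x y coordinates and
#' optional `ID=`, `IMAGE=` and `SCALE=` lines. A `SCALE=` factor multiplies
#' the record's coordinates. The specimen identifier comes from `ID=`, else
#' `IMAGE=`, else the 0-based record index. All records in a file must share
#' the same landmark count.
#'
#' @param file path to a TPS file.
#' @return named list of k x 2 numeric matrices, one per specimen.
#' @export
read_tps <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines)]
  configs <- list()
  i <- 1L
  rec <- 0L
  k_expected <- NA_integer_
  while (i <= length(lines)) {
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE))
      stop(sprintf("record %d: expected 'LM=' line, got '%s'", rec, lines[i]))
    k <- as.integer(sub("^LM\\s*=\\s*", "", lines[i], ignore.case = TRUE))
    if (is.na(k) || k < 1L)
      stop(sprintf("record %d: invalid landmark count in '%s'", rec, lines[i]))
    if (!is.na(k_expected) && k != k_expected)
      stop(sprintf("record %d has LM=%d but earlier records have LM=%d: landmark counts must match across a dataset",
                   rec, k, k_expected))
    k_expected <- k
    i <- i + 1L
    coords <- matrix(NA_real_, k, 2)
    for (l in seq_len(k)) {
      if (i > length(lines) || grepl("^(LM|ID|IMAGE|SCALE)\\s*=", lines[i],
                                     ignore.case = TRUE))
        stop(sprintf("record %d: LM=%d but only %d coordinate line(s) found",
                     rec, k, l - 1L))
      xy <- suppressWarnings(as.numeric(strsplit(lines[i], "[ \t,]+")[[1]]))
      if (length(xy) != 2L || anyNA(xy))
        stop(sprintf("record %d, landmark %d: cannot parse coordinates '%s'",
                     rec, l, lines[i]))
      coords[l, ] <- xy
      i <- i + 1L
    }
    id <- NULL
    image <- NULL
    scale <- 1
    while (i <= length(lines) &&
           grepl("^(ID|IMAGE|SCALE)\\s*=", lines[i], ignore.case = TRUE)) {
      key <- toupper(sub("\\s*=.*$", "", lines[i]))
      val <- sub("^[^=]*=\\s*", "", lines[i])
      if (key == "ID") id <- val
      if (key == "IMAGE") image <- val
      if (key == "SCALE") {
        scale <- suppressWarnings(as.numeric(val))
        if (is.na(scale) || scale <= 0)
          stop(sprintf("record %d: invalid SCALE '%s'", rec, val))
      }
      i <- i + 1L
    }
    if (is.null(id)) id <- if (!is.null(image)) image else as.character(rec)
    if (any(!is.finite(coords)))
      stop(sprintf("record %d: non-finite coordinates", rec))
    configs[[id]] <- coords * scale
    rec <- rec + 1L
  }
  if (!length(configs)) stop("no TPS records found")
  if (anyDuplicated(names(configs)))
    stop("duplicate specimen identifiers in TPS file")
  configs
}

#' Write landmark configurations to a TPS file
#'
#' @param configs named list of k x 2 matrices.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_tps <- function(configs, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (id in names(configs)) {
    m <- configs[[id]]
    writeLines(sprintf("LM=%d", nrow(m)), con)
    writeLines(sprintf("%.10g %.10g", m[, 1], m[, 2]), con)
    writeLines(sprintf("ID=%s", id), con)
  }
  invisible(file)
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks to their
#' centroid -- the standard geometric-morphometric size measure, which scales
#' linearly with the configuration.
#'
#' @param config a k x 2 numeric matrix, k >= 2.
#' @return scalar centroid size.
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 2L) stop("centroid size requires at least 2 landmarks")
  c0 <- colMeans(config)
  sqrt(sum(sweep(config, 2, c0)^2))
}

#' Generalized Procrustes superimposition of 2-D landmark configurations
#'
#' Removes position, scale and orientation: every configuration is translated
#' to centroid origin and scaled to unit centroid size, then iteratively
#' rotated (orthogonal Procrustes, reflections disallowed) to the current
#' mean shape until the mean stabilizes. Centroid sizes are recorded from the
#' raw configurations before scaling, so size can be analysed separately.
#'
#' @param configs named list of k x 2 matrices with a common k, length >= 2.
#' @param tol convergence tolerance on the Frobenius change of the mean shape
#'   (default 1e-10).
#' @param max_iter maximum rotation sweeps (default 100).
#' @return an object of class `gpa_fit`: list with `aligned` (n x k x 2
#'   array), `centroid_sizes` (named vector), `mean_shape` (k x 2),
#'   `iterations`, `converged`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L) {
  if (length(configs) < 2L) stop("GPA requires at least 2 configurations")
  ks <- vapply(configs, nrow, integer(1))
  if (length(unique(ks)) != 1L)
    stop("all configurations must have the same number of landmarks")
  k <- ks[1]
  if (k < 3L) stop("GPA requires at least 3 landmarks")
  ids <- names(configs)
  if (is.null(ids)) ids <- as.character(seq_along(configs))
  cs <- vapply(configs, centroid_size, numeric(1))
  names(cs) <- ids
  zero <- cs < .Machine$double.eps
  if (any(zero))
    stop(sprintf("degenerate (zero centroid size) configuration(s): %s",
                 paste(ids[zero], collapse = ", ")))
  X <- lapply(configs, function(m) {
    m <- sweep(as.matrix(m), 2, colMeans(m))
    m / sqrt(sum(m^2))
  })
  # the rotation step is invariant to the target's scale, so the running mean
  # is kept as the plain coordinate-wise mean of the aligned configurations
  mean_shape <- Reduce(`+`, X) / length(X)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    X <- lapply(X, rotate_onto, target = mean_shape)
    new_mean <- Reduce(`+`, X) / length(X)
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  aligned <- array(0, dim = c(length(X), k, 2),
                   dimnames = list(ids, NULL, c("x", "y")))
  for (i in seq_along(X)) aligned[i, , ] <- X[[i]]
  structure(list(aligned = aligned, centroid_sizes = cs,
                 mean_shape = mean_shape, iterations = it,
                 converged = converged),
            class = "gpa_fit")
}

# optimal rotation of a centered configuration onto a centered target,
# reflections excluded (determinant forced to +1)
rotate_onto <- function(config, target) {
  s <- svd(crossprod(config, target))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  config %*% R
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(sprintf("Procrustes superimposition: %d specimens, %d landmarks, %d iteration(s)%s\n",
              dim(x$aligned)[1], dim(x$aligned)[2], x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Principal component analysis of Procrustes shape coordinates
#'
#' Flattens the aligned configurations to a specimens x 2k matrix and
#' performs a covariance PCA (the shape-analysis convention: coordinates
#' share units, so no correlation scaling). In 2-D, four dimensions
#' (two translations, one rotation, one size) are removed by the
#' superimposition, so at most 2k - 4 components carry variance.
#'
#' @param fit a `gpa_fit` from [gpa()].
#' @return an object of class `shape_pca`: list with `scores` (specimens x
#'   components, zero column means), `explained_fraction`, `loadings`
#'   (2k x components), `center` (the flattened mean), `k`.
#' @export
shape_pca <- function(fit) {
  stopifnot(inherits(fit, "gpa_fit"))
  n <- dim(fit$aligned)[1]
  if (n < 3L) stop("shape PCA requires at least 3 specimens")
  k <- dim(fit$aligned)[2]
  flat <- matrix(fit$aligned, nrow = n)   # columns: x1..xk, y1..yk
  rownames(flat) <- dimnames(fit$aligned)[[1]]
  pc <- stats::prcomp(flat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(scores = pc$x,
                 explained_fraction = ev / sum(ev),
                 loadings = pc$rotation,
                 center = pc$center,
                 k = k),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  pct <- 100 * x$explained_fraction
  m <- min(5L, length(pct))
  cat("Shape PCA:",
      paste(sprintf("PC%d %.1f%%", seq_len(m), pct[seq_len(m)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate specimen-level values to species (tip) level
#'
#' Multi-specimen species are mapped onto single tree tips by averaging:
#' the per-species mean of each column.
#'
#' @param values numeric matrix or data.frame, rows named by specimen id.
#' @param species named character vector mapping specimen id -> species/tip
#'   label.
#' @return numeric matrix with one row per species, rows named by species.
#' @export
aggregate_by_species <- function(values, species) {
  values <- as.matrix(values)
  ids <- rownames(values)
  if (is.null(ids)) stop("`values` must have specimen ids as row names")
  missing <- setdiff(ids, names(species))
  if (length(missing))
    stop(sprintf("no species mapping for specimen(s): %s",
                 paste(missing, collapse = ", ")))
  sp <- species[ids]
  out <- apply(values, 2, function(col) tapply(col, sp, mean))
  if (is.null(dim(out)))
    out <- matrix(out, ncol = ncol(values),
                  dimnames = list(unique(sp), colnames(values)))
  out
}
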