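#' Basicranium / skull length ratios per specimen and species
#'
#' Computes the ratio of basicranium anteroposterior length (bsL) to total
#' skull anteroposterior length (stL) for each specimen. The ratio describes
#' what share of the skull the basicranium occupies. Specimens with a missing
#' stL (incomplete fossils) are dropped, with the count reported via a
#' message. Species means are returned alongside the specimen records.
#'
#' @param measurements data.frame with columns `specimen_id`, `species`,
#'   `subfamily`, `bsL`, `stL` (consistent length units).
#' @return list with `records` (the input rows retained, plus `ratio`),
#'   `species_means` (data.frame: `species`, `subfamily`, `mean_ratio`, `n`),
#'   and `n_dropped`.
#' @export
compute_ratios <- function(measurements) {
  required <- c("specimen_id", "species", "subfamily", "bsL", "stL")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols))
    stop(sprintf("measurement table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  m <- measurements
  drop <- is.na(m$stL)
  if (any(drop)) {
    message(sprintf("dropped %d specimen(s) with missing skull length", sum(drop)))
    m <- m[!drop, , drop = FALSE]
  }
  bad <- which(is.na(m$bsL) | m$bsL <= 0 | m$stL <= 0)
  if (length(bad))
    stop(sprintf("nonpositive or missing measurement for specimen(s): %s",
                 paste(m$specimen_id[bad], collapse = ", ")))
  over <- which(m$bsL > m$stL)
  if (length(over))
    stop(sprintf("bsL exceeds stL for specimen(s): %s",
                 paste(m$specimen_id[over], collapse = ", ")))
  m$ratio <- m$bsL / m$stL
  sm <- do.call(rbind, lapply(split(m, m$species), function(g) {
    data.frame(species = g$species[1], subfamily = g$subfamily[1],
               mean_ratio = mean(g$ratio), n = nrow(g))
  }))
  rownames(sm) <- NULL
  list(records = m, species_means = sm, n_dropped = sum(drop))
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper over [stats::kruskal.test()] taking a named list of numeric
#' vectors; the H statistic is tie-corrected and compared to a chi-square
#' distribution on (number of groups - 1) degrees of freedom.
#'
#' @param groups named list of numeric vectors, at least 2 groups of >= 2
#'   values each.
#' @return list with `H`, `df`, `pvalue`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stop("every group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       pvalue = kt$p.value)
}

#' Pairwise Wilcoxon rank-sum tests with multiplicity adjustment
#'
#' Two-sided rank-sum test for each unordered pair of groups via
#' [stats::pairwise.wilcox.test()]: the exact null distribution is used for
#' small tie-free samples, the tie-corrected normal approximation otherwise.
#' P-values are adjusted across pairs (Holm step-down by default).
#'
#' @param groups named list of numeric vectors, at least 2 non-empty groups.
#' @param adjustment adjustment method passed to [stats::p.adjust()]
#'   (default `"holm"`).
#' @return list with `pairwise` (lower-triangular matrix of adjusted
#'   p-values, as returned by `pairwise.wilcox.test`) and `adjustment`.
#' @export
pairwise_wilcoxon <- function(groups, adjustment = "holm") {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) == 0L)) stop("empty group supplied")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(values, g, p.adjust.method = adjustment,
                                exact = NULL)
  )
  list(pairwise = pw$p.value, adjustment = adjustment)
}

#' Subfamily comparison of skull ratios
#'
#' Runs the Kruskal-Wallis test across subfamilies and pairwise Wilcoxon
#' rank-sum tests (Holm-adjusted) on specimen-level ratios.
#'
#' @param ratios output of [compute_ratios()], or a data.frame with `ratio`
#'   and `subfamily` columns.
#' @param adjustment pairwise adjustment method (default `"holm"`).
#' @return list with `kw` (H, df, pvalue), `pairwise`, `adjustment`,
#'   `group_medians`.
#' @export
ratio_group_test <- function(ratios, adjustment = "holm") {
  rec <- if (is.list(ratios) && !is.null(ratios$records)) ratios$records else ratios
  if (!all(c("ratio", "subfamily") %in% names(rec)))
    stop("need `ratio` and `subfamily` columns")
  groups <- split(rec$ratio, rec$subfamily)
  kw <- kruskal_wallis(groups)
  pw <- pairwise_wilcoxon(groups, adjustment)
  list(kw = kw, pairwise = pw$pairwise, adjustment = adjustment,
       group_medians = vapply(groups, stats::median, numeric(1)))
}
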