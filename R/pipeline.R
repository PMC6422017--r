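#' Screen a set of tip traits for phylogenetic signal
#'
#' Runs, for every requested trait column, both topology-only signal tests --
#' the orthonormal decomposition ([orthogram_test()]) and Abouheif's C-mean
#' ([c_mean_test()]) -- and combines them into a per-trait verdict: a trait
#' shows "signal" when at least two of the four orthogram statistics are
#' significant at `alpha`, or when the C-mean test is. Individual statistic
#' values and p-values are always returned so any other rule can be applied.
#'
#' @param tree a validated `phylo` object.
#' @param traits data.frame or matrix of numeric tip traits; rows named by
#'   tip label (or a `tip_label` column).
#' @param variables columns to test (default: all numeric columns).
#' @param n_perm permutations per test (default 999).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed; per-variable sub-seeds are derived from it so
#'   adding a variable does not perturb the others. `NULL` for current RNG.
#' @param policy `"strict"` (tip sets must match exactly) or `"prune"` (drop
#'   tree tips without trait rows, with a message).
#' @return an object of class `signal_screen`: list with `summary` (one row
#'   per variable: statistics, p-values, verdict), `orthograms`, `cmeans`,
#'   `significant_nodes` (lists keyed by variable), `alpha`, `n_perm`,
#'   `seed`, `tree`.
#' @export
run_signal_screen <- function(tree, traits, variables = NULL,
                              n_perm = 999L, alpha = 0.05, seed = NULL,
                              policy = c("strict", "prune")) {
  policy <- match.arg(policy)
  validate_topology(tree)
  traits <- as.data.frame(traits)
  if ("tip_label" %in% names(traits)) {
    rownames(traits) <- traits$tip_label
    traits$tip_label <- NULL
  }
  if (is.null(rownames(traits)))
    stop("traits must carry tip labels as row names or a `tip_label` column")
  extra <- setdiff(rownames(traits), tree$tip.label)
  if (length(extra))
    stop(sprintf("trait rows not present in the tree: %s",
                 paste(extra, collapse = ", ")))
  absent <- setdiff(tree$tip.label, rownames(traits))
  if (length(absent)) {
    if (policy == "strict")
      stop(sprintf("tree tip(s) missing from the trait table: %s",
                   paste(absent, collapse = ", ")))
    message(sprintf("pruning %d tree tip(s) without trait rows: %s",
                    length(absent), paste(absent, collapse = ", ")))
    tree <- ape::drop.tip(tree, absent)
    tree$edge.length <- NULL
    validate_topology(tree)
  }
  if (is.null(variables))
    variables <- names(traits)[vapply(traits, is.numeric, logical(1))]
  if (!length(variables)) stop("no numeric trait columns to test")
  missing_vars <- setdiff(variables, names(traits))
  if (length(missing_vars))
    stop(sprintf("trait column(s) not found: %s",
                 paste(missing_vars, collapse = ", ")))

  orthograms <- list()
  cmeans <- list()
  signif <- list()
  rows <- list()
  for (i in seq_along(variables)) {
    v <- variables[i]
    x <- stats::setNames(traits[tree$tip.label, v], tree$tip.label)
    sub_seed <- if (is.null(seed)) NULL else (seed + 1000L * i) %% 2147483647L
    og <- orthogram_test(x, tree, n_perm = n_perm, seed = sub_seed,
                         alpha = alpha)
    cm <- c_mean_test(x, tree, n_perm = n_perm,
                      seed = if (is.null(sub_seed)) NULL else sub_seed + 1L)
    sig_nodes <- significant_nodes(og)
    n_og_sig <- sum(unlist(og$pvalues) <= alpha)
    verdict <- if (n_og_sig >= 2L || cm$pvalue <= alpha) "signal" else "no signal"
    orthograms[[v]] <- og
    cmeans[[v]] <- cm
    signif[[v]] <- sig_nodes
    rows[[v]] <- data.frame(
      variable = v,
      R2Max = og$stats$R2Max, p_R2Max = og$pvalues$R2Max,
      SkR2k = og$stats$SkR2k, p_SkR2k = og$pvalues$SkR2k,
      Dmax = og$stats$Dmax, p_Dmax = og$pvalues$Dmax,
      SCE = og$stats$SCE, p_SCE = og$pvalues$SCE,
      Cmean = cm$c_mean, p_Cmean = cm$pvalue,
      n_orthogram_significant = n_og_sig,
      verdict = verdict,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(summary = summary, orthograms = orthograms, cmeans = cmeans,
                 significant_nodes = signif, alpha = alpha,
                 n_perm = as.integer(n_perm), seed = seed, tree = tree),
            class = "signal_screen")
}

#' @export
print.signal_screen <- function(x, ...) {
  cat(sprintf("Phylogenetic signal screen: %d variable(s), %d tips, %d permutations, alpha %.2f\n",
              nrow(x$summary), ape::Ntip(x$tree), x$n_perm, x$alpha))
  df <- x$summary
  df[] <- lapply(df, function(col) if (is.numeric(col)) signif(col, 3) else col)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Run the full topology-only analysis
#'
#' Orchestrates every stage the package provides on one dataset: the signal
#' screen over the requested variables, squared-change (or linear)
#' reconstruction of ancestral landmark configurations when landmark data are
#' supplied, Fitch optimization of a binary habitat character when codings
#' are supplied, and subfamily ratio tests when measurements are supplied.
#' When `output_dir` is given, machine-readable artifacts are written:
#' `report.json`, per-variable orthogram CSVs, a TPS file of reconstructed
#' node shapes, and a CSV of Fitch node states.
#'
#' @param tree a validated `phylo` object.
#' @param traits tip trait table for [run_signal_screen()].
#' @param variables trait columns to screen (default all numeric).
#' @param landmarks optional named list of superimposed tip configurations
#'   for [reconstruct_landmarks()].
#' @param habitat optional named binary vector for [fitch_optimize()].
#' @param measurements optional specimen table for [compute_ratios()].
#' @param n_perm,alpha,seed,policy as in [run_signal_screen()].
#' @param criterion ancestral-shape criterion (`"squared"` or `"linear"`).
#' @param adjustment pairwise p-value adjustment for the ratio tests.
#' @param output_dir optional directory for output artifacts.
#' @return an object of class `cladosig_report`: list with `screen`,
#'   `ancestral`, `fitch`, `ratios`, `ratio_tests`, `config`.
#' @export
run_full <- function(tree, traits, variables = NULL,
                     landmarks = NULL, habitat = NULL, measurements = NULL,
                     n_perm = 999L, alpha = 0.05, seed = NULL,
                     policy = c("strict", "prune"),
                     criterion = c("squared", "linear"),
                     adjustment = "holm", output_dir = NULL) {
  policy <- match.arg(policy)
  criterion <- match.arg(criterion)
  screen <- run_signal_screen(tree, traits, variables, n_perm = n_perm,
                              alpha = alpha, seed = seed, policy = policy)
  anc <- NULL
  if (!is.null(landmarks))
    anc <- reconstruct_landmarks(screen$tree, landmarks, criterion = criterion)
  fit <- NULL
  if (!is.null(habitat))
    fit <- fitch_optimize(screen$tree, habitat)
  rat <- NULL
  rat_test <- NULL
  if (!is.null(measurements)) {
    rat <- compute_ratios(measurements)
    rat_test <- ratio_group_test(rat, adjustment = adjustment)
  }
  config <- list(n_perm = as.integer(n_perm), alpha = alpha, seed = seed,
                 policy = policy, criterion = criterion,
                 adjustment = adjustment,
                 version = as.character(utils::packageVersion("cladosig")))
  report <- structure(list(screen = screen, ancestral = anc, fitch = fit,
                           ratios = rat, ratio_tests = rat_test,
                           config = config),
                      class = "cladosig_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.cladosig_report <- function(x, ...) {
  print(x$screen)
  if (!is.null(x$ancestral)) print(x$ancestral)
  if (!is.null(x$fitch)) print(x$fitch)
  if (!is.null(x$ratio_tests))
    cat(sprintf("Ratio Kruskal-Wallis: H = %.3f, df = %d, p = %.4g\n",
                x$ratio_tests$kw$H, x$ratio_tests$kw$df, x$ratio_tests$kw$pvalue))
  invisible(x)
}

# serialize a full report to output_dir: report.json + per-variable CSVs +
# TPS node shapes + Fitch state CSV
write_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  screen <- report$screen
  utils::write.csv(screen$summary,
                   file.path(output_dir, "signal_summary.csv"),
                   row.names = FALSE)
  for (v in names(screen$orthograms)) {
    og <- screen$orthograms[[v]]
    utils::write.csv(
      data.frame(column = seq_along(og$r2), node = og$node_of_column,
                 np = og$np_of_column, r2 = og$r2,
                 cumulative = og$cumulative,
                 r2_upper_envelope = og$r2_upper_envelope),
      file.path(output_dir, sprintf("orthogram_%s.csv", v)),
      row.names = FALSE)
  }
  if (!is.null(report$ancestral))
    write_tps(report$ancestral$node_configs,
              file.path(output_dir, "ancestral_shapes.tps"))
  if (!is.null(report$fitch))
    utils::write.csv(
      data.frame(node = names(report$fitch$assignment),
                 state = report$fitch$levels[report$fitch$assignment + 1L]),
      file.path(output_dir, "fitch_states.csv"), row.names = FALSE)
  json <- list(
    config = report$config,
    summary = screen$summary,
    pvalues = lapply(screen$orthograms, function(o) o$pvalues),
    cmean = lapply(screen$cmeans, function(cm)
      list(c_mean = cm$c_mean, pvalue = cm$pvalue)),
    significant_nodes = screen$significant_nodes,
    tree_score = if (!is.null(report$ancestral)) report$ancestral$tree_score,
    fitch_steps = if (!is.null(report$fitch)) report$fitch$steps,
    kruskal_wallis = if (!is.null(report$ratio_tests)) report$ratio_tests$kw)
  jsonlite::write_json(json, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  invisible(output_dir)
}
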