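#' Read a rooted, topology-only tree from Newick text or a file
#'
#' Parses a single Newick description into an [ape::phylo] object and
#' validates it for topology-only analysis: a unique root, internal nodes of
#' out-degree at least two (polytomies allowed), and unique non-empty tip
#' labels. Branch lengths, if present in the input, are dropped with a
#' warning -- every method in this package reads the cladogram topology only.
#'
#' @param text a Newick string ending in `;`, or `NULL` if `file` is given.
#' @param file path to a file containing a single Newick tree.
#' @return a rooted `phylo` object with no `edge.length` component.
#' @examples
#' tr <- read_topology("((A,B),C);")
#' ape::Ntip(tr)
#' @export
read_topology <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file))
    stop("supply either `text` or `file`")
  if (is.null(text)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  if (!nzchar(text))
    stop("empty Newick input")
  # locate unbalanced parentheses before handing off to the parser, so the
  # error can name the offending position
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("unbalanced ')' at position %d in Newick input", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("Newick input has %d unclosed '(' parenthes%s", depth,
                 if (depth == 1L) "is" else "es"))
  if (!grepl(";\\s*$", text))
    stop("Newick description must end in ';'")
  tree <- ape::read.tree(text = text)
  if (is.null(tree))
    stop("could not parse Newick input")
  if (!is.null(tree$edge.length)) {
    warning("branch lengths present in input were dropped: analyses are topology-only")
    tree$edge.length <- NULL
  }
  validate_topology(tree)
  tree
}

#' Validate a tree for topology-only analysis
#'
#' Checks the invariants every downstream statistic assumes: rooted, one
#' parent per non-root node, internal out-degree >= 2, unique non-empty tip
#' labels. Called by [read_topology()] and by the simulators; exported so
#' user-constructed `phylo` objects can be checked the same way.
#'
#' @param tree a `phylo` object.
#' @return `tree`, invisibly, if valid; otherwise an error.
#' @export
validate_topology <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("`tree` must be a `phylo` object")
  n <- ape::Ntip(tree)
  if (n < 2L)
    stop("tree must have at least 2 tips")
  labs <- tree$tip.label
  if (anyNA(labs) || any(!nzchar(labs)))
    stop("tip labels must be non-empty")
  if (anyDuplicated(labs))
    stop(sprintf("duplicate tip label(s): %s",
                 paste(unique(labs[duplicated(labs)]), collapse = ", ")))
  parent <- tree$edge[, 1]
  child  <- tree$edge[, 2]
  all_nodes <- seq_len(n + tree$Nnode)
  indeg <- tabulate(child, nbins = n + tree$Nnode)
  roots <- all_nodes[indeg == 0L]
  if (length(roots) != 1L || roots[1] <= n)
    stop(sprintf("tree must have exactly one (internal) root, found %d parentless node(s)",
                 length(roots)))
  if (any(indeg > 1L))
    stop("some node has more than one parent")
  outdeg <- tabulate(parent, nbins = n + tree$Nnode)
  internal <- (n + 1L):(n + tree$Nnode)
  if (any(outdeg[internal] < 2L))
    stop("every internal node must have at least 2 children (collapse singleton nodes first)")
  invisible(tree)
}

#' Number of tips descending from each node
#'
#' The node "complexity" np: 1 for tips, the total tip count for the root,
#' and the sum over children for any internal node. Basal nodes have high np,
#' terminal ones low np; the orthogram is conventionally read along
#' decreasing np.
#'
#' @param tree a validated `phylo` object.
#' @return integer vector of length `Ntip + Nnode`, indexed by node id.
#' @export
node_complexity <- function(tree) {
  n <- ape::Ntip(tree)
  np <- c(rep(1L, n), integer(tree$Nnode))
  # postorder edge walk accumulates child counts into parents
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (e in seq_len(nrow(edge))) {
    np[edge[e, 1]] <- np[edge[e, 1]] + np[edge[e, 2]]
  }
  np
}

# Canonical ordering of internal node ids: decreasing np, ties broken by
# preorder (root-first, cladewise) traversal rank. All per-node outputs
# (orthobasis columns, orthogram bars) follow this order.
internal_node_order <- function(tree) {
  n <- ape::Ntip(tree)
  internal <- (n + 1L):(n + tree$Nnode)
  np <- node_complexity(tree)
  edge <- tree$edge[ape::reorder.phylo(tree, "cladewise", index.only = TRUE), ,
                    drop = FALSE]
  pre_rank <- integer(n + tree$Nnode)
  seen <- unique(as.vector(t(edge[, c(1, 2)])))
  pre_rank[seen] <- seq_along(seen)
  internal[order(-np[internal], pre_rank[internal])]
}

#' Tip-by-node clade membership indicator matrix
#'
#' @param tree a validated `phylo` object.
#' @return a 0/1 matrix with one row per tip (named by tip label) and one
#'   column per internal node in canonical order (decreasing np, preorder
#'   tie-break), named by node id; entry 1 iff the tip descends from the node.
#'   The root column is all ones.
#' @export
clade_membership <- function(tree) {
  n <- ape::Ntip(tree)
  nodes <- internal_node_order(tree)
  children <- children_list(tree)
  M <- matrix(0L, n, length(nodes),
              dimnames = list(tree$tip.label, as.character(nodes)))
  tipsets <- descendant_tip_sets(tree)
  for (j in seq_along(nodes)) M[tipsets[[as.character(nodes[j])]], j] <- 1L
  M
}

# list: internal node id (character) -> integer vector of descendant tips
descendant_tip_sets <- function(tree) {
  n <- ape::Ntip(tree)
  sets <- vector("list", tree$Nnode)
  names(sets) <- as.character((n + 1L):(n + tree$Nnode))
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  acc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) acc[[i]] <- i
  for (e in seq_len(nrow(edge))) {
    acc[[edge[e, 1]]] <- c(acc[[edge[e, 1]]], acc[[edge[e, 2]]])
  }
  for (v in (n + 1L):(n + tree$Nnode)) sets[[as.character(v)]] <- sort(acc[[v]])
  sets
}

# list: node id -> integer vector of direct children, in edge (input) order
children_list <- function(tree) {
  n <- ape::Ntip(tree)
  out <- vector("list", n + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    out[[tree$edge[e, 1]]] <- c(out[[tree$edge[e, 1]]], tree$edge[e, 2])
  }
  out
}

#' Number of direct descendants (children) of an internal node
#'
#' @param tree a validated `phylo` object.
#' @param node internal node id (integer, > `Ntip(tree)`).
#' @return integer out-degree, always >= 2 for a valid tree.
#' @export
direct_descendant_count <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n || node > n + tree$Nnode)
    stop(sprintf("node %d is not an internal node of this tree", node))
  sum(tree$edge[, 1] == node)
}

#' Internal nodes on the path between two tips
#'
#' Returns the internal nodes lying on the unique tree path between two tips,
#' each once, always including their most recent common ancestor. These node
#' sets, combined with direct-descendant counts, define the Abouheif
#' phylogenetic proximity.
#'
#' @param tree a validated `phylo` object.
#' @param tip_a,tip_b tip labels (or tip ids), distinct.
#' @return integer vector of internal node ids.
#' @export
tip_path_internal_nodes <- function(tree, tip_a, tip_b) {
  a <- resolve_tip(tree, tip_a)
  b <- resolve_tip(tree, tip_b)
  if (a == b) stop("tip_a and tip_b must be distinct tips")
  pa <- ancestor_chain(tree, a)
  pb <- ancestor_chain(tree, b)
  common <- intersect(pa, pb)
  mrca <- common[1]  # chains are ordered node -> root; first shared is MRCA
  union(c(setdiff(pa, common), setdiff(pb, common)), mrca)
}

# internal ancestors of a node, ordered from its parent up to the root
ancestor_chain <- function(tree, node) {
  parent <- integer(ape::Ntip(tree) + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  out <- integer(0)
  v <- node
  while (parent[v] != 0L) {
    v <- parent[v]
    out <- c(out, v)
  }
  out
}

resolve_tip <- function(tree, tip) {
  if (is.character(tip)) {
    i <- match(tip, tree$tip.label)
    if (is.na(i)) stop(sprintf("unknown tip label '%s'", tip))
    return(i)
  }
  tip <- as.integer(tip)
  if (tip < 1L || tip > ape::Ntip(tree))
    stop(sprintf("tip id %d out of range", tip))
  tip
}
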