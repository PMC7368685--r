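# Combinatorial algebra on phylogenetic trees: Newick round-trip,
# bipartitions, Robinson-Foulds distance, quartet agreement, NNI
# rearrangement and ultrametricization. Trees are ape "phylo" objects.

#' Parse a single Newick statement
#'
#' Thin validating wrapper around [ape::read.tree()]. Branch lengths absent
#' from the input are filled with a configurable constant so that
#' topology-only trees (e.g. coalescent-unit topologies) remain usable by
#' downstream length-consuming code.
#'
#' @param text A single Newick statement terminated by ";".
#' @param default_blen Branch length assigned to edges with none in the input.
#' @return A `phylo` tree.
#' @export
parse_newick <- function(text, default_blen = 1.0) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick string")
  if (!endsWith(text, ";")) stop("Newick statement must end with ';'")
  op <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  cl <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (op != cl)
    stop("unbalanced parentheses: ", op, " '(' vs ", cl, "')' in Newick at position ",
         nchar(text))
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || inherits(tr, "multiPhylo"))
    stop("failed to parse Newick (expected exactly one tree): ", text)
  if (is.null(tr$tip.label) || length(tr$tip.label) < 2L)
    stop("tree must have at least 2 tips")
  bad <- which(is.na(tr$tip.label) | !nzchar(tr$tip.label))
  if (length(bad)) stop("empty tip label at tip position ", bad[1L])
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup)) stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(default_blen, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    tr$edge.length[is.na(tr$edge.length)] <- default_blen
  }
  if (any(tr$edge.length < 0))
    stop("negative branch length in Newick input")
  tr
}

#' Write a tree as a Newick string
#'
#' @param tree A `phylo` tree.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string terminated by ";".
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

#' Read a multi-tree Newick file (one statement per line)
#'
#' @param file Path to a Newick file.
#' @param default_blen Branch length for edges without one.
#' @return A list of `phylo` trees, named if the file has one tree per line
#'   and a names vector is attached downstream.
#' @export
read_newick_file <- function(file, default_blen = 1.0) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lapply(lines, parse_newick, default_blen = default_blen)
}

canon_split <- function(side, all_tips) {
  other <- setdiff(all_tips, side)
  a <- paste(sort(side), collapse = ",")
  b <- paste(sort(other), collapse = ",")
  if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
}

#' Non-trivial bipartitions of a tree
#'
#' One bipartition per internal edge of the unrooted form, in a canonical
#' string encoding `"side1|side2"` with each side's tips sorted and the
#' lexicographically smaller side first, so set operations on the result are
#' well defined. A binary n-tip tree yields exactly n - 3 bipartitions;
#' multifurcating trees yield fewer; a star tree yields none.
#'
#' @param tree A `phylo` tree with at least 4 tips.
#' @return Character vector of canonical bipartition encodings (possibly
#'   empty).
#' @export
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4L) stop("bipartitions require at least 4 tips, got ", n)
  ut <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  pp <- ape::prop.part(ut)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    if (length(side) >= 2L && length(side) <= n - 2L)
      out <- c(out, canon_split(side, labs))
  }
  sort(unique(out))
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of non-trivial bipartitions, computed on the
#' unrooted forms. The normalized variant divides by 2(n - 3), the maximum
#' for binary trees.
#'
#' @param t1,t2 `phylo` trees on the same tip set.
#' @param normalized Divide by 2(n - 3)?
#' @return Non-negative number.
#' @export
rf_distance <- function(t1, t2, normalized = FALSE) {
  a <- sort(t1$tip.label)
  b <- sort(t2$tip.label)
  if (!identical(a, b)) {
    d1 <- setdiff(a, b)
    d2 <- setdiff(b, a)
    stop("tip sets differ; only in tree 1: {", paste(d1, collapse = ", "),
         "}; only in tree 2: {", paste(d2, collapse = ", "), "}")
  }
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  d <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  if (normalized) d / (2 * (length(a) - 3L)) else d
}

# Resolution profile of all 4-tip subsets of `tips` within `tree`.
# Returns an integer vector over columns of `combs` (4 x m index matrix into
# `tips`): 0 = unresolved, 1 = (12|34), 2 = (13|24), 3 = (14|23).
# Uses the four-point condition on topological (unit-branch) path lengths.
quartet_profile <- function(tree, tips, combs = utils::combn(length(tips), 4L)) {
  tr <- tree
  if (length(tr$tip.label) > length(tips)) tr <- ape::keep.tip(tr, tips)
  tr$edge.length <- rep(1, nrow(tr$edge))
  D <- stats::cophenetic(tr)[tips, tips]
  i <- combs[1L, ]; j <- combs[2L, ]; k <- combs[3L, ]; l <- combs[4L, ]
  s1 <- D[cbind(i, j)] + D[cbind(k, l)]
  s2 <- D[cbind(i, k)] + D[cbind(j, l)]
  s3 <- D[cbind(i, l)] + D[cbind(j, k)]
  m <- pmin(s1, s2, s3)
  res <- integer(length(m))
  res[s1 == m & s2 > m & s3 > m] <- 1L
  res[s2 == m & s1 > m & s3 > m] <- 2L
  res[s3 == m & s1 > m & s2 > m] <- 3L
  res
}

#' Quartet agreement between two trees
#'
#' Both trees are restricted to their shared tips; every 4-tip subset is
#' classified as one of the three resolutions or unresolved. `comparable`
#' counts subsets resolved in both restricted trees, `shared` those resolved
#' identically.
#'
#' @param t1,t2 `phylo` trees with at least 4 shared tips.
#' @return Named integer vector `c(shared =, comparable =)`.
#' @export
quartet_agreement <- function(t1, t2) {
  tips <- sort(intersect(t1$tip.label, t2$tip.label))
  if (length(tips) < 4L)
    stop("need at least 4 shared tips, got ", length(tips))
  combs <- utils::combn(length(tips), 4L)
  q1 <- quartet_profile(t1, tips, combs)
  q2 <- quartet_profile(t2, tips, combs)
  both <- q1 > 0L & q2 > 0L
  c(shared = sum(both & q1 == q2), comparable = sum(both))
}

# undirected adjacency representation used for NNI surgery
tree_adjacency <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lens <- new.env(parent = emptyenv())
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    assign(paste(min(a, b), max(a, b), sep = ":"),
           tree$edge.length[e], envir = lens)
  }
  list(adj = adj, lens = lens)
}

adjacency_to_tree <- function(adj, lens, labels, root) {
  getlen <- function(a, b) get(paste(min(a, b), max(a, b), sep = ":"), envir = lens)
  build <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    if (!length(kids)) return(labels[node])
    parts <- vapply(kids, function(k)
      paste0(build(k, node), ":", format(getlen(node, k), digits = 15)), "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  parse_newick(paste0(build(root, 0L), ";"))
}

#' Nearest-neighbor-interchange neighbors around an internal edge
#'
#' For an internal edge of an unrooted binary tree, returns the two
#' alternative resolutions obtained by swapping one subtree across the edge.
#' Both neighbors differ from the input by RF distance 2 at that edge;
#' collecting both neighbors over all n - 3 internal edges gives the full
#' 2(n - 3) NNI neighborhood.
#'
#' @param tree A `phylo` tree; it is unrooted internally first.
#' @param edge Row index into `ape::unroot(tree)$edge` of an internal edge.
#' @return List of two `phylo` trees.
#' @export
nni_neighbors <- function(tree, edge) {
  ut <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  if (is.null(ut$edge.length)) ut$edge.length <- rep(1, nrow(ut$edge))
  ntip <- length(ut$tip.label)
  stopifnot(length(edge) == 1L, edge >= 1L, edge <= nrow(ut$edge))
  u <- ut$edge[edge, 1L]; v <- ut$edge[edge, 2L]
  if (u <= ntip || v <= ntip)
    stop("edge ", edge, " is pendant; NNI requires an internal edge")
  ad <- tree_adjacency(ut)
  un <- setdiff(ad$adj[[u]], v)
  vn <- setdiff(ad$adj[[v]], u)
  if (length(un) != 2L || length(vn) != 2L)
    stop("NNI requires a binary neighborhood around the edge (found degrees ",
         length(un) + 1L, " and ", length(vn) + 1L, ")")
  swap <- function(b, c) {
    adj <- ad$adj
    adj[[u]] <- c(setdiff(adj[[u]], b), c)
    adj[[v]] <- c(setdiff(adj[[v]], c), b)
    adj[[b]] <- c(setdiff(adj[[b]], u), v)
    adj[[c]] <- c(setdiff(adj[[c]], v), u)
    lens <- new.env(parent = emptyenv())
    for (nm in ls(ad$lens)) assign(nm, get(nm, envir = ad$lens), envir = lens)
    # moved subtrees keep their stalk lengths
    kb <- paste(min(u, b), max(u, b), sep = ":")
    kc <- paste(min(v, c), max(v, c), sep = ":")
    lb <- get(kb, envir = lens); lc <- get(kc, envir = lens)
    rm(list = c(kb, kc), envir = lens)
    assign(paste(min(v, b), max(v, b), sep = ":"), lb, envir = lens)
    assign(paste(min(u, c), max(u, c), sep = ":"), lc, envir = lens)
    adjacency_to_tree(adj, lens, ut$tip.label, u)
  }
  list(swap(un[2L], vn[1L]), swap(un[2L], vn[2L]))
}

# internal edges of the unrooted form, as row indices into unroot(tree)$edge
internal_edges <- function(tree) {
  ut <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ntip <- length(ut$tip.label)
  which(ut$edge[, 1L] > ntip & ut$edge[, 2L] > ntip)
}

#' Convert a tree to a relative-time ultrametric tree
#'
#' Mean-path-length smoothing: each internal node's age is set to the mean
#' path length to its descendant tips, ages are clamped so a parent is never
#' younger than a child, and the result is rescaled so the root sits at
#' relative age 1. Unrooted inputs are midpoint-rooted first. Topology and
#' labels are unchanged.
#'
#' @param tree A `phylo` tree with non-negative branch lengths, not all zero.
#' @return A rooted ultrametric `phylo` tree with root-to-tip depth 1.
#' @export
ultrametricize <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (all(tree$edge.length == 0)) stop("zero-height tree: all branch lengths are 0")
  tr <- if (!ape::is.rooted(tree)) phangorn::midpoint(tree) else tree
  ntip <- length(tr$tip.label)
  n_node <- ntip + tr$Nnode
  root <- ntip + 1L
  # postorder accumulation of summed tip path lengths and tip counts
  sum_len <- numeric(n_node)
  n_tips <- integer(n_node)
  n_tips[seq_len(ntip)] <- 1L
  po <- ape::reorder.phylo(tr, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    a <- po$edge[e, 1L]; b <- po$edge[e, 2L]; w <- po$edge.length[e]
    sum_len[a] <- sum_len[a] + sum_len[b] + n_tips[b] * w
    n_tips[a] <- n_tips[a] + n_tips[b]
  }
  age <- numeric(n_node)
  age[(ntip + 1L):n_node] <- sum_len[(ntip + 1L):n_node] / n_tips[(ntip + 1L):n_node]
  # clamp parent >= child, bottom-up
  for (e in seq_len(nrow(po$edge))) {
    a <- po$edge[e, 1L]; b <- po$edge[e, 2L]
    if (age[a] < age[b]) age[a] <- age[b]
  }
  if (age[root] <= 0) stop("zero-height tree after smoothing")
  age <- age / age[root]
  out <- tr
  out$edge.length <- age[tr$edge[, 1L]] - age[tr$edge[, 2L]]
  out
}

# root-to-tip depth spread; used to validate clock trees
ultrametric_spread <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  max(d) - min(d)
}
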