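# Quartet-score partitioned coalescence support (PCS). The optimality
# criterion is the ASTRAL one: the number of resolved 4-tip subsets a gene
# tree shares with a candidate species tree. For each internal branch (clade)
# of the species tree, the best alternative lacking that clade is found among
# the candidates (NNI rearrangements by default, or user-supplied trees), and
# each gene's support is its fit difference between the species tree and that
# alternative. Positive = support, negative = conflict, zero = ambiguity.

#' Quartet fit of a gene tree to a species tree
#'
#' Number of 4-tip subsets, over the shared taxa, resolved identically in
#' both trees. This is the gene's contribution to an ASTRAL-style quartet
#' criterion. Branch lengths are ignored.
#'
#' @param gene_tree,species_tree `phylo` trees with >= 4 shared tips.
#' @return Integer count.
#' @export
gene_quartet_fit <- function(gene_tree, species_tree) {
  unname(quartet_agreement(gene_tree, species_tree)["shared"])
}

# quartet profile of `tree` on `tips` (a subset of its tips), relative to the
# master quartet index `combs` over `all_tips`; quartets with tips outside
# `tips` get NA
masked_quartet_profile <- function(tree, tips, all_tips, combs) {
  prof <- rep(NA_integer_, ncol(combs))
  present <- all_tips %in% tips
  ok <- present[combs[1L, ]] & present[combs[2L, ]] &
    present[combs[3L, ]] & present[combs[4L, ]]
  if (!any(ok)) return(prof)
  sub <- combs[, ok, drop = FALSE]
  # re-index into the tip ordering used for the cophenetic matrix
  tr <- tree
  if (length(tr$tip.label) > length(tips)) tr <- ape::keep.tip(tr, tips)
  tr$edge.length <- rep(1, nrow(tr$edge))
  D <- stats::cophenetic(tr)[all_tips[present], all_tips[present]]
  remap <- match(all_tips, all_tips[present])
  i <- remap[sub[1L, ]]; j <- remap[sub[2L, ]]
  k <- remap[sub[3L, ]]; l <- remap[sub[4L, ]]
  s1 <- D[cbind(i, j)] + D[cbind(k, l)]
  s2 <- D[cbind(i, k)] + D[cbind(j, l)]
  s3 <- D[cbind(i, l)] + D[cbind(j, k)]
  m <- pmin(s1, s2, s3)
  res <- integer(length(m))
  res[s1 == m & s2 > m & s3 > m] <- 1L
  res[s2 == m & s1 > m & s3 > m] <- 2L
  res[s3 == m & s1 > m & s2 > m] <- 3L
  prof[ok] <- res
  prof
}

# shared resolved quartets between two masked profiles
profile_fit <- function(a, b) sum(!is.na(a) & !is.na(b) & a > 0L & b > 0L & a == b)

#' Partitioned coalescence support per gene
#'
#' For each clade c (internal branch) of the species tree, the candidate
#' alternatives lacking c are ranked by total quartet fit summed over genes;
#' against the best one, `PCS[g, c] = fit_g(species tree) - fit_g(A*(c))`.
#' Gene-level PCS is either the sum over all clades (default) or the value at
#' one focal clade. Genes with missing taxa contribute fits over their shared
#' taxa only (unnormalized integer counts).
#'
#' @param gene_trees Named list of `phylo` gene trees (taxa subsets of the
#'   species tree allowed; genes with < 4 shared taxa are skipped and
#'   reported).
#' @param species_tree `phylo`, the optimal species-tree topology.
#' @param alternatives `"nni"` (default: the two NNI rearrangements at each
#'   internal branch) or a list of alternative species trees on the same
#'   taxon set.
#' @param clade `NULL` to aggregate over all clades, or an integer index
#'   (into the internal edges of the unrooted species tree) restricting PCS
#'   to one focal clade.
#' @return Data frame (`gene`, `PCS`, `class`) with attributes `per_clade`
#'   (gene x clade matrix), `clades` (bipartition encodings), `mode`, and
#'   `skipped`.
#' @export
pcs_scores <- function(gene_trees, species_tree, alternatives = "nni",
                       clade = NULL) {
  if (is.null(names(gene_trees)))
    names(gene_trees) <- paste0("gene", seq_along(gene_trees))
  sp <- if (ape::is.rooted(species_tree)) ape::unroot(species_tree) else species_tree
  all_tips <- sort(sp$tip.label)
  shared_n <- vapply(gene_trees, function(g)
    length(intersect(g$tip.label, all_tips)), 0L)
  skipped <- names(gene_trees)[shared_n < 4L]
  gene_trees <- gene_trees[shared_n >= 4L]
  if (!length(gene_trees)) stop("no gene tree shares >= 4 taxa with the species tree")

  combs <- utils::combn(length(all_tips), 4L)
  prof_g <- lapply(gene_trees, function(g)
    masked_quartet_profile(g, intersect(all_tips, g$tip.label), all_tips, combs))
  prof_sp <- masked_quartet_profile(sp, all_tips, all_tips, combs)
  fit_sp <- vapply(prof_g, profile_fit, 0L, b = prof_sp)

  edges <- internal_edges(sp)
  clade_splits <- vapply(edges, function(e) {
    side <- ape::extract.clade(sp, sp$edge[e, 2L])$tip.label
    canon_split(side, sp$tip.label)
  }, "")

  nni_mode <- identical(alternatives, "nni")
  if (!nni_mode) {
    if (!is.list(alternatives) || !length(alternatives))
      stop("alternatives must be \"nni\" or a non-empty list of trees")
    for (a in alternatives)
      if (!identical(sort(a$tip.label), all_tips))
        stop("alternative tree has a different taxon set")
    alt_splits <- lapply(alternatives, tree_bipartitions)
    alt_profs <- lapply(alternatives, function(a)
      masked_quartet_profile(a, all_tips, all_tips, combs))
  }

  per_clade <- matrix(0L, nrow = length(gene_trees), ncol = length(edges),
                      dimnames = list(names(gene_trees), clade_splits))
  for (ci in seq_along(edges)) {
    cands <- if (nni_mode) {
      nni_neighbors(sp, edges[ci])  # both lack the clade at this edge
    } else {
      keep <- !vapply(alt_splits, function(s) clade_splits[ci] %in% s, TRUE)
      alternatives[keep]
    }
    if (!length(cands)) next  # no candidate lacks this clade
    cand_profs <- if (nni_mode) {
      lapply(cands, function(a) masked_quartet_profile(a, all_tips, all_tips, combs))
    } else alt_profs[keep]
    totals <- vapply(cand_profs, function(ap)
      sum(vapply(prof_g, profile_fit, 0L, b = ap)), 0L)
    best <- cand_profs[[which.max(totals)]]
    fit_alt <- vapply(prof_g, profile_fit, 0L, b = best)
    per_clade[, ci] <- fit_sp - fit_alt
  }

  pcs <- if (is.null(clade)) rowSums(per_clade) else {
    stopifnot(clade >= 1L, clade <= ncol(per_clade))
    per_clade[, clade]
  }
  out <- data.frame(gene = names(gene_trees), PCS = as.integer(pcs),
                    class = ifelse(pcs > 0, "positive",
                                   ifelse(pcs < 0, "negative", "zero")),
                    stringsAsFactors = FALSE)
  attr(out, "per_clade") <- per_clade
  attr(out, "clades") <- clade_splits
  attr(out, "mode") <- if (nni_mode) "nni" else "explicit"
  attr(out, "aggregation") <- if (is.null(clade)) "sum over clades"
    else paste0("focal clade ", clade)
  attr(out, "skipped") <- skipped
  out
}
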