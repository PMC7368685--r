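# Robinson-Foulds tree space over gene trees plus species trees: common-taxon
# restriction, the pairwise RF matrix, classical PCoA ordination, and the
# per-gene discordance statistic GD (distance to the coalescent species tree
# in the first two principal coordinates).

#' Restrict a set of trees to their common taxa
#'
#' All trees are pruned to the intersection of their tip sets, because RF
#' tree space requires identical tips. Optionally, a bounded greedy pass
#' first drops genes whose removal strictly enlarges the common taxon set
#' (sporadically missing loci); every drop and pruning decision is recorded
#' in the `"report"` attribute.
#'
#' @param trees Named list of `phylo` trees (>= 2).
#' @param drop_genes Allow dropping up to `max_dropped` trees to enlarge the
#'   intersection?
#' @param max_dropped Greedy drop budget.
#' @return Named list of pruned trees (dropped genes removed), with
#'   attributes `report` (character vector of decisions) and `common_taxa`.
#' @export
restrict_to_common_taxa <- function(trees, drop_genes = FALSE, max_dropped = 4L) {
  if (length(trees) < 2L) stop("need at least 2 trees")
  if (is.null(names(trees))) names(trees) <- paste0("tree", seq_along(trees))
  report <- character(0)
  tipsets <- lapply(trees, `[[`, "tip.label")
  common <- Reduce(intersect, tipsets)
  if (drop_genes) {
    dropped <- 0L
    repeat {
      if (dropped >= max_dropped || length(trees) <= 2L) break
      gains <- vapply(seq_along(trees), function(i)
        length(Reduce(intersect, tipsets[-i])) - length(common), 0L)
      if (max(gains) < 1L) break
      i <- which.max(gains)
      report <- c(report, paste0("dropped gene '", names(trees)[i],
                                 "': removal enlarges the common taxon set by ",
                                 gains[i]))
      trees <- trees[-i]
      tipsets <- tipsets[-i]
      common <- Reduce(intersect, tipsets)
      dropped <- dropped + 1L
    }
  }
  if (length(common) < 4L)
    stop("common taxon set has ", length(common), " taxa (< 4)")
  out <- lapply(trees, function(tr) {
    if (length(tr$tip.label) > length(common)) ape::keep.tip(tr, common) else tr
  })
  pruned <- names(trees)[vapply(tipsets, length, 0L) > length(common)]
  if (length(pruned))
    report <- c(report, paste0("pruned to ", length(common), " common taxa; ",
                               "trees with extra tips: ",
                               paste(pruned, collapse = ", ")))
  removed_taxa <- sort(setdiff(unique(unlist(tipsets)), common))
  if (length(removed_taxa))
    report <- c(report, paste0("taxa removed from the analysis: ",
                               paste(removed_taxa, collapse = ", ")))
  attr(out, "report") <- report
  attr(out, "common_taxa") <- sort(common)
  out
}

#' Pairwise Robinson-Foulds distance matrix
#'
#' @param trees Named list of `phylo` trees with identical tip sets.
#' @param normalized Normalize each distance by 2(n - 3)?
#' @return Symmetric labeled matrix of RF distances.
#' @export
rf_matrix <- function(trees, normalized = FALSE) {
  stopifnot(length(trees) >= 2L)
  if (is.null(names(trees))) names(trees) <- paste0("tree", seq_along(trees))
  tips <- lapply(trees, function(t) sort(t$tip.label))
  for (i in seq_along(trees)[-1L])
    if (!identical(tips[[i]], tips[[1L]]))
      stop("tip-set mismatch between '", names(trees)[1L], "' and '",
           names(trees)[i], "'; use restrict_to_common_taxa() first")
  mp <- trees
  class(mp) <- "multiPhylo"
  D <- as.matrix(phangorn::RF.dist(mp, normalize = normalized))
  dimnames(D) <- list(names(trees), names(trees))
  D
}

#' Classical principal coordinate analysis of a distance matrix
#'
#' Classical MDS: the squared-distance matrix is double-centered and
#' eigendecomposed; coordinates exist for positive eigenvalues only
#' (axis i = eigenvector_i * sqrt(lambda_i)); negative eigenvalues are
#' reported but excluded. Variance explained is relative to the sum of
#' positive eigenvalues. Eigenvector signs follow a deterministic convention
#' (largest-magnitude loading positive).
#'
#' @param D Symmetric distance matrix with labels.
#' @param k Number of axes requested (>= 2); fewer are returned with a
#'   warning if fewer positive eigenvalues exist.
#' @return An object of class `ordination`: list with `ids`, `coords`
#'   (items x axes), `eigenvalues` (all, descending), `variance_explained`
#'   (per returned axis).
#' @export
pcoa_ordination <- function(D, k = 2L) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (k < 2L) stop("k must be >= 2")
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("item", seq_len(nrow(D)))
  n <- nrow(D)
  fit <- stats::cmdscale(as.dist(D), k = min(k, n - 1L), eig = TRUE)
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- eig[eig > 1e-12]
  k_eff <- min(k, length(pos))
  if (k_eff < k)
    warning("only ", k_eff, " positive eigenvalue(s); returning ", k_eff, " axes")
  coords <- if (k_eff == 0L) {
    # degenerate (e.g. all items identical): an empty embedding
    matrix(0, n, 0L)
  } else fit$points[, seq_len(k_eff), drop = FALSE]
  # deterministic sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(coords))) {
    v <- coords[, j]
    if (v[which.max(abs(v))] < 0) coords[, j] <- -v
  }
  # items with identical distance profiles must embed identically; assign
  # each duplicate the coordinates of its first occurrence so equality is
  # exact, not just within eigendecomposition round-off
  key <- apply(D, 1L, paste, collapse = "\r")
  coords <- coords[match(key, key), , drop = FALSE]
  rownames(coords) <- ids
  if (k_eff > 0L) colnames(coords) <- paste0("axis", seq_len(k_eff))
  structure(list(ids = ids, coords = coords, eigenvalues = eig,
                 variance_explained = pos[seq_len(k_eff)] / sum(pos)),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("PCoA ordination:", length(x$ids), "items,", ncol(x$coords), "axes;",
      "variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Per-gene discordance (GD) from a tree-space ordination
#'
#' GD of a gene is its Euclidean distance to the coalescent species tree in
#' the first two principal-coordinate axes of RF tree space. A gene tree
#' topologically identical to the species tree has an identical RF profile,
#' hence identical coordinates and GD = 0.
#'
#' @param ord An `ordination` containing gene trees and the species tree.
#' @param species_tree_id Identifier of the coalescent species tree in the
#'   ordination.
#' @param exclude_ids Further ids (e.g. a second species tree) excluded from
#'   the per-gene table.
#' @return Data frame (`gene`, `GD`) with attributes `mean` and `median`.
#' @export
gene_discordance <- function(ord, species_tree_id, exclude_ids = character(0)) {
  stopifnot(inherits(ord, "ordination"))
  if (!species_tree_id %in% ord$ids)
    stop("unknown species tree id: ", species_tree_id)
  k_use <- min(2L, ncol(ord$coords))  # degenerate ordinations have fewer axes
  xy <- ord$coords[, seq_len(k_use), drop = FALSE]
  genes <- setdiff(ord$ids, c(species_tree_id, exclude_ids))
  gd <- if (k_use == 0L) rep(0, length(genes)) else {
    ref <- xy[species_tree_id, ]
    sqrt(rowSums((xy[genes, , drop = FALSE] -
                    matrix(ref, length(genes), k_use, byrow = TRUE))^2))
  }
  out <- data.frame(gene = genes, GD = unname(gd), stringsAsFactors = FALSE)
  attr(out, "mean") <- mean(out$GD)
  attr(out, "median") <- stats::median(out$GD)
  out
}
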