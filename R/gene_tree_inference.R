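# Distance-based gene-tree estimation: Jukes-Cantor distances with pairwise
# deletion and a saturation cap, then Saitou-Nei neighbor joining, so
# synthetic end-to-end runs need no external tree-inference software.

#' Jukes-Cantor distance matrix from an alignment
#'
#' Pairwise comparisons use only columns where both sequences carry an
#' unambiguous base (pairwise deletion). The JC69 correction
#' d = -(3/4) ln(1 - (4/3) p) is applied to the mismatch proportion p;
#' saturated pairs (p >= 0.75) are capped at `d_max` with a warning so they
#' stay finite without dominating joins.
#'
#' @param aln A `gene_alignment` (or character matrix) with >= 2 sequences.
#' @param d_max Cap for saturated distances, substitutions/site.
#' @return Symmetric numeric matrix with zero diagonal, labeled by taxon.
#' @export
jc_distance_matrix <- function(aln, d_max = 5.0) {
  m <- toupper(unclass(aln))
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  ok <- m %in% DNA_BASES
  dim(ok) <- dim(m)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  capped <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- ok[i, ] & ok[j, ]
    nc <- sum(comp)
    if (nc == 0L)
      stop("no comparable columns between ", rownames(m)[i], " and ", rownames(m)[j])
    p <- sum(m[i, comp] != m[j, comp]) / nc
    d <- if (p >= 0.75) {
      capped <- capped + 1L
      d_max
    } else -0.75 * log(1 - 4 * p / 3)
    D[i, j] <- D[j, i] <- d
  }
  if (capped > 0L)
    warning(capped, " saturated pair(s) (p >= 0.75) capped at d_max = ", d_max)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via [ape::nj()]); negative estimated
#' branch lengths are clamped to zero. The output is unrooted.
#'
#' @param D Symmetric distance matrix with labels, n >= 3.
#' @return An unrooted `phylo` tree on the matrix labels.
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (nrow(D) < 3L) stop("neighbor joining needs n >= 3, got ", nrow(D))
  if (any(!is.finite(D))) stop("non-finite entries in distance matrix")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param D Labeled square distance matrix.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_phylip_distances <- function(D, file) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), !is.null(rownames(D)))
  lines <- c(format(nrow(D)),
             vapply(seq_len(nrow(D)), function(i)
               paste(formatC(rownames(D)[i], width = -10),
                     paste(formatC(D[i, ], format = "f", digits = 6),
                           collapse = " ")), ""))
  writeLines(lines, file)
  invisible(file)
}

#' Infer NJ gene trees for every usable gene of a dataset
#'
#' Genes with fewer than 4 taxa are skipped (reported via the
#' `"skipped"` attribute).
#'
#' @param alignments Named list of `gene_alignment`s.
#' @param d_max Saturation cap passed to [jc_distance_matrix()].
#' @return Named list of unrooted `phylo` trees, with attribute `skipped`.
#' @export
infer_gene_trees <- function(alignments, d_max = 5.0) {
  usable <- vapply(alignments, nrow, 0L) >= 4L
  trees <- lapply(alignments[usable], function(a)
    neighbor_joining(suppressWarnings(jc_distance_matrix(a, d_max = d_max))))
  attr(trees, "skipped") <- names(alignments)[!usable]
  trees
}
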