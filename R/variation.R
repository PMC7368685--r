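# Genetic variation and phylogenetic informativeness: segregating sites,
# nucleotide diversity, percent variability, parsimony-informative sites,
# per-site JC69 rate estimation on a fixed relative-time ultrametric tree,
# and Townsend informativeness profiles.

aln_state_matrix <- function(aln) {
  m <- toupper(unclass(aln))
  s <- match(m, DNA_BASES)  # NA for gaps/ambiguity
  matrix(s, nrow = nrow(m), dimnames = dimnames(m))
}

#' Number of segregating (variable) sites
#'
#' Columns with at least two distinct unambiguous bases; gaps and ambiguity
#' codes are ignored per column.
#'
#' @param aln A `gene_alignment` with >= 2 sequences.
#' @return Integer count.
#' @export
segregating_sites <- function(aln) {
  s <- aln_state_matrix(aln)
  if (nrow(s) < 2L || ncol(s) == 0L) stop("empty alignment")
  sum(apply(s, 2L, function(col) {
    v <- col[!is.na(col)]
    length(unique(v)) >= 2L
  }))
}

#' Nucleotide diversity (pi)
#'
#' Mean over all unordered sequence pairs of the per-site mismatch
#' proportion, with pairwise deletion of columns where either sequence has a
#' gap or ambiguous base. Pairs without comparable columns are excluded with
#' a warning; if no pair is comparable an error is raised.
#'
#' @param aln A `gene_alignment` with >= 2 sequences.
#' @return Numeric in [0, 1].
#' @export
nucleotide_diversity <- function(aln) {
  s <- aln_state_matrix(aln)
  if (nrow(s) < 2L) stop("need at least 2 sequences")
  n <- nrow(s)
  vals <- c()
  excluded <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- !is.na(s[i, ]) & !is.na(s[j, ])
    if (!any(comp)) { excluded <- excluded + 1L; next }
    vals <- c(vals, sum(s[i, comp] != s[j, comp]) / sum(comp))
  }
  if (excluded > 0L)
    warning(excluded, " pair(s) with no comparable columns excluded")
  if (!length(vals)) stop("no sequence pair has comparable columns")
  mean(vals)
}

#' Percent variability (PV = S / L)
#'
#' @param aln A `gene_alignment`.
#' @return Numeric in [0, 1].
#' @export
percent_variability <- function(aln) {
  L <- ncol(aln)
  if (L < 1L) stop("alignment has no columns")
  segregating_sites(aln) / L
}

#' Number of parsimony-informative sites
#'
#' Columns with at least two states each present in at least two sequences;
#' gaps and ambiguity codes are not counted as states.
#'
#' @param aln A `gene_alignment` with >= 4 sequences.
#' @return Integer count.
#' @export
parsimony_informative_sites <- function(aln) {
  s <- aln_state_matrix(aln)
  if (nrow(s) < 4L) stop("parsimony-informative counting needs >= 4 sequences")
  sum(apply(s, 2L, function(col) {
    tb <- tabulate(col[!is.na(col)], nbins = 4L)
    sum(tb >= 2L) >= 2L
  }))
}

# conditional-likelihood pruning for JC69 on a fixed tree, vectorized over
# site patterns with per-pattern rates; returns per-pattern log-likelihood
jc_pattern_loglik <- function(lambda, tree_po, tip_states, npat) {
  ntip <- nrow(tip_states)
  nnode <- ntip + tree_po$Nnode
  L <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    M <- matrix(1, npat, 4L)
    obs <- tip_states[i, ]
    known <- !is.na(obs)
    if (any(known)) {
      M[known, ] <- 0
      M[cbind(which(known), obs[known])] <- 1
    }
    L[[i]] <- M
  }
  for (e in seq_len(nrow(tree_po$edge))) {
    a <- tree_po$edge[e, 1L]; b <- tree_po$edge[e, 2L]
    w <- tree_po$edge.length[e]
    psame <- 0.25 + 0.75 * exp(-4 / 3 * lambda * w)
    pdiff <- (1 - psame) / 3
    Lc <- L[[b]]
    rs <- Lc[, 1L] + Lc[, 2L] + Lc[, 3L] + Lc[, 4L]
    M <- pdiff * rs + (psame - pdiff) * Lc
    L[[a]] <- if (is.null(L[[a]])) M else L[[a]] * M
  }
  root <- ntip + 1L
  lik <- rowSums(L[[root]]) / 4
  log(pmax(lik, 1e-300))
}

#' Per-site substitution rates on a fixed relative-time ultrametric tree
#'
#' Maximum-likelihood per-column rate multiplier under JC69 on the fixed
#' clock tree (Felsenstein pruning; bounded golden-section maximization on
#' `[0, lambda_max]` to tolerance `tol`). Invariant columns get rate 0.
#' Columns are collapsed to unique site patterns internally. If the tree has
#' tips absent from the alignment it is pruned to the alignment's taxa and
#' rescaled to unit height.
#'
#' @param aln A `gene_alignment`.
#' @param clock_tree Rooted ultrametric `phylo` with root-to-tip depth 1
#'   whose tips include the alignment's taxa.
#' @param lambda_max Upper bound on the rate, substitutions per site per unit
#'   relative time.
#' @param tol Bracket tolerance of the maximization.
#' @return Numeric vector of per-column rates with attribute `lambda_max`.
#' @export
site_rates <- function(aln, clock_tree, lambda_max = 20, tol = 1e-6) {
  taxa <- rownames(aln)
  missing_taxa <- setdiff(taxa, clock_tree$tip.label)
  if (length(missing_taxa))
    stop("clock tree lacks taxa: ", paste(missing_taxa, collapse = ", "))
  tr <- clock_tree
  if (length(tr$tip.label) > length(taxa)) {
    tr <- ape::keep.tip(tr, taxa)
    tr <- scale_to_unit_height(tr)
  }
  if (ultrametric_spread(tr) > 1e-6)
    stop("clock tree is not ultrametric (root-to-tip spread ",
         format(ultrametric_spread(tr)), ")")
  s <- aln_state_matrix(aln)[tr$tip.label, , drop = FALSE]
  nvals <- apply(s, 2L, function(col) length(unique(col[!is.na(col)])))
  variable <- nvals >= 2L
  rates <- numeric(ncol(s))
  if (any(variable)) {
    pat_key <- apply(s[, variable, drop = FALSE], 2L, paste, collapse = ",")
    uniq <- !duplicated(pat_key)
    tip_states <- s[, variable, drop = FALSE][, uniq, drop = FALSE]  # tips x patterns
    npat <- ncol(tip_states)
    po <- ape::reorder.phylo(tr, "postorder")
    f <- function(lam) jc_pattern_loglik(lam, po, tip_states, npat)
    # vectorized golden-section maximization, one bracket per pattern
    gr <- (sqrt(5) - 1) / 2
    a <- rep(0, npat); b <- rep(lambda_max, npat)
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- f(x1); f2 <- f(x2)
    while (max(b - a) > tol) {
      lower <- f1 >= f2   # maximum in [a, x2]
      b[lower] <- x2[lower]; x2[lower] <- x1[lower]; f2[lower] <- f1[lower]
      x1[lower] <- b[lower] - gr * (b[lower] - a[lower])
      a[!lower] <- x1[!lower]; x1[!lower] <- x2[!lower]; f1[!lower] <- f2[!lower]
      x2[!lower] <- a[!lower] + gr * (b[!lower] - a[!lower])
      fx <- f(ifelse(lower, x1, x2))
      f1[lower] <- fx[lower]
      f2[!lower] <- fx[!lower]
    }
    lam_hat <- (a + b) / 2
    rates[variable] <- lam_hat[match(pat_key, pat_key[uniq])]
  }
  attr(rates, "lambda_max") <- lambda_max
  rates
}

#' Townsend phylogenetic-informativeness profile
#'
#' Per-site informativeness rho(t; lambda) = 16 lambda^2 t exp(-4 lambda t)
#' (the quartet formula), summed over sites, evaluated on a grid of relative
#' times in (0, 1]. The profile maximum and its argmax summarize the gene.
#'
#' @param rates Per-site rates (see [site_rates()]).
#' @param t_grid Relative-time grid, subset of (0, 1].
#' @return Data frame (`t`, `PI`) with attributes `PI_max` and `t_star`.
#' @export
pi_profile <- function(rates, t_grid = seq(0.01, 1, by = 0.01)) {
  if (!length(t_grid)) stop("empty time grid")
  if (any(t_grid <= 0) || any(t_grid > 1))
    stop("t_grid must lie in (0, 1]")
  lam <- as.numeric(rates)
  pi_t <- vapply(t_grid, function(t) sum(16 * lam^2 * t * exp(-4 * lam * t)), 0)
  out <- data.frame(t = t_grid, PI = pi_t)
  i <- which.max(pi_t)
  attr(out, "PI_max") <- pi_t[i]
  attr(out, "t_star") <- t_grid[i]
  out
}

#' Full variation/informativeness record for one gene
#'
#' @param aln A `gene_alignment`.
#' @param clock_tree Relative-time ultrametric tree (root depth 1).
#' @param t_grid Time grid for the informativeness profile.
#' @param lambda_max Rate bound for [site_rates()].
#' @return One-row data frame (`gene`, `L`, `S`, `pi`, `PV`, `PI_max`,
#'   `t_star`).
#' @export
variation_record <- function(aln, clock_tree, t_grid = seq(0.01, 1, by = 0.01),
                             lambda_max = 20) {
  S <- segregating_sites(aln)
  rates <- site_rates(aln, clock_tree, lambda_max = lambda_max)
  prof <- pi_profile(rates, t_grid)
  data.frame(gene = attr(aln, "gene"), L = ncol(aln), S = S,
             pi = nucleotide_diversity(aln), PV = S / ncol(aln),
             PI_max = attr(prof, "PI_max"), t_star = attr(prof, "t_star"),
             stringsAsFactors = FALSE)
}
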