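# Simulators: Yule species trees, multispecies-coalescent gene trees,
# HKY+Gamma nucleotide alignments and GY94 (M0) codon alignments, plus
# planted gene-loss injection. All randomness flows through explicit seeds.

#' Simulate an ultrametric Yule species tree
#'
#' @param n_taxa Number of tips (>= 3), labeled `T1..Tn`.
#' @param birth_rate Speciation rate per unit time (> 0).
#' @param seed Integer seed; same seed gives an identical tree.
#' @return A rooted ultrametric `phylo` tree.
#' @export
simulate_species_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  if (n_taxa < 3L) stop("n_taxa must be >= 3, got ", n_taxa)
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  tr <- with_seed(seed, ape::rphylo(n_taxa, birth = birth_rate, death = 0))
  tr$tip.label <- paste0("T", seq_len(n_taxa))
  tr
}

# ages of every node above the youngest tip (tips of an ultrametric tree = 0)
node_ages <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  max(d[seq_along(tree$tip.label)]) - d
}

#' Simulate gene trees under the multispecies coalescent
#'
#' One haploid lineage is sampled per species. Within each species-tree
#' branch, k lineages coalesce at rate k(k-1)/2 per coalescent unit; lineages
#' reaching the root coalesce freely. Species-tree branch lengths must be in
#' coalescent units.
#'
#' @param species_tree Rooted `phylo` tree, branch lengths in coalescent
#'   units (non-negative).
#' @param n_genes Number of gene trees to simulate.
#' @param seed Integer seed.
#' @return List of `n_genes` rooted `phylo` gene trees (branch lengths in
#'   coalescent units).
#' @export
simulate_msc_gene_trees <- function(species_tree, n_genes, seed = NULL) {
  if (!ape::is.rooted(species_tree))
    stop("species tree must be rooted for coalescent simulation")
  if (is.null(species_tree$edge.length) || any(species_tree$edge.length < 0))
    stop("species tree must have non-negative branch lengths in coalescent units")
  stopifnot(n_genes >= 1L)
  ntip <- length(species_tree$tip.label)
  ages <- node_ages(species_tree)
  po <- ape::reorder.phylo(species_tree, "postorder")
  children <- split(po$edge[, 2L], po$edge[, 1L])
  root <- ntip + 1L
  # process internal nodes in postorder order of appearance
  internal_order <- unique(po$edge[, 1L])

  with_seed(seed, lapply(seq_len(n_genes), function(g) {
    # each lineage: list(frag = newick fragment, age = coalescent age)
    # coalescence clock runs from the branch's lower end (t_start) to its
    # upper end (t_end); lineage ages are global and may predate t_start
    evolve <- function(lin, t_start, t_end) {
      k <- length(lin)
      t <- t_start
      while (k >= 2L) {
        t <- t + stats::rexp(1L, rate = k * (k - 1L) / 2)
        if (t > t_end) break
        pick <- sample.int(k, 2L)
        a <- lin[[pick[1L]]]; b <- lin[[pick[2L]]]
        merged <- list(
          frag = paste0("(", a$frag, ":", format(t - a$age, digits = 15), ",",
                        b$frag, ":", format(t - b$age, digits = 15), ")"),
          age = t)
        lin <- c(lin[-pick], list(merged))
        k <- k - 1L
      }
      lin
    }
    pool <- vector("list", ntip + species_tree$Nnode)
    for (i in seq_len(ntip))
      pool[[i]] <- list(list(frag = species_tree$tip.label[i], age = ages[i]))
    for (nd in internal_order) {
      lin <- list()
      for (ch in children[[as.character(nd)]]) {
        # lineages of child evolve through the branch ending at `nd`
        lin <- c(lin, evolve(pool[[ch]], t_start = ages[ch], t_end = ages[nd]))
      }
      pool[[nd]] <- lin
    }
    lin <- evolve(pool[[root]], t_start = ages[root], t_end = Inf)
    parse_newick(paste0(lin[[1L]]$frag, ";"))
  }))
}

# discrete-gamma category rates: 4 equal-probability classes, median
# representatives
discrete_gamma_rates <- function(shape, k = 4L) {
  if (is.null(shape) || !is.finite(shape)) return(rep(1, k))
  stats::qgamma((seq_len(k) - 0.5) / k, shape = shape, rate = shape)
}

#' Simulate a nucleotide alignment under HKY + discrete Gamma
#'
#' Sites are assigned to one of four equal-probability Gamma rate categories
#' (median representatives); each category evolves by HKY along the gene
#' tree, with branch lengths interpreted as expected substitutions per site
#' before the per-gene rate multiplier.
#'
#' @param tree `phylo` gene tree with branch lengths in substitutions/site.
#' @param length Alignment length in bp (>= 1).
#' @param kappa Transition/transversion rate ratio.
#' @param base_freqs Frequencies of A, C, G, T summing to 1.
#' @param gamma_shape Gamma shape for among-site rate variation; `NULL`
#'   disables rate variation.
#' @param rate_multiplier Per-gene rate scaler (> 0).
#' @param seed Integer seed.
#' @param ... Metadata passed to [gene_alignment()] (gene, group, region).
#' @return A `gene_alignment`.
#' @export
simulate_nt_alignment <- function(tree, length, kappa = 2,
                                  base_freqs = c(0.25, 0.25, 0.25, 0.25),
                                  gamma_shape = NULL, rate_multiplier = 1,
                                  seed = NULL, ...) {
  stopifnot(length >= 1L, rate_multiplier > 0, kappa > 0)
  if (any(base_freqs < 0) || abs(sum(base_freqs) - 1) > 1e-9)
    stop("base_freqs must be non-negative and sum to 1")
  Q <- c(1, kappa, 1, 1, kappa, 1)  # AC AG AT CG CT GT
  with_seed(seed, {
    cat_rates <- discrete_gamma_rates(gamma_shape)
    site_cat <- sample.int(4L, length, replace = TRUE)
    out <- matrix("", nrow = length(tree$tip.label), ncol = length,
                  dimnames = list(tree$tip.label, NULL))
    for (cc in seq_len(4L)) {
      idx <- which(site_cat == cc)
      if (!length(idx)) next
      sim <- phangorn::simSeq(tree, l = length(idx), Q = Q, bf = base_freqs,
                              type = "DNA", rate = cat_rates[cc] * rate_multiplier)
      m <- toupper(as.character(sim))
      out[, idx] <- m[rownames(out), , drop = FALSE]
    }
    gene_alignment(out, ...)
  })
}

#' Simulate an in-frame codon alignment under GY94 (M0)
#'
#' Goldman-Yang style M0 process on the 61 sense codons: instantaneous rate
#' to a single-nucleotide neighbor proportional to the target codon frequency
#' times `kappa` for transitions times `omega` for nonsynonymous changes.
#' Stop codons are excluded from the state space, so none are ever emitted.
#' Branch lengths are expected substitutions per codon. Sequences are
#' generated by sampling the root from the codon frequencies and propagating
#' with exact transition-probability matrices per branch.
#'
#' @param tree `phylo` gene tree with branch lengths in substitutions/codon.
#' @param n_codons Number of codons (>= 10).
#' @param kappa Transition/transversion rate ratio.
#' @param omega dN/dS of the process (> 0).
#' @param codon_freqs Frequencies over [SENSE_CODONS]; default F3x4 from
#'   uniform position frequencies.
#' @param seed Integer seed.
#' @param ... Metadata passed to [gene_alignment()].
#' @return A `gene_alignment` with `codon = TRUE`.
#' @export
simulate_codon_alignment <- function(tree, n_codons, kappa = 2, omega = 0.2,
                                     codon_freqs = NULL, seed = NULL, ...) {
  if (n_codons < 10L) stop("n_codons must be >= 10, got ", n_codons)
  if (omega <= 0) stop("omega must be > 0")
  if (is.null(codon_freqs))
    codon_freqs <- f3x4_frequencies(matrix(0.25, 3, 4))
  Q <- gy94_rate_matrix(kappa, omega, codon_freqs)
  ptrans <- codon_transition_fn(Q, codon_freqs)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  pre <- ape::reorder.phylo(tree, "cladewise")  # parent before child
  with_seed(seed, {
    states <- matrix(NA_integer_, nrow = ntip + tree$Nnode, ncol = n_codons)
    states[root, ] <- sample.int(61L, n_codons, replace = TRUE, prob = codon_freqs)
    for (e in seq_len(nrow(pre$edge))) {
      a <- pre$edge[e, 1L]; b <- pre$edge[e, 2L]
      P <- ptrans(pre$edge.length[e])
      parent <- states[a, ]
      child <- integer(n_codons)
      for (st in unique(parent)) {
        at <- which(parent == st)
        child[at] <- sample.int(61L, length(at), replace = TRUE, prob = P[st, ])
      }
      states[b, ] <- child
    }
    seqs <- SENSE_CODONS[states[seq_len(ntip), , drop = FALSE]]
    dim(seqs) <- c(ntip, n_codons)
    chars <- matrix("", nrow = ntip, ncol = 3L * n_codons,
                    dimnames = list(tree$tip.label, NULL))
    for (p in 1:3)
      chars[, seq(p, 3L * n_codons, by = 3L)] <- substr(seqs, p, p)
    gene_alignment(chars, codon = TRUE, ...)
  })
}

#' Remove taxa from named genes of a synthetic dataset
#'
#' Emulates clade-restricted or sporadic gene loss: the listed taxa are
#' removed from the named genes' alignments and true gene trees, the truth
#' record is updated, and genes left with fewer than 4 taxa are flagged
#' unusable for tree building.
#'
#' @param dataset A `synthetic_dataset` (see [make_benchmark_dataset()]).
#' @param gene_names Genes to edit.
#' @param taxa Taxa to remove (must be species-tree tips).
#' @return The modified dataset.
#' @export
inject_gene_loss <- function(dataset, gene_names, taxa) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  all_taxa <- dataset$species_tree$tip.label
  bad <- setdiff(taxa, all_taxa)
  if (length(bad)) stop("unknown taxa: ", paste(bad, collapse = ", "))
  bad <- setdiff(gene_names, names(dataset$alignments))
  if (length(bad)) stop("unknown genes: ", paste(bad, collapse = ", "))
  for (g in gene_names) {
    keep <- setdiff(rownames(dataset$alignments[[g]]), taxa)
    dataset$alignments[[g]] <- aln_keep_taxa(dataset$alignments[[g]], keep)
    if (!is.null(dataset$gene_trees[[g]])) {
      if (length(keep) >= 2L)
        dataset$gene_trees[[g]] <- ape::keep.tip(dataset$gene_trees[[g]], keep)
      else dataset$gene_trees[[g]] <- NULL
    }
    i <- match(g, dataset$truth$genes$gene)
    prev <- dataset$truth$genes$lost_taxa[i]
    lost <- union(if (nzchar(prev)) strsplit(prev, ",")[[1L]] else character(0),
                  intersect(taxa, all_taxa))
    dataset$truth$genes$lost_taxa[i] <- paste(sort(lost), collapse = ",")
    dataset$truth$genes$n_taxa[i] <- length(keep)
    dataset$truth$genes$usable[i] <- length(keep) >= 4L
  }
  dataset
}
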