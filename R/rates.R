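# Nei-Gojobori (1986) counting estimator of dN, dS and dN/dS with
# Jukes-Cantor correction, per gene and (after codon-respecting
# concatenation) per functional group and plastome region. Mutational
# pathways through stop codons are excluded; multi-difference codons are
# averaged over all single-step pathway orderings.

.ng86_cache <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86_cache$tab)) return(.ng86_cache$tab)
  s <- SENSE_CODONS
  aa <- GENETIC_CODE_AA
  mat <- do.call(rbind, strsplit(s, ""))
  n <- length(s)

  # fractional site counts per codon: each non-stop single-nucleotide change
  # contributes 1/3 to the synonymous or nonsynonymous site count; changes to
  # stop codons contribute to neither (NG86 convention)
  syn_sites <- numeric(n)
  nonsyn_sites <- numeric(n)
  for (i in seq_len(n)) {
    for (p in 1:3) for (b in setdiff(c("T", "C", "A", "G"), mat[i, p])) {
      alt <- mat[i, ]
      alt[p] <- b
      alt <- paste(alt, collapse = "")
      if (aa[alt] == "*") next
      if (aa[alt] == aa[s[i]]) syn_sites[i] <- syn_sites[i] + 1 / 3
      else nonsyn_sites[i] <- nonsyn_sites[i] + 1 / 3
    }
  }

  # pathway-averaged synonymous/nonsynonymous difference counts per ordered
  # codon pair; a pathway is invalid if it passes through a stop codon
  Sd <- matrix(0, n, n)
  Nd <- matrix(0, n, n)
  valid <- matrix(TRUE, n, n)
  perms <- list(`1` = list(1L),
                `2` = list(1:2, 2:1),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- which(mat[i, ] != mat[j, ])
    k <- length(d)
    sd_tot <- 0; nd_tot <- 0; n_ok <- 0L
    for (ord in perms[[k]]) {
      cur <- mat[i, ]
      sd <- 0; nd <- 0; ok <- TRUE
      for (step in d[ord]) {
        nxt <- cur
        nxt[step] <- mat[j, step]
        a1 <- aa[paste(cur, collapse = "")]
        a2 <- aa[paste(nxt, collapse = "")]
        if (a2 == "*") { ok <- FALSE; break }
        if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; n_ok <- n_ok + 1L }
    }
    if (n_ok == 0L) valid[i, j] <- FALSE
    else { Sd[i, j] <- sd_tot / n_ok; Nd[i, j] <- nd_tot / n_ok }
  }
  .ng86_cache$tab <- list(syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
                          Sd = Sd, Nd = Nd, valid = valid)
  .ng86_cache$tab
}

#' NG86 synonymous and nonsynonymous site counts of a codon
#'
#' Each of the nine single-nucleotide changes contributes 1/3 of a site to
#' the synonymous or nonsynonymous total; changes producing a stop codon are
#' excluded from both, so `syn + nonsyn = 3 - n_stop_changes / 3`.
#'
#' @param codon A sense codon string (e.g. `"TTT"`).
#' @return Named numeric vector `c(syn_sites =, nonsyn_sites =)`.
#' @export
ng86_sites <- function(codon) {
  codon <- toupper(codon)
  i <- match(codon, SENSE_CODONS)
  if (is.na(i))
    stop("'", codon, "' is not a sense codon of the universal code")
  tab <- ng86_tables()
  c(syn_sites = tab$syn_sites[i], nonsyn_sites = tab$nonsyn_sites[i])
}

jc_correct <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

# core pairwise NG86 on two codon index vectors (NA = unusable codon)
ng86_core <- function(i1, i2) {
  tab <- ng86_tables()
  use <- !is.na(i1) & !is.na(i2) & tab$valid[cbind(pmax(i1, 1L), pmax(i2, 1L))]
  use[is.na(use)] <- FALSE
  i1 <- i1[use]; i2 <- i2[use]
  S <- sum((tab$syn_sites[i1] + tab$syn_sites[i2]) / 2)
  N <- sum((tab$nonsyn_sites[i1] + tab$nonsyn_sites[i2]) / 2)
  Sd <- sum(tab$Sd[cbind(i1, i2)])
  Nd <- sum(tab$Nd[cbind(i1, i2)])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  omega <- if (is.na(dN) || is.na(dS) || dS == 0) NA_real_ else dN / dS
  list(dN = dN, dS = dS, omega = omega, Nd = Nd, Sd = Sd, N = N, S = S,
       n_codons_used = length(i1))
}

#' Pairwise NG86 dN, dS and dN/dS
#'
#' Site counts are averaged over the two sequences; differences in
#' multi-difference codons are averaged over all orderings of single-step
#' pathways, excluding pathways through stop codons; proportions are
#' Jukes-Cantor corrected. Codons containing gaps, ambiguous bases or stops
#' in either sequence are skipped pairwise. Saturated proportions
#' (p >= 0.75) and dS = 0 yield missing values rather than infinities.
#'
#' @param seq1,seq2 Equal-length in-frame nucleotide strings or character
#'   vectors.
#' @return List with `dN`, `dS`, `omega`, raw counts `Nd`, `Sd`, site totals
#'   `N`, `S`, and `n_codons_used`.
#' @export
ng86_pair <- function(seq1, seq2) {
  to_chars <- function(s) if (length(s) == 1L && nchar(s[1L]) > 1L)
    strsplit(toupper(s), "")[[1L]] else toupper(s)
  s1 <- to_chars(seq1)
  s2 <- to_chars(seq2)
  if (length(s1) != length(s2))
    stop("sequence length mismatch: ", length(s1), " vs ", length(s2))
  if (length(s1) %% 3L != 0L)
    stop("sequence length ", length(s1), " violates codon frame")
  m <- rbind(a = s1, b = s2)
  idx <- codon_index_matrix(m)
  ng86_core(idx[1L, ], idx[2L, ])
}

#' Mean pairwise NG86 rates of an alignment unit
#'
#' Unit dN and dS are means over all unordered sequence pairs (pairs with a
#' missing value excluded from that rate's mean); unit omega is the ratio of
#' the mean dN to the mean dS, reported missing when mean dS is 0 or
#' undefined.
#'
#' @param aln In-frame codon `gene_alignment` (>= 2 sequences).
#' @param unit Unit identifier for the output record.
#' @return One-row data frame (`unit`, `dN`, `dS`, `omega`, `n_pairs_dN`,
#'   `n_pairs_dS`).
#' @export
unit_rates <- function(aln, unit = attr(aln, "gene")) {
  m <- unclass(aln)
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  idx <- codon_index_matrix(m)
  n <- nrow(idx)
  dn <- c(); ds <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- ng86_core(idx[i, ], idx[j, ])
    dn <- c(dn, r$dN)
    ds <- c(ds, r$dS)
  }
  dN <- if (any(!is.na(dn))) mean(dn, na.rm = TRUE) else NA_real_
  dS <- if (any(!is.na(ds))) mean(ds, na.rm = TRUE) else NA_real_
  omega <- if (is.na(dN) || is.na(dS) || dS == 0) NA_real_ else dN / dS
  data.frame(unit = if (is.na(unit) || is.null(unit)) "unit" else unit,
             dN = dN, dS = dS, omega = omega,
             n_pairs_dN = sum(!is.na(dn)), n_pairs_dS = sum(!is.na(ds)),
             stringsAsFactors = FALSE)
}

#' Read a gene-to-group and gene-to-region configuration
#'
#' Each file is a two-column TSV (`gene`, label). The packaged fixtures
#' `gene_groups.tsv` and `gene_regions.tsv` reproduce the standard plastid
#' functional groups and quadripartite region assignment.
#'
#' @param group_file,region_file Paths to two-column TSVs.
#' @return List with named character vectors `group_map` and `region_map`.
#' @export
read_grouping <- function(group_file, region_file) {
  rd <- function(f) {
    x <- utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    stats::setNames(x[[2L]], x[[1L]])
  }
  list(group_map = rd(group_file), region_map = rd(region_file))
}

#' Default grouping configuration from the plastid gene template
#'
#' @return List with `group_map` and `region_map` named character vectors.
#' @export
default_grouping <- function() {
  tab <- plastid_gene_table()
  list(group_map = stats::setNames(tab$group, tab$gene),
       region_map = stats::setNames(tab$region, tab$gene))
}

#' NG86 rates per functional group and plastome region
#'
#' Genes are concatenated codon-respectingly within each functional group and
#' each region (taxa missing a gene contribute gap codons, which pairwise
#' comparisons skip), then [unit_rates()] is applied to each concatenation.
#'
#' @param genes Named list of in-frame codon `gene_alignment`s.
#' @param cfg Grouping configuration (see [read_grouping()],
#'   [default_grouping()]); every gene must be mapped in both maps.
#' @return Data frame of rate records with a `kind` column ("group" or
#'   "region").
#' @export
group_region_rates <- function(genes, cfg) {
  nm <- names(genes)
  unmapped <- nm[!(nm %in% names(cfg$group_map)) | !(nm %in% names(cfg$region_map))]
  if (length(unmapped))
    stop("unmapped gene(s): ", paste(unmapped, collapse = ", "))
  run <- function(members, unit, kind) {
    taxa <- sort(unique(unlist(lapply(genes[members], rownames))))
    cat_aln <- concatenate_alignments(genes[members], taxa)
    r <- unit_rates(cat_aln, unit = unit)
    r$kind <- kind
    r
  }
  groups <- sort(unique(cfg$group_map[nm]))
  regions <- sort(unique(cfg$region_map[nm]))
  out <- rbind(
    do.call(rbind, lapply(groups, function(g)
      run(nm[cfg$group_map[nm] == g], g, "group"))),
    do.call(rbind, lapply(regions, function(r)
      run(nm[cfg$region_map[nm] == r], r, "region")))
  )
  rownames(out) <- NULL
  out
}
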