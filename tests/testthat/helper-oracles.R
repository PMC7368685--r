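# Independent oracles and shared fixtures. Oracles deliberately use
# different code paths (or different packages) than the implementation they
# check.

# -- bipartition oracle: own DFS on the edge matrix (no prop.part) ----------
oracle_bipartitions <- function(tree) {
  ut <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ntip <- length(ut$tip.label)
  desc_tips <- function(node) {
    if (node <= ntip) return(ut$tip.label[node])
    kids <- ut$edge[ut$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  out <- character(0)
  for (e in seq_len(nrow(ut$edge))) {
    child <- ut$edge[e, 2]
    if (child <= ntip) next
    side <- desc_tips(child)
    if (length(side) < 2 || length(side) > ntip - 2) next
    other <- setdiff(ut$tip.label, side)
    a <- paste(sort(side), collapse = ",")
    b <- paste(sort(other), collapse = ",")
    out <- c(out, if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|"))
  }
  sort(unique(out))
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# -- quartet oracle: prune every 4-tip subset and compare topologies --------
oracle_quartets <- function(t1, t2) {
  tips <- sort(intersect(t1$tip.label, t2$tip.label))
  stopifnot(length(tips) >= 4)
  shared <- 0L
  comparable <- 0L
  resolved_split <- function(tr) {
    # returns the canonical split string of a 4-tip tree, or NA if star
    b <- oracle_bipartitions(tr)
    if (length(b) == 0) NA_character_ else b[1]
  }
  for (q in utils::combn(tips, 4L, simplify = FALSE)) {
    s1 <- resolved_split(ape::keep.tip(t1, q))
    s2 <- resolved_split(ape::keep.tip(t2, q))
    if (!is.na(s1) && !is.na(s2)) {
      comparable <- comparable + 1L
      if (s1 == s2) shared <- shared + 1L
    }
  }
  c(shared = shared, comparable = comparable)
}

# -- NG86 oracle: independent re-derivation of site and pathway counts ------
oracle_ng86_sites <- function(codon) {
  bases <- c("T", "C", "A", "G")
  code <- plastidscape::GENETIC_CODE_AA
  cs <- strsplit(codon, "")[[1]]
  syn <- 0; nonsyn <- 0
  for (p in 1:3) for (b in setdiff(bases, cs[p])) {
    alt <- cs
    alt[p] <- b
    aa <- code[paste(alt, collapse = "")]
    if (aa == "*") next
    if (aa == code[codon]) syn <- syn + 1 / 3 else nonsyn <- nonsyn + 1 / 3
  }
  c(syn = syn, nonsyn = nonsyn)
}

oracle_ng86_path_counts <- function(c1, c2) {
  # mean syn/nonsyn difference counts over all stop-free orderings
  code <- plastidscape::GENETIC_CODE_AA
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  d <- which(a != b)
  if (!length(d)) return(c(sd = 0, nd = 0, valid = 1))
  perms <- if (length(d) == 1) list(d) else {
    pm <- combinat_perms(length(d))
    lapply(pm, function(o) d[o])
  }
  sds <- c(); nds <- c()
  for (path in perms) {
    cur <- a
    sd <- 0; nd <- 0; ok <- TRUE
    for (p in path) {
      nxt <- cur
      nxt[p] <- b[p]
      if (code[paste(nxt, collapse = "")] == "*") { ok <- FALSE; break }
      if (code[paste(cur, collapse = "")] == code[paste(nxt, collapse = "")])
        sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { sds <- c(sds, sd); nds <- c(nds, nd) }
  }
  if (!length(sds)) return(c(sd = NA, nd = NA, valid = 0))
  c(sd = mean(sds), nd = mean(nds), valid = 1)
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- combinat_perms(n - 1L)
    idx <- setdiff(seq_len(n), i)
    out <- c(out, lapply(rest, function(r) c(i, idx[r])))
  }
  out
}

# -- HKY transition-probability oracle (Pade expm from pracma) --------------
oracle_hky_p_identical <- function(t, kappa, bf) {
  # probability that the two ends of a branch of length t show the same base
  stopifnot(requireNamespace("pracma", quietly = TRUE))
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  ts_pair <- function(x, y) (x %in% c("A", "G") && y %in% c("A", "G")) ||
    (x %in% c("C", "T") && y %in% c("C", "T"))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    Q[i, j] <- bf[j] * if (ts_pair(rownames(Q)[i], rownames(Q)[j])) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-bf * diag(Q))  # expected substitutions per site = 1 per unit t
  P <- pracma::expm(Q * t)
  sum(bf * diag(P))
}

# -- shared fixtures --------------------------------------------------------
.fixture_cache <- new.env(parent = emptyenv())

get_benchmark42 <- function() {
  if (is.null(.fixture_cache$ds42))
    .fixture_cache$ds42 <- make_benchmark_dataset(benchmark_config(), seed = 42)
  .fixture_cache$ds42
}

small_benchmark_config <- function() {
  tab <- plastid_gene_table()
  keep <- c("petN", "psbE", "rps14", "rpl20", "ndhC", "ndhE", "rpl2", "rps7",
            "ccsA", "rpl33")
  benchmark_config(n_taxa = 8L, genes = tab[tab$gene %in% keep, ],
                   ndh_clade_size = 3L, sporadic_n_taxa = 1L)
}

random_binary_tree <- function(n) ape::rtree(n)
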