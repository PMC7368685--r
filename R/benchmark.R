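# The default synthetic benchmark: 26 taxa, the 76 shared plastid
# protein-coding genes with their functional groups (photosystems, ATP
# synthase, cytochrome b6f, Rubisco, RNA polymerase, ribosomal proteins,
# NADH dehydrogenase, other genes) and plastome regions (LSC/SSC/IR),
# heavy-tailed per-gene rate multipliers, purifying selection coupled to
# rate, MSC-driven topological discordance, and planted gene loss.

#' Template table of plastid protein-coding genes
#'
#' The 76 protein-coding genes shared across typical angiosperm plastomes,
#' with functional-group labels, plastome-region assignment (typical
#' quadripartite gene order) and approximate real coding lengths (bp,
#' divisible by 3).
#'
#' @return Data frame with columns `gene`, `group`, `region`, `length`.
#' @export
plastid_gene_table <- function() {
  g <- function(genes, group, lens) data.frame(gene = genes, group = group,
                                               length = lens)
  df <- rbind(
    g(c("psaA", "psaB", "psaC", "psaI", "psaJ"), "PSA",
      c(2253, 2205, 246, 111, 129)),
    g(c("psbA", "psbB", "psbC", "psbD", "psbE", "psbF", "psbH", "psbI", "psbJ",
        "psbL", "psbM", "psbN", "psbT", "psbZ"), "PSB",
      c(1062, 1527, 1422, 1062, 252, 120, 222, 111, 123, 117, 105, 132, 108, 189)),
    g(c("petA", "petB", "petD", "petG", "petF", "petN"), "PET",
      c(963, 648, 483, 114, 297, 90)),
    g(c("atpA", "atpB", "atpE", "atpF", "atpH", "atpI"), "ATP",
      c(1524, 1497, 402, 555, 246, 744)),
    g("rbcL", "Rubisco", 1428),
    g(c("rpoA", "rpoB", "rpoC1", "rpoC2"), "RPO", c(1014, 3213, 2040, 4110)),
    g(c("rpl2", "rpl14", "rpl16", "rpl20", "rpl22", "rpl23", "rpl32", "rpl33",
        "rpl36"), "RPL", c(825, 369, 408, 354, 375, 282, 171, 201, 114)),
    g(c("rps2", "rps3", "rps4", "rps7", "rps8", "rps11", "rps12", "rps14",
        "rps15", "rps18", "rps19"), "RPS",
      c(711, 657, 606, 468, 405, 417, 372, 303, 273, 306, 279)),
    g(c("ndhA", "ndhB", "ndhC", "ndhD", "ndhE", "ndhF", "ndhG", "ndhH", "ndhI",
        "ndhJ", "ndhK"), "NDH",
      c(1092, 1533, 363, 1503, 306, 2241, 531, 1182, 501, 477, 678)),
    g(c("ycf1", "ycf2", "ycf3", "ycf4", "accD", "clpP", "ccsA", "cemA", "matK"),
      "OG", c(5400, 6837, 507, 555, 1467, 591, 966, 690, 1530))
  )
  ir <- c("rpl2", "rpl23", "ycf2", "ndhB", "rps7", "rps12")
  ssc <- c("ndhF", "rpl32", "ccsA", "ndhD", "psaC", "ndhE", "ndhG", "ndhI",
           "ndhA", "ndhH", "rps15", "ycf1")
  df$region <- ifelse(df$gene %in% ir, "IR", ifelse(df$gene %in% ssc, "SSC", "LSC"))
  df
}

#' Default position-specific base frequencies for plastid coding sequence
#'
#' AT-rich composition with the usual decline of GC content from first to
#' third codon position.
#'
#' @return 3 x 4 matrix (positions x A,C,G,T).
#' @export
plastid_pos_freqs <- function() {
  m <- rbind(c(0.28, 0.20, 0.26, 0.26),
             c(0.30, 0.20, 0.19, 0.31),
             c(0.33, 0.16, 0.14, 0.37))
  dimnames(m) <- list(paste0("pos", 1:3), c("A", "C", "G", "T"))
  m
}

#' Configuration for the synthetic benchmark
#'
#' Defaults define the study conditions the package is calibrated on: 26
#' taxa, the 76-gene plastid template, a species tree of height 10 coalescent
#' units (moderate incomplete lineage sorting), lognormal per-gene rate
#' multipliers scaled by region (IR slowest, SSC fastest), per-gene omega
#' under purifying selection (omega < 1) coupled positively to the rate
#' multiplier, clade-restricted loss of the 11 NDH genes and sporadic loss of
#' rpl33 in two taxa.
#'
#' @param n_taxa Number of species.
#' @param genes Gene template table (see [plastid_gene_table()]).
#' @param coal_height Species-tree root height in coalescent units.
#' @param birth_rate Yule speciation rate.
#' @param mu Expected codon substitutions per coalescent unit at rate
#'   multiplier 1.
#' @param kappa Transition/transversion ratio.
#' @param pos_freqs 3 x 4 codon-position base frequencies (F3x4 input).
#' @param r_sdlog Lognormal sdlog of the per-gene rate multiplier.
#' @param region_factor Named multipliers applied to r_g by region.
#' @param ils_rate_coupling Exponent g >= 0 coupling per-gene coalescent
#'   depth to the rate multiplier: gene g's species tree is scaled by
#'   `r_g^ils_rate_coupling` (in coalescent units) before MSC simulation, so
#'   slowly evolving genes experience deeper coalescence and hence more
#'   topological discordance. This plants the negative discordance-rate
#'   association at construction level; 0 disables the coupling.
#' @param omega_base,omega_power,omega_sdlog Per-gene omega model:
#'   `omega_g = omega_base * r_g^omega_power * exp(N(0, omega_sdlog))`.
#' @param omega_range Omega clamped into this interval (purifying selection).
#' @param ndh_clade_size Approximate size of the clade losing the NDH genes.
#' @param sporadic_gene Gene hit by sporadic loss.
#' @param sporadic_n_taxa Number of taxa losing `sporadic_gene`.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(n_taxa = 26L, genes = plastid_gene_table(),
                             coal_height = 10, birth_rate = 1, mu = 0.012,
                             kappa = 2, pos_freqs = plastid_pos_freqs(),
                             r_sdlog = 0.7,
                             region_factor = c(LSC = 1, SSC = 1.3, IR = 0.3),
                             ils_rate_coupling = 1,
                             omega_base = 0.15, omega_power = 0.5,
                             omega_sdlog = 0.3, omega_range = c(0.02, 0.9),
                             ndh_clade_size = 6L, sporadic_gene = "rpl33",
                             sporadic_n_taxa = 2L) {
  cfg <- list(n_taxa = as.integer(n_taxa), genes = genes,
              coal_height = coal_height, birth_rate = birth_rate, mu = mu,
              kappa = kappa, pos_freqs = pos_freqs, r_sdlog = r_sdlog,
              region_factor = region_factor,
              ils_rate_coupling = ils_rate_coupling, omega_base = omega_base,
              omega_power = omega_power, omega_sdlog = omega_sdlog,
              omega_range = omega_range, ndh_clade_size = as.integer(ndh_clade_size),
              sporadic_gene = sporadic_gene,
              sporadic_n_taxa = as.integer(sporadic_n_taxa))
  class(cfg) <- "benchmark_config"
  validate_benchmark_config(cfg)
  cfg
}

validate_benchmark_config <- function(cfg) {
  req <- c("gene", "group", "region", "length")
  if (!all(req %in% names(cfg$genes)))
    stop("gene table must have columns ", paste(req, collapse = ", "))
  if (anyDuplicated(cfg$genes$gene)) stop("duplicate genes in gene table")
  if (any(cfg$genes$length %% 3L != 0L))
    stop("gene lengths must be divisible by 3")
  if (!all(cfg$genes$region %in% names(cfg$region_factor)))
    stop("region_factor missing regions: ",
         paste(setdiff(cfg$genes$region, names(cfg$region_factor)), collapse = ", "))
  if (cfg$n_taxa < 4L) stop("n_taxa must be >= 4")
  if (cfg$coal_height <= 0 || cfg$mu <= 0) stop("coal_height and mu must be > 0")
  if (length(cfg$sporadic_gene) && !all(cfg$sporadic_gene %in% cfg$genes$gene))
    stop("sporadic_gene not in gene table")
  if (cfg$omega_range[1] <= 0 || cfg$omega_range[2] >= 1)
    stop("omega_range must lie inside (0, 1) for a purifying-selection benchmark")
  invisible(cfg)
}

# internal node whose clade size is closest to `target`; ties -> smallest id
pick_clade <- function(tree, target) {
  ntip <- length(tree$tip.label)
  sizes <- vapply((ntip + 2L):(ntip + tree$Nnode), function(nd)
    length(ape::extract.clade(tree, nd)$tip.label), 0L)
  nd <- (ntip + 2L):(ntip + tree$Nnode)
  best <- nd[which.min(abs(sizes - target))]
  ape::extract.clade(tree, best)$tip.label
}

#' Generate the full synthetic benchmark dataset
#'
#' Simulates a Yule species tree (rescaled to `coal_height` coalescent
#' units), MSC gene trees for every gene, GY94 codon alignments with per-gene
#' rate multipliers and omegas, and planted gene loss; returns the dataset
#' together with its ground-truth record.
#'
#' @param config A `benchmark_config`.
#' @param seed Integer master seed (mandatory; all stages derive from it).
#' @return A list of class `synthetic_dataset` with elements `alignments`
#'   (named `gene_alignment`s), `gene_trees` (true MSC trees, coalescent
#'   units), `species_tree` (coalescent units), `species_tree_time`
#'   (relative-time, root depth 1), `truth` (a `SyntheticTruth`-style list)
#'   and `config`.
#' @export
make_benchmark_dataset <- function(config = benchmark_config(), seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory when simulating")
  validate_benchmark_config(config)
  genes <- config$genes
  ng <- nrow(genes)

  sp <- simulate_species_tree(config$n_taxa, config$birth_rate,
                              seed = derive_seed(seed, "species_tree"))
  sp$edge.length <- sp$edge.length * config$coal_height /
    max(ape::node.depth.edgelength(sp))
  r_g <- with_seed(derive_seed(seed, "rates"), {
    r <- stats::rlnorm(ng, meanlog = 0, sdlog = config$r_sdlog)
    r * unname(config$region_factor[genes$region])
  })
  # slow genes coalesce on a shallower species tree (more ILS); the gene
  # tree is rescaled back afterwards so sequence divergence is governed by
  # mu and r_g alone
  ils_scale <- r_g^config$ils_rate_coupling
  gtrees <- vector("list", ng)
  names(gtrees) <- genes$gene
  for (i in seq_len(ng)) {
    sp_g <- sp
    sp_g$edge.length <- sp_g$edge.length * ils_scale[i]
    gt <- simulate_msc_gene_trees(sp_g, 1L,
                                  seed = derive_seed(seed, paste0("msc_", genes$gene[i])))[[1L]]
    gt$edge.length <- gt$edge.length / ils_scale[i]
    gtrees[[i]] <- gt
  }
  omega_g <- with_seed(derive_seed(seed, "omega"), {
    o <- config$omega_base * r_g^config$omega_power *
      exp(stats::rnorm(ng, 0, config$omega_sdlog))
    pmin(pmax(o, config$omega_range[1]), config$omega_range[2])
  })
  codon_freqs <- f3x4_frequencies(config$pos_freqs)

  alns <- vector("list", ng)
  names(alns) <- genes$gene
  for (i in seq_len(ng)) {
    gt <- gtrees[[i]]
    gt$edge.length <- gt$edge.length * config$mu * r_g[i]
    alns[[i]] <- simulate_codon_alignment(
      gt, n_codons = genes$length[i] %/% 3L, kappa = config$kappa,
      omega = omega_g[i], codon_freqs = codon_freqs,
      seed = derive_seed(seed, paste0("gene_", genes$gene[i])),
      gene = genes$gene[i], group = genes$group[i], region = genes$region[i])
  }

  truth <- list(
    species_tree = sp,
    genes = data.frame(gene = genes$gene, group = genes$group,
                       region = genes$region, length = genes$length,
                       rate = r_g, omega = omega_g,
                       n_taxa = config$n_taxa, lost_taxa = "",
                       usable = TRUE, stringsAsFactors = FALSE),
    globals = list(kappa = config$kappa, pos_freqs = config$pos_freqs,
                   codon_freqs = codon_freqs, mu = config$mu,
                   coal_height = config$coal_height, seed = seed)
  )
  ds <- structure(list(alignments = alns, gene_trees = gtrees,
                       species_tree = sp,
                       species_tree_time = scale_to_unit_height(sp),
                       truth = truth, config = config),
                  class = "synthetic_dataset")

  # clade-restricted loss of the NDH genes, then sporadic single-gene loss
  ndh <- genes$gene[genes$group == "NDH"]
  if (length(ndh) && config$ndh_clade_size >= 2L &&
      config$ndh_clade_size <= config$n_taxa - 4L) {
    lost_clade <- pick_clade(sp, config$ndh_clade_size)
    ds <- inject_gene_loss(ds, ndh, lost_clade)
    ds$truth$loss_events <- list(list(genes = ndh, taxa = sort(lost_clade),
                                      kind = "clade"))
  }
  if (length(config$sporadic_gene) && config$sporadic_n_taxa > 0L) {
    pool_taxa <- rownames(ds$alignments[[config$sporadic_gene]])
    lost2 <- with_seed(derive_seed(seed, "sporadic_loss"),
                       sort(sample(pool_taxa, config$sporadic_n_taxa)))
    ds <- inject_gene_loss(ds, config$sporadic_gene, lost2)
    ds$truth$loss_events <- c(ds$truth$loss_events,
                              list(list(genes = config$sporadic_gene,
                                        taxa = lost2, kind = "sporadic")))
  }
  ds
}

scale_to_unit_height <- function(tree) {
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h
  tree
}

#' Write a synthetic dataset to disk
#'
#' Per-gene aligned FASTA (unwrapped), true gene trees and species tree as
#' Newick, and the truth record as TSV. Output is byte-reproducible for a
#' fixed (config, seed).
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(file.path(dir, "alignments"), recursive = TRUE, showWarnings = FALSE)
  for (g in names(dataset$alignments))
    write_fasta_alignment(dataset$alignments[[g]],
                          file.path(dir, "alignments", paste0(g, ".fasta")))
  writeLines(vapply(dataset$gene_trees, write_newick, ""),
             file.path(dir, "gene_trees.nwk"))
  writeLines(names(dataset$gene_trees), file.path(dir, "gene_trees.ids"))
  writeLines(write_newick(dataset$species_tree), file.path(dir, "species_tree.nwk"))
  write_tsv(dataset$truth$genes, file.path(dir, "truth_genes.tsv"))
  invisible(dir)
}
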