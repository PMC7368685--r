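test_that("Yule species trees are ultrametric, labeled and reproducible", {
  t3 <- simulate_species_tree(3, seed = 1)
  expect_equal(sort(t3$tip.label), c("T1", "T2", "T3"))
  expect_equal(t3$Nnode, 2)  # root plus one internal node
  for (n in c(5, 12)) {
    tr <- simulate_species_tree(n, seed = 2)
    expect_length(tr$tip.label, n)
    expect_lt(plastidscape:::ultrametric_spread(tr), 1e-9)
  }
  expect_identical(write_newick(simulate_species_tree(10, seed = 7)),
                   write_newick(simulate_species_tree(10, seed = 7)))
  expect_error(simulate_species_tree(2), "n_taxa")
})

test_that("MSC gene trees are concordant when internal branches are long", {
  sp <- simulate_species_tree(8, seed = 3)
  min_int <- min(sp$edge.length[sp$edge[, 2] > 8])
  sp$edge.length <- sp$edge.length * 15 / min_int  # every internal branch >= 15 CU
  gt <- simulate_msc_gene_trees(sp, 15, seed = 4)
  for (g in gt) expect_equal(rf_distance(ape::unroot(g), ape::unroot(sp)), 0)
  bad <- sp
  bad$edge.length[1] <- -0.1
  expect_error(simulate_msc_gene_trees(bad, 1, seed = 1), "non-negative")
})

test_that("3-taxon MSC concordance matches the closed form at moderate depth", {
  sp <- parse_newick("((A:1.5,B:1.5):1.0,C:2.5);")
  gt <- simulate_msc_gene_trees(sp, 2000, seed = 5)
  conc <- mean(vapply(gt, function(t) {
    D <- ape::cophenetic.phylo(t)
    D["A", "B"] < D["A", "C"] && D["A", "B"] < D["B", "C"]
  }, TRUE))
  expected <- 1 - (2 / 3) * exp(-1)
  se <- sqrt(expected * (1 - expected) / 2000)
  expect_lt(abs(conc - expected), 4 * se)
})

test_that("a zero-length internal branch gives the three resolutions equally", {
  sp0 <- parse_newick("((A:1.5,B:1.5):0.0,C:1.5);")
  gt <- simulate_msc_gene_trees(sp0, 3000, seed = 6)
  first_pair <- vapply(gt, function(t) {
    D <- ape::cophenetic.phylo(t)
    which.min(c(D["A", "B"], D["A", "C"], D["B", "C"]))
  }, 0L)
  freqs <- tabulate(first_pair, 3) / 3000
  expect_true(all(abs(freqs - 1 / 3) < 0.035))
})

test_that("HKY simulation is stationary and matches the closed-form p-distance", {
  skip_if_not_installed("pracma")
  two <- parse_newick("(A:0.15,B:0.15);")
  bf <- c(0.35, 0.15, 0.15, 0.35)
  aln <- simulate_nt_alignment(two, 100000, kappa = 3, base_freqs = bf, seed = 8)
  m <- unclass(aln)
  p_obs <- mean(m["A", ] != m["B", ])
  p_exp <- 1 - oracle_hky_p_identical(0.3, kappa = 3, bf = bf)
  expect_lt(abs(p_obs - p_exp), 0.02)
  comp <- table(factor(m, levels = c("A", "C", "G", "T"))) / length(m)
  expect_true(all(abs(as.numeric(comp) - bf) < 0.01))

  frozen <- two
  frozen$edge.length[] <- 0
  a0 <- simulate_nt_alignment(frozen, 500, seed = 9)
  expect_identical(unname(unclass(a0)["A", ]), unname(unclass(a0)["B", ]))
  expect_error(simulate_nt_alignment(two, 100, base_freqs = c(1, 1, 0, 0)),
               "sum to 1")
})

test_that("codon simulation emits only sense codons and respects omega", {
  set.seed(10)
  tr <- random_binary_tree(6)
  tr$edge.length <- tr$edge.length * 0.2
  a <- simulate_codon_alignment(tr, 60, kappa = 2, omega = 0.3, seed = 11, gene = "x")
  idx <- plastidscape:::codon_index_matrix(a)
  expect_false(anyNA(idx))  # every emitted codon is one of the 61 sense codons
  expect_equal(ncol(a) %% 3, 0)

  # near-zero omega: no nonsynonymous differences between any two sequences
  a2 <- simulate_codon_alignment(tr, 80, kappa = 2, omega = 1e-9, seed = 12)
  rows <- rownames(a2)
  for (i in 1:2) {
    r <- ng86_pair(paste(unclass(a2)[rows[i], ], collapse = ""),
                   paste(unclass(a2)[rows[i + 1], ], collapse = ""))
    expect_equal(r$Nd, 0)
  }
  expect_error(simulate_codon_alignment(tr, 60, omega = 0), "omega")
  expect_error(simulate_codon_alignment(tr, 5), "n_codons")

  # two-taxon transition probabilities match an independent matrix exponential
  skip_if_not_installed("pracma")
  f <- f3x4_frequencies(plastid_pos_freqs())
  Q <- plastidscape:::gy94_rate_matrix(2, 0.2, f)
  P1 <- plastidscape:::codon_transition_fn(Q, f)(0.7)
  P2 <- pracma::expm(Q * 0.7)
  expect_lt(max(abs(P1 - P2)), 1e-6)
})

test_that("gene loss injection edits alignments, trees and the truth record", {
  ds <- make_benchmark_dataset(small_benchmark_config(), seed = 31)
  n0 <- nrow(ds$alignments$psbE)
  taxa <- rownames(ds$alignments$psbE)[1:2]
  ds2 <- inject_gene_loss(ds, "psbE", taxa)
  expect_equal(nrow(ds2$alignments$psbE), n0 - 2)
  rec <- ds2$truth$genes[ds2$truth$genes$gene == "psbE", ]
  expect_true(all(taxa %in% strsplit(rec$lost_taxa, ",")[[1]]))
  # dropping all but three taxa flags the gene unusable
  keep3 <- rownames(ds$alignments$rps14)[1:3]
  ds3 <- inject_gene_loss(ds, "rps14", setdiff(rownames(ds$alignments$rps14), keep3))
  expect_false(ds3$truth$genes$usable[ds3$truth$genes$gene == "rps14"])
  expect_error(inject_gene_loss(ds, "nope", taxa), "unknown genes")
  expect_error(inject_gene_loss(ds, "psbE", "TX99"), "unknown taxa")
})

test_that("the benchmark dataset matches its configuration and is reproducible", {
  ds <- get_benchmark42()
  expect_length(ds$alignments, 76)
  expect_equal(length(ds$species_tree$tip.label), 26)
  expect_equal(nrow(ds$truth$genes), 76)
  # NDH genes lack the planted clade; rpl33 lacks two sporadic taxa
  ndh <- ds$truth$genes[ds$truth$genes$group == "NDH", ]
  expect_true(all(nzchar(ndh$lost_taxa)))
  expect_equal(length(unique(ndh$lost_taxa)), 1)
  expect_equal(ds$truth$genes$n_taxa[ds$truth$genes$gene == "rpl33"], 24)

  # byte-identical FASTA under the same (config, seed)
  cfg <- small_benchmark_config()
  d1 <- file.path(tempdir(), "bm1"); d2 <- file.path(tempdir(), "bm2")
  write_dataset(make_benchmark_dataset(cfg, seed = 5), d1)
  write_dataset(make_benchmark_dataset(cfg, seed = 5), d2)
  for (f in list.files(file.path(d1, "alignments")))
    expect_identical(readBin(file.path(d1, "alignments", f), "raw", 1e6),
                     readBin(file.path(d2, "alignments", f), "raw", 1e6))

  # genes with larger planted rate multipliers accumulate more variable sites
  S <- vapply(ds$alignments, segregating_sites, 0L)
  pv <- S / vapply(ds$alignments, ncol, 0L)
  expect_gt(cor(ds$truth$genes$rate, pv, method = "spearman"), 0.7)
})
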