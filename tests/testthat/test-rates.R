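test_that("NG86 site counts match exhaustive enumeration for all sense codons", {
  for (cd in SENSE_CODONS) {
    s <- ng86_sites(cd)
    o <- oracle_ng86_sites(cd)
    expect_equal(unname(s[["syn_sites"]]), unname(o[["syn"]]), info = cd)
    expect_equal(unname(s[["nonsyn_sites"]]), unname(o[["nonsyn"]]), info = cd)
    tot <- sum(s)
    expect_true(tot > 2.3 && tot <= 3, info = cd)
  }
  expect_equal(unname(ng86_sites("ATG")[["syn_sites"]]), 0)
  expect_equal(unname(ng86_sites("TGG")[["syn_sites"]]), 0)
  expect_equal(unname(ng86_sites("TTT")[["syn_sites"]]), 1 / 3)
  expect_error(ng86_sites("TAA"), "sense codon")
  expect_error(ng86_sites("NNN"), "sense codon")
})

test_that("pathway-averaged difference counts match the enumeration oracle", {
  tab <- plastidscape:::ng86_tables()
  s <- SENSE_CODONS
  set.seed(67)
  pairs <- cbind(sample(61, 250, replace = TRUE), sample(61, 250, replace = TRUE))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    o <- oracle_ng86_path_counts(s[i], s[j])
    if (o[["valid"]] == 0) {
      expect_false(tab$valid[i, j])
    } else {
      expect_equal(tab$Sd[i, j], unname(o[["sd"]]))
      expect_equal(tab$Nd[i, j], unname(o[["nd"]]))
    }
  }
})

test_that("pairwise NG86 matches hand computation and is symmetric", {
  s_same <- strrep("TTT", 10)
  r0 <- ng86_pair(s_same, s_same)
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)
  expect_true(is.na(r0$omega))

  # one TTT -> TTC change among ten TTT codons: hand derivation
  s2 <- paste0(strrep("TTT", 9), "TTC")
  r1 <- ng86_pair(s_same, s2)
  S_hand <- 10 * (1 / 3 + 1 / 3) / 2   # both sequences: 1/3 syn site per codon
  pS_hand <- 1 / S_hand
  expect_equal(r1$Sd, 1)
  expect_equal(r1$Nd, 0)
  expect_equal(r1$dN, 0)
  expect_equal(r1$dS, -0.75 * log(1 - 4 * pS_hand / 3))

  # two-difference codon: counts equal the mean over both orderings
  r2 <- ng86_pair("TTT", "CTA")
  o <- oracle_ng86_path_counts("TTT", "CTA")
  expect_equal(r2$Sd, unname(o[["sd"]]))
  expect_equal(r2$Nd, unname(o[["nd"]]))

  # symmetry in the two inputs
  set.seed(71)
  tr <- ape::rtree(4); tr$edge.length <- tr$edge.length * 0.3
  a <- simulate_codon_alignment(tr, 50, seed = 72)
  x <- paste(unclass(a)[1, ], collapse = "")
  y <- paste(unclass(a)[2, ], collapse = "")
  expect_equal(ng86_pair(x, y)[c("dN", "dS")], ng86_pair(y, x)[c("dN", "dS")])

  # gap-containing codons are skipped pairwise
  g1 <- paste0("TT-", strrep("ATG", 5))
  g2 <- paste0("TTT", strrep("ATG", 5))
  expect_equal(ng86_pair(g1, g2)$n_codons_used, 5)

  expect_error(ng86_pair("TTTA", "TTT"), "mismatch")
  expect_error(ng86_pair("TTTA", "TTTA"), "frame")
})

test_that("unit rates aggregate pairs and are invariant under duplication", {
  set.seed(73)
  tr <- ape::rtree(6); tr$edge.length <- tr$edge.length * 0.25
  a <- simulate_codon_alignment(tr, 80, kappa = 2, omega = 0.3, seed = 74,
                                gene = "u")
  r <- unit_rates(a)
  expect_gt(r$dS, 0)
  expect_true(r$omega < 1)

  ident <- gene_alignment(matrix(rep(strsplit(strrep("ATT", 20), "")[[1]], 3),
                                 nrow = 3, byrow = TRUE,
                                 dimnames = list(c("a", "b", "c"), NULL)),
                          codon = TRUE)
  r0 <- unit_rates(ident, unit = "ident")
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)

  doubled <- concatenate_alignments(list(g1 = a, g2 = a), rownames(a))
  r2 <- unit_rates(doubled, unit = "doubled")
  expect_equal(r2$dN, r$dN)
  expect_equal(r2$dS, r$dS)
})

test_that("group and region rates respect the configuration", {
  cfg <- default_grouping()
  # the RNA polymerase group is exactly rpoA, rpoB, rpoC1, rpoC2
  expect_setequal(names(cfg$group_map)[cfg$group_map == "RPO"],
                  c("rpoA", "rpoB", "rpoC1", "rpoC2"))
  # packaged fixtures reproduce the template
  fx <- read_grouping(system.file("extdata", "gene_groups.tsv",
                                  package = "plastidscape"),
                      system.file("extdata", "gene_regions.tsv",
                                  package = "plastidscape"))
  expect_identical(fx$group_map, cfg$group_map)
  expect_identical(fx$region_map, cfg$region_map)

  set.seed(79)
  tr <- ape::rtree(5); tr$edge.length <- tr$edge.length * 0.2
  g1 <- simulate_codon_alignment(tr, 40, seed = 80, gene = "rbcL")
  g2 <- simulate_codon_alignment(tr, 40, seed = 81, gene = "matK")
  out <- group_region_rates(list(rbcL = g1, matK = g2), cfg)
  # a single-gene group equals that gene's unit rates
  r_single <- out[out$unit == "Rubisco", ]
  expect_equal(r_single$dN, unit_rates(g1)$dN)
  expect_equal(r_single$dS, unit_rates(g1)$dS)
  bad <- list(foo = g1)
  expect_error(group_region_rates(bad, cfg), "unmapped")
})

test_that("planted region rate ordering is recovered (IR slowest)", {
  ds <- get_benchmark42()
  rr <- group_region_rates(ds$alignments, default_grouping())
  reg <- rr[rr$kind == "region", ]
  expect_lt(reg$dS[reg$unit == "IR"], reg$dS[reg$unit == "LSC"])
  expect_lt(reg$dS[reg$unit == "IR"], reg$dS[reg$unit == "SSC"])
})
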