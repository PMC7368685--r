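test_that("segregating sites, pi and PV match hand-enumerated fixtures", {
  a <- gene_alignment(rbind(s1 = strsplit("AAAAAAAAAA", "")[[1]],
                            s2 = strsplit("ACAATAAAGA", "")[[1]]))
  expect_equal(segregating_sites(a), 3L)  # variable columns 2, 5, 9
  expect_equal(nucleotide_diversity(a), 0.3)
  expect_equal(percent_variability(a), 0.3)

  ident <- gene_alignment(rbind(s1 = rep("G", 8), s2 = rep("G", 8)))
  expect_equal(segregating_sites(ident), 0L)
  expect_equal(nucleotide_diversity(ident), 0)
  expect_equal(percent_variability(ident), 0)

  # a column with a single non-gap state is not segregating
  g <- gene_alignment(rbind(s1 = c("A", "A"), s2 = c("-", "A"), s3 = c("-", "A")))
  expect_equal(segregating_sites(g), 0L)

  # two sequences, one difference in ten sites
  b <- gene_alignment(rbind(s1 = strsplit("ACGTACGTAC", "")[[1]],
                            s2 = strsplit("ACGTACGTAT", "")[[1]]))
  expect_equal(nucleotide_diversity(b), 0.1)

  # four sequences: mean over the six pairs, computed explicitly
  rows <- c(s1 = "AAAA", s2 = "AAAT", s3 = "AATT", s4 = "GATT")
  m4 <- gene_alignment(do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]])))
  pairs <- combn(4, 2)
  hand <- mean(apply(pairs, 2, function(p) {
    x <- strsplit(rows[[p[1]]], "")[[1]]
    y <- strsplit(rows[[p[2]]], "")[[1]]
    mean(x != y)
  }))
  expect_equal(nucleotide_diversity(m4), hand)

  # every column variable
  v <- gene_alignment(rbind(s1 = c("A", "C", "G"), s2 = c("C", "G", "T")))
  expect_equal(percent_variability(v), 1)
})

test_that("parsimony-informative sites require two states in two sequences", {
  a <- gene_alignment(rbind(s1 = c("A", "A", "A", "A"),
                            s2 = c("A", "A", "C", "T"),
                            s3 = c("G", "A", "C", "T"),
                            s4 = c("G", "C", "G", "T")))
  # col1: AAGG informative; col2: AAAC singleton; col3: ACCG only one
  # duplicated state; col4: ATTT singleton
  expect_equal(parsimony_informative_sites(a), 1L)
  b <- gene_alignment(rbind(s1 = strsplit("AACT", "")[[1]],
                            s2 = strsplit("AACT", "")[[1]],
                            s3 = strsplit("CACG", "")[[1]],
                            s4 = strsplit("CTCG", "")[[1]]))
  # col1 AACC informative, col2 AAAT not, col3 invariant, col4 TTGG informative
  expect_equal(parsimony_informative_sites(b), 2L)
  expect_error(parsimony_informative_sites(gene_alignment(
    rbind(s1 = c("A", "C"), s2 = c("A", "G")))), ">= 4")
})

test_that("site rates are zero for invariant columns and bounded", {
  sp <- simulate_species_tree(8, seed = 83)
  clock <- ultrametricize(sp)
  inv <- gene_alignment(matrix("A", 8, 5,
                               dimnames = list(clock$tip.label, NULL)))
  r <- site_rates(inv, clock)
  expect_equal(as.numeric(r), rep(0, 5))

  aln <- simulate_nt_alignment(clock, 120, rate_multiplier = 1.5, seed = 84)
  r2 <- site_rates(aln, clock)
  expect_true(all(r2 >= 0 & r2 <= attr(r2, "lambda_max")))

  non_clock <- sp
  non_clock$edge.length[1] <- non_clock$edge.length[1] * 3
  expect_error(site_rates(aln, non_clock), "not ultrametric")
})

test_that("estimated site rates rank true simulation rates correctly", {
  clock <- ultrametricize(simulate_species_tree(16, seed = 85))
  rates_true <- c(0.1, 0.5, 2.0)
  est_means <- vapply(seq_along(rates_true), function(i) {
    aln <- simulate_nt_alignment(clock, 400, rate_multiplier = rates_true[i],
                                 seed = 86 + i)
    mean(site_rates(aln, clock))
  }, 0)
  expect_true(all(diff(est_means) > 0))
})

test_that("informativeness profiles peak at 1/(4 lambda) and add over sites", {
  none <- pi_profile(rep(0, 10))
  expect_true(all(none$PI == 0))

  for (lam in c(0.8, 2, 5)) {
    prof <- pi_profile(lam, t_grid = seq(0.005, 1, by = 0.005))
    expect_lt(abs(attr(prof, "t_star") - 1 / (4 * lam)), 0.006)
  }

  lam_a <- c(0.5, 1.2, 3)
  lam_b <- c(0.9, 2.2)
  pa <- pi_profile(lam_a)
  pb <- pi_profile(lam_b)
  pab <- pi_profile(c(lam_a, lam_b))
  expect_equal(pab$PI, pa$PI + pb$PI)

  expect_error(pi_profile(1, t_grid = numeric(0)), "empty")
  expect_error(pi_profile(1, t_grid = c(0, 0.5)), "\\(0, 1\\]")
})

test_that("variation records assemble all per-gene statistics", {
  sp <- simulate_species_tree(8, seed = 91)
  clock <- ultrametricize(sp)
  aln <- simulate_nt_alignment(clock, 200, rate_multiplier = 1.2, seed = 92,
                               gene = "demo")
  rec <- variation_record(aln, clock)
  expect_equal(rec$gene, "demo")
  expect_equal(rec$L, 200)
  expect_equal(rec$PV, rec$S / rec$L)
  expect_gt(rec$PI_max, 0)
  expect_true(rec$t_star > 0 && rec$t_star <= 1)
})
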