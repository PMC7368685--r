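---
title: "Quantifying plastid gene-tree discordance and its molecular-evolutionary correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plastid gene-tree discordance and its molecular-evolutionary correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Plastomes are routinely analyzed as if their genes were a single linked
locus, yet individual plastid protein-coding genes (PCGs) can tell visibly
different phylogenetic stories. `plastidscape` measures that disagreement
gene by gene and asks what molecular-evolutionary properties of a gene
predict it. This vignette is the package's methods account: the statistics
it computes, the models behind its simulator, the tunable parameters and the
reasoning behind every default, and what the bundled tests do and do not
demonstrate.

## The discordance statistic (GD)

Gene trees and one or two species trees (typically a coalescent summary tree
and a concatenation tree) are placed in a common Robinson-Foulds (RF) tree
space. RF distance is the symmetric-difference count of non-trivial
bipartitions between the unrooted forms; all trees must first be restricted
to a shared taxon set. The pairwise RF matrix is ordinated by classical
principal coordinate analysis (PCoA): the squared-distance matrix is
double-centered and eigendecomposed, coordinates exist only for positive
eigenvalues, and negative eigenvalues are reported, not corrected — GD uses
only axes 1 and 2, and Cailliez/Lingoes corrections rescale the embedding
unpredictably without changing the ordering of distances we care about.

A gene's discordance GD is its Euclidean distance to the coalescent species
tree in axes 1–2. A gene tree topologically identical to the species tree
has an identical RF profile and therefore GD exactly 0; the ordination
enforces this by assigning bit-identical coordinates to items with identical
distance profiles, so the zero is exact rather than a rounding accident.
Unnormalized RF feeds the ordination by default (`rf_normalized` switches
this); with a fixed common taxon set the choice rescales GD without
reordering it.

Missing data are handled the way practitioners prune real data sets: a
bounded greedy pass drops a locus when removing it strictly enlarges the
common taxon intersection (the sporadically missing gene case), then all
trees are pruned to the intersection; every removal is logged, and the
pruning report deliberately surfaces inconsistencies rather than resolving
them silently.

## Partitioned coalescence support (PCS)

PCS asks, for each gene, whether it pushes a summary-coalescent analysis
toward or away from the species tree. The optimality criterion is the
quartet score: the number of 4-tip subsets resolved identically in the gene
tree and a candidate species tree, computed by brute-force enumeration over
all `choose(n, 4)` subsets (exact and fast at plastome scale; n = 26 gives
14,950 quartets). For each internal branch (clade) of the species tree the
candidate set is either the two nearest-neighbor-interchange rearrangements
at that branch (default) or user-supplied alternative trees (e.g. a
concatenation ML tree); the best alternative lacking the clade is the one
with the highest total quartet fit over genes, and a gene's per-clade PCS is
its fit difference between the species tree and that alternative. Because
the per-gene score the field reports is a single integer whose aggregation
is not standardized, both behaviors are exposed: the default sums over all
clades, and `clade =` restricts to one focal branch; the output records
which was used. Quartet counts are left as unnormalized integers so genes
with missing taxa contribute exactly the quartets they carry.

## Substitution rates: NG86 with Jukes-Cantor correction

Per-gene dN, dS and dN/dS are estimated by Nei-Gojobori (1986) counting:
fractional synonymous/nonsynonymous site counts per codon (mutations to stop
codons count toward neither class), pathway averaging over the orderings of
multi-difference codons with stop-passing pathways excluded, and the
Jukes-Cantor correction d = -(3/4) ln(1 - 4p/3). Proportions at or beyond
the correction's domain (p >= 0.75) and dS = 0 yield missing values, never
zeros or infinities. Codon columns containing gaps, ambiguity codes or stops
in either sequence of a pair are skipped for that pair, mirroring strict
gap-cleaning. A counting estimator was chosen over ML codon-model fitting
deliberately: it is deterministic, dependency-free and checkable against an
exhaustive enumeration oracle codon by codon, and the downstream analyses
need relative rates and a purifying-selection signal rather than ML point
estimates. The known cost is a transition/transversion bias: NG86 weights
transitions and transversions equally when counting sites, so when the true
process has kappa > 1 it overestimates dS and biases omega downward (the
package's neutrality calibration therefore simulates at kappa = 1 to
isolate the counting machinery, while the purifying-selection recovery runs
at kappa = 2 and tolerates the modest downward pull).

Unit estimates are means over all sequence pairs (pairs with a missing value
leave that rate's mean); unit omega is the ratio of mean dN to mean dS,
which is stabler than averaging pairwise ratios and defined whenever mean dS
is positive. Functional-group and region rates concatenate the member genes
codon-respectingly — taxa missing a gene receive gap codons, which pairwise
comparisons skip — and apply the same estimator. Group and region membership
is entirely configuration-driven (two two-column TSVs; packaged defaults
cover the standard plastid functional groups and a typical quadripartite
LSC/SSC/IR gene order), because region assignment of boundary genes after an
IR expansion is a data-set-specific judgment call.

## Variation and phylogenetic informativeness

Segregating sites S count columns with two or more unambiguous bases;
nucleotide diversity pi is the mean pairwise per-site mismatch proportion
under pairwise deletion (configurable in spirit, but pairwise deletion is
the default because it uses all comparable data in gappy plastome
alignments); PV = S/L; parsimony-informative sites require two states each
in two or more sequences. Per-site rates are maximum-likelihood JC69 rate
multipliers on a fixed relative-time ultrametric tree (root depth 1),
computed by Felsenstein pruning with a vectorized golden-section search on
[0, `lambda_max`] to a bracket tolerance of 1e-6; invariant columns get rate
0 and columns are collapsed to unique site patterns first. `lambda_max`
defaults to 20 substitutions per site per unit relative time — roughly two
orders of magnitude above the benchmark's median site rate, so the bound is
inert except for saturated columns. Townsend's quartet informativeness
rho(t; lambda) = 16 lambda^2 t exp(-4 lambda t) is summed over sites on a
grid over (0, 1]; because the single "net PI" number reported in the
literature does not pin down an evaluation time, the package reports the
whole profile plus its maximum and argmax, and rankings use the maximum by
default.

The clock tree comes from `ultrametricize()`: mean-path-length smoothing
(each internal node's age is its mean path length to descendant tips,
clamped so parents are never younger than children, then rescaled to root
age 1), with midpoint rooting for unrooted inputs. This replaces external
clock-ML tools; it is deterministic and adequate for relative-time
informativeness profiling, though it is not a substitute for calibrated
divergence-time estimation.

## Correlation report

The 12-panel report correlates each of dN, dS, omega with GD, pi, PV and the
PI maximum (Pearson r, two-sided t test on n - 2 degrees of freedom), with
pairwise exclusion of genes missing either variable, so n varies by panel
exactly as per-gene tables with gaps do. Raw p-values with a 0.05 convention
are reported (a Holm flag exists for users who want family-wise control).
Phylogenetically independent contrasts are deliberately out of scope: the
genes share one genome, and the analysis this package mirrors treated them
as exchangeable observations too.

## The synthetic benchmark: what it emulates

`make_benchmark_dataset()` generates the study conditions the package is
tested under: 26 taxa and the 76 PCGs shared by typical angiosperm
plastomes, with realistic per-gene coding lengths (90–6,837 bp, 67.7 kb
total), functional groups and a typical quadripartite region assignment.

- **Species tree**: a Yule tree (`birth_rate` 1) rescaled to `coal_height`
  10 coalescent units — deep enough that most branches are mostly
  concordant, shallow enough that short internal branches still sort
  incompletely, i.e. moderate ILS.
- **Gene trees**: the multispecies coalescent with one haploid lineage per
  species (one plastome per taxon), k(k-1)/2 coalescence rate per branch,
  free coalescence above the root; validated against the closed-form
  three-taxon concordance probability 1 - (2/3)exp(-T).
- **Sequences**: GY94/M0 codon simulation on the 61 sense codons (exact
  per-branch transition matrices, F3x4 frequencies from AT-rich
  position-specific base composition, kappa = 2), with branch lengths
  `mu` = 0.012 expected codon substitutions per coalescent unit times a
  heavy-tailed per-gene multiplier r_g (lognormal, sdlog 0.7) times a region
  factor (IR 0.3, LSC 1.0, SSC 1.3 — inverted repeats evolve slowest, the
  small single-copy region fastest). The resulting per-gene pi spans roughly
  0.005–0.1, the range observed in real congeneric plastome panels.
- **Selection**: per-gene omega is drawn coupled to r_g
  (`omega_base * r_g^0.5 * lognoise`, clamped to (0.02, 0.9)) so every gene
  is under purifying selection and faster genes are under weaker constraint
  — the empirical pattern the correlation analysis is designed to detect.
- **Discordance coupling**: gene g's species tree is scaled by
  `r_g^ils_rate_coupling` (default exponent 1) in coalescent units before
  coalescent simulation, then the gene tree is rescaled back so sequence
  divergence stays governed by mu and r_g alone. Slow genes thus experience
  deeper coalescence and more topological discordance, planting the negative
  discordance-rate association at construction level; estimation noise (slow
  genes also carry less signal for tree building) reinforces it. Setting the
  exponent to 0 removes the planted association.
- **Gene loss**: the 11 NDH genes are deleted from one clade of about six
  taxa (clade-restricted loss), and one small ribosomal-protein gene
  (`rpl33` by default) from two random taxa (sporadic loss). The pipeline's
  pruning pass then reproduces the canonical handling: the sporadic locus is
  dropped, the clade's taxa are pruned from tree space.

What the generator does **not** emulate: recombination and introgression
(gene trees differ only through ILS), indels and alignment error (alignments
are simulation-perfect; gaps arise only from whole-gene loss), among-gene
linkage (plastid genes are physically linked; here gene trees are
conditionally independent given the species tree), codon-position rate
structure beyond F3x4, and base-compositional heterogeneity across lineages.
Passing tests therefore demonstrate the correctness and calibration of the
estimators under a clean MSC + M0 world, not robustness to alignment error
or model violation on real data.

## Numerical and reproducibility choices

- All randomness flows from one master seed; each stage derives its own seed
  by hashing the stage name (`derive_seed`), so stages re-run in isolation
  reproduce their output, and identical config + seed gives byte-identical
  files.
- JC distances cap saturated pairs (p >= 0.75) at `d_max` = 5
  substitutions/site — finite, but far beyond any resolvable distance, so
  saturated pairs do not dominate neighbor joining. Negative NJ branch
  estimates are clamped to zero.
- PCoA eigenvector signs follow a deterministic convention (the
  largest-magnitude loading is positive); GD is invariant to the choice.
- Degenerate tree spaces (all trees identical) yield an empty embedding and
  GD 0 rather than an error.
- Golden-section maximization was chosen over derivative-based search for
  the per-site rates because the likelihood is cheap, unimodal in practice,
  and the method is immune to flat-gradient pathologies at lambda = 0.

## Problem sizes used by the test suite

Oracle-equivalence tests enumerate all 15 five-tip topologies and hundreds
of random eight-tip pairs; simulator calibration uses 10,000 three-taxon
coalescent replicates per branch depth; omega recovery uses 20 replicates of
20 taxa x 300 codons per regime; the end-to-end recovery study runs the full
26-taxon, 76-gene benchmark across 20 seeds. These sizes give Monte-Carlo
standard errors comfortably inside the asserted bands while keeping the
whole suite desk-scale.

## Known limitations

- NG86's transition bias (above) makes absolute omega values conservative
  when kappa > 1; relative comparisons across genes are unaffected.
- GD depends on the composition of the tree set (PCoA axes are re-estimated
  per data set), so GD values are comparable within one analysis, not across
  analyses.
- PCS with NNI alternatives explores only the immediate neighborhood of the
  species tree; a gene can conflict with the species tree in ways no NNI
  alternative captures. Supplying explicit alternative trees covers the
  cases practitioners care about most.
- The mean-path ultrametricization is a relative-time heuristic; absolute
  ages and rate units downstream of it are relative quantities by design.
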