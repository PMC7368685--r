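Package: plastidscape
Title: Plastid Gene-Tree Landscapes: Discordance, Substitution Rates and
    Phylogenetic Informativeness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying gene-tree/species-tree discordance across
    plastid protein-coding genes and relating it to molecular-evolutionary
    gene characteristics. Builds Robinson-Foulds tree spaces over per-gene
    trees, ordinates them by principal coordinate analysis and measures
    per-gene discordance (GD) as the distance to the coalescent species tree;
    computes quartet-score partitioned coalescence support (PCS); estimates
    dN, dS and dN/dS by Nei-Gojobori (1986) counting with Jukes-Cantor
    correction per gene, functional group and plastome region; computes
    nucleotide diversity, segregating sites, percent variability and Townsend
    phylogenetic-informativeness profiles from per-site rates on a
    relative-time ultrametric tree; and correlates rates with gene
    characteristics. A multispecies-coalescent plus codon/nucleotide sequence
    simulator with planted rate heterogeneity and gene loss exercises the
    whole pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
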