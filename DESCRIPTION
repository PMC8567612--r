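Package: achiasma
Title: Tetrad Segregation, Mutation Accumulation and Recombination-Signal
    Analysis for Achiasmate Yeast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for detecting (or excluding)
    meiotic crossing over from whole-genome data of tetrad-forming yeasts.
    Provides a ground-truth simulator for hybrid parental genomes, meioses
    with configurable crossover and gene-conversion rates, intratetrad
    matings and diploid mutation-accumulation genealogies; high-confidence
    discriminant-marker selection from per-sample allele depths; parental
    origin assignment, 2:2/3:1/4:0 segregation classification and
    crossover / non-crossover / loss-of-heterozygosity event calling with
    maximum tract bounds; base-substitutional mutation-rate estimation
    with exact Poisson confidence intervals, composition-weighted AT-bias
    and equilibrium-GC estimation, and mitotic LOH detection; per
    chromosome tree-concordance scoring with five unrooted topological
    tree distances normalised against random tree pairs; and genome-wide
    linkage-disequilibrium decay curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
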