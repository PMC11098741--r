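Package: cellsnv
Title: Germline and Somatic SNV Calling from Sparse Single-Cell Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects germline and putative somatic single-nucleotide variants
    (SNVs) from sparse single-cell sequencing evidence. Germline genotype
    likelihoods computed from pooled read pileups are refined with a
    haplotype-copying hidden Markov model over a phased reference panel,
    exploiting population-level linkage disequilibrium (LD). Persistently
    discordant loci feed a 12-category sequencing-error model; candidate de
    novo SNVs are filtered on depth, allele fraction and a support-vector
    classifier. Somatic SNVs are separated from germline ones by cell-population
    LD refinement: two- and three-locus allele cosegregation profiles over
    distance bins phase each de novo SNV against neighbouring germline
    heterozygotes and score the fraction of cells in which alleles do not
    cosegregate. Includes benchmarking metrics, projection-Procrustes ancestry
    inference, and a synthetic-data generator (copying-process panel, clonal
    cell populations, allelic dropout, fragment-level physical phasing) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
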