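Package: mutscreen
Title: Quantitative Analysis of Fluorescent-Reporter Mutagenesis Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of flow-cytometry based mutagenesis
    screens of a fluorescent reporter gene in yeast. Provides per-cell
    fluorescence phenotyping with Z-score mutant calling against replicate
    controls, estimation of the frequency of activity-affecting mutants from
    paired treated/control fluorescence distributions with conversion to a
    Poisson mutation load and a mutagen-calibrated spontaneous mutation rate,
    functional classification of mutants into coding, cis-regulatory,
    trans-acting and copy-number classes from reporter-gene mutation records
    and pyrosequencing allele fractions, dominance analysis in heterozygous
    diploid crosses including model II regression of haploid against diploid
    effects, and a seeded synthetic-data generator with truth tables for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
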