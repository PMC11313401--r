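Package: rhizotyper
Title: Molecular Typing, Diversity and Symbiotic Screening of Rhizobial Isolate Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising collections of root-nodule bacteria
    (rhizobia) trapped from field soils. Implements in-silico PCR-RFLP typing
    of the 16S-23S rRNA intergenic spacer (restriction digestion, virtual gel
    binning and fingerprint grouping), multilocus sequence analysis (MLSA)
    species assignment against a type-strain panel with novel-genospecies
    clustering, symbiovar calling from nodulation genes, Hill-number alpha
    diversity and community-environment ordination, a weighted symbiotic
    performance score with compact-letter significance display, and
    abiotic-stress tolerance screening and ranking. A synthetic community
    generator with planted ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    vegan,
    withr,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
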