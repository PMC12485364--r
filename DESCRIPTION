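Package: homoplasyD
Title: Rate-Variation Artifacts in Site-Pattern Tests for Introgression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how lineage-specific substitution-rate variation
    corrupts site-pattern tests for introgression (Patterson's D and
    HyDe-style tests) in shallow four-taxon phylogenies. Provides exact
    expected ABBA/BABA/BBAA site-pattern frequencies under the multispecies
    coalescent with introgression (MSci) and Jukes-Cantor (JC69) multiple
    hits, with per-lineage relative-rate multipliers; a coalescent and
    sequence simulator for four-taxon genomes built from independent
    short loci; block-jackknife D-statistic and HyDe-style tests; a
    relative rate test; and scenario orchestration for false-positive-rate
    and power summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
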