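Package: glycoproteomap
Title: Mapping the Plasma N-Glycome onto the Circulating Proteome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for correlating total plasma N-glycome profiles measured by
    HILIC-UPLC with high-multiplex (aptamer-style) plasma protein levels.
    Provides a parser for Oxford-notation N-glycan structure labels, a
    catalog-driven engine that derives 113 glycan traits (36 chromatographic
    peak percentages plus 77 derived group, sub-fraction and ratio traits)
    from peak areas, rank-based inverse-normal scaling, an all-pairs
    discovery association scan with Bonferroni control followed by
    sign-consistent nominal replication in a second cohort, and a synthetic
    cohort generator in which the glycome is an abundance-weighted mixture of
    protein-specific glycoform profiles with planted, recoverable
    protein-glycan links.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
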