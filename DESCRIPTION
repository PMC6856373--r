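Package: naddkit
Title: Discovery and Characterization Toolkit for NADH Diphosphatases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-analysis toolkit for the NADH diphosphatase (NADD)
    subfamily of Nudix hydrolases. Provides a Prosite-syntax pattern engine
    carrying the designed NADD detection pattern, a binary NADD classifier
    with zinc-site, Nudix-box and signature annotation, taxonomy and
    Pfam-style domain-architecture profilers, a MISTIC-style mutual
    information coevolution analyzer for protein alignments, a
    neighbor-joining tree builder with column-bootstrap support, a
    Michaelis-Menten kinetics fitter with catalytic-efficiency reporting,
    and seeded synthetic-data generators that make every component testable
    without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
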