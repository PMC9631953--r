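Package: sexscaff
Title: Sex-Linked Scaffold Identification from Male and Female Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assigns genome-assembly scaffolds to autosomes, the X and the Y
    chromosome by combining two lines of evidence: the normalized female:male
    average-depth ratio (AD-ratio) computed from per-scaffold coverage
    summaries of one male and one female sample, and homology anchoring of
    scaffolds to a chromosome-level reference of a related species via a
    merged-interval best-hit dominance rule. Putative Y scaffolds are
    confirmed with known Y marker genes while excluding scaffolds that also
    carry the X or autosomal homolog, and the two assignment methods are
    reconciled into a consensus with length-weighted agreement statistics.
    Includes a fully labelled synthetic-data generator (karyotype
    fragmentation, Gamma-distributed depths, noisy alignment and marker-hit
    evidence) so the whole pipeline is testable end to end against known
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    IRanges,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
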