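Package: snpchar
Title: Functional Characterization of Coding SNPs Between Yeast Strains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for functional characterization of single nucleotide
    polymorphisms (SNPs) located in open reading frames, modelled on
    comparative resequencing of Saccharomyces cerevisiae laboratory strains.
    Provides a quality-filter cascade for candidate SNP calls (read depth,
    region uniqueness and phred-quality thresholds), codon-level
    classification of each SNP as silent, missense, nonsense or stop-loss
    under the standard genetic code, profiling of amino-acid physicochemical
    property changes against homologue multiple alignments, per-column
    conservation statistics (reference and variant match frequencies,
    dominant-residue frequency and Conservation Distance), hypergeometric
    term enrichment with multiple-testing correction, summary reporting, and
    a fully seeded synthetic-data generator producing ORFs, candidate SNPs
    with known effect labels, and homologue alignments with controlled
    conservation for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
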