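Package: polybs
Title: Polysome-Resolved RNA Bisulfite Sequencing Analysis of m5C Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Candidate 5-methylcytosine (m5C) site calling from bisulfite
    converted RNA-seq alignments using a read-level non-conversion filter
    (3C), signal-to-noise flagging (S/N90), quality- and end-masked pileups,
    and per-replicate coverage/evidence thresholds (30RC, 5C, 80CT, 10MM),
    together with site annotation (transcript features, metagene profiles,
    spatial and codon enrichment, sequence context, base-pairing profiles)
    and polysome-fraction methylation-trend analysis (fuzzy c-means
    clustering of per-fraction non-conversion profiles and pairwise
    binomial logistic-regression differential methylation). Includes a
    synthetic-data generator that emulates stranded bisulfite conversion
    with planted methylation stoichiometry across polysome fractions, so
    the whole pipeline is testable against a known truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    Rsamtools,
    rtracklayer,
    graphics,
    stats,
    utils
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
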