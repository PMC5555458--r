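Package: ripseed
Title: RIP-Seq Target Calling and miRNA Seed Site Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identify transcripts bound by an RNA-binding protein from RNA
    immunoprecipitation sequencing (RIP-Seq) count data and quantify the
    enrichment of conserved microRNA seed-match sites in the 3' untranslated
    regions of the bound mRNAs. Implements library-proportion adjusted counts,
    an IP enrichment score against pre-IP total RNA, a negative-binomial Wald
    test for IP versus control enrichment with Benjamini-Hochberg target
    calling, canonical 8mer/7mer-m8/7mer-A1 seed-site scanning with a
    median-over-isoforms site-density statistic, hypergeometric gene-set
    overlap and Fisher phenotype statistics for genetic enhancer screens, and
    a negative-binomial synthetic-data generator with planted ground truth
    that makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
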