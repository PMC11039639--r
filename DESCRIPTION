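Package: pandiff
Title: Differential TF-Gene Regulatory Networks and Signature-Reversion
    Drug Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds condition-specific transcription-factor to gene
    regulatory networks by legacy PANDA message passing from RNA-seq
    counts, a TF binding-motif prior and a TF-TF protein interaction
    network; contrasts two conditions edge-wise to obtain differential
    targeting scores; tests per-TF targeting changes (Wilcoxon
    signed-rank with Benjamini-Hochberg correction); runs rank-based
    gene set enrichment of differential gene targeting; and matches
    signed top-TF signatures against a drug-signature database by
    cosine similarity to nominate signature-reversing repurposing
    candidates.  Includes a synthetic-data generator with planted
    ground truth so the whole pipeline is testable without external
    cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
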