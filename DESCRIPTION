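Package: ptscore
Title: Polytranscriptomic Scoring and TWAS-Based Gene Prioritisation for
    Case-Control Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for downstream analysis of transcriptome- and proteome-wide
    association study (TWAS/PWAS) summary statistics in case-control designs:
    triage of high-confidence disease genes from association, colocalisation,
    HEIDI and fine-mapping evidence; construction of polytranscriptomic scores
    (PTS) by expression-correlation clumping and p-value thresholding of TWAS
    Z-scores; evaluation of PTS against disease status and clinical outcomes
    with conversion of variance explained to the liability scale and
    inverse-variance meta-analysis across expression platforms; directional
    drug-gene and ATC drug-class enrichment; and comparison of inferred versus
    observed differential expression. A synthetic-data module generates every
    pipeline input under a liability-threshold model with known ground truth,
    so all stages are testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
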