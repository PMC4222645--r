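Package: cistrans
Title: Cis and Trans Regulatory Divergence from Allele-Specific
    Expression in F1 Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies cis and trans regulatory divergence between a
    domesticated lineage (maize) and its wild progenitor (teosinte) from
    allele-resolved RNA-seq read counts in F1 hybrids and parent inbreds.
    Provides a synthetic-data generator with known regulatory truth,
    replicate pooling and library-size correction, per-cross and overall
    maize:teosinte expression ratios with depth filters, binomial and
    Fisher's exact tests with Storey q-value FDR control, seven-category
    regulatory classification, depth-weighted consistency tiers for
    candidate gene lists, cis-share and leave-one-out influence metrics,
    per-gene weighted variance partitioning between parents, dominance
    analysis with iterative Dixon outlier exclusion, and gene-set
    enrichment utilities for selection scans, QTL intervals, and
    methylation annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    graphics,
    stats,
    utils,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
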