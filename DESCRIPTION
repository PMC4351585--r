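Package: meqtlscan
Title: Genome-Wide Methylation QTL Discovery, Enrichment and Replication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for discovering methylation quantitative trait
    loci (meQTL) at genome scale: computation of methylation beta-values from
    intensity pairs with detection masking and probe/sample quality control,
    cell-composition surrogate principal components and per-CpG variability
    profiles, a proximal/distal SNP-CpG association scan based on nested
    ordinary least squares models (likelihood-ratio p-values and partial R2
    effect sizes) with Benjamini-Hochberg false discovery rate control per
    distance class, LD-defined region construction with feature enrichment by
    SNP resampling, interaction-network proximity analysis, and a replication
    harness with QQ/lambda diagnostics. Includes a synthetic-cohort generator
    that plants genotype effects of known latent partial R2 so that every
    stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    vcfR,
    jsonlite,
    withr
Config/testthat/edition: 3
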