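Package: cuticula
Title: Cuticle Trait Differentiation Between Alpine and Foothill Plant
    Ecotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for establishing ecotypic differentiation in
    leaf cuticle traits between alpine and foothill plant populations grown
    in reciprocal common gardens. Computes minimum leaf conductance and
    water saturation deficit from leaf drying curves, droplet contact
    angles from sessile-drop geometry, and per-leaf-area cuticular wax
    abundances from GC-MS peak tables with internal-standard and
    retention-index calibration. Trait and per-compound differentiation is
    tested with random-intercept linear mixed models (Type III F tests with
    Satterthwaite degrees of freedom) and Benjamini-Hochberg correction.
    Genetic differentiation is assessed with a targeted allele-frequency-
    difference selection scan over a defined gene set in autotetraploid
    genotype data (outlier SNP calling, SNP-to-gene mapping with flanking
    regions, per-gene outlier density, candidate selection, coding-effect
    classification) and a parallel negative-binomial differential-expression
    contrast with growth condition as covariate. A synthetic-data generator
    produces all pipeline inputs with the statistical structure the
    analysis assumes, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    edgeR,
    jsonlite,
    lme4,
    lmerTest,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
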