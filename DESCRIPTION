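Package: fnrscape
Title: Inference of Oxygen-Responsive Fnr Regulons from ChIP-Seq and RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to infer the direct regulons of the paralogous
    oxygen-responsive transcription factors Fnr1 and Fnr3 in
    Herbaspirillum seropedicae by integrating ChIP-Seq binding with
    RNA-Seq differential expression across fnr deletion strains.
    Implements sliding-window enrichment peak calling against a total-DNA
    input under a robust normal model, a negative-binomial exact test for
    count data, binding-by-expression classification of promoters into
    Fnr1-only, Fnr3-only and co-regulated groups, ZOOPS EM discovery of
    14-bp binding motifs with half-site decomposition to assess hybrid
    (heterodimer) sites, and a seeded synthetic-data generator that
    emulates the full study design for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
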