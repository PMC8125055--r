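Package: napregulon
Title: Integrative Mapping of a Nucleoid-Associated Protein Regulon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to map the regulon of a bacterial nucleoid-associated
    protein (NAP) such as the mycobacterial xenogeneic silencer Lsr2 by
    integrating ChIP binding sites with differential-expression tables.
    Implements windowed AT-content scans of GC-rich bacterial chromosomes,
    orientation classification of binding sites against gene models (tandem,
    convergent, divergent, intragenic), nearest-site spacing statistics with a
    bridged-gene estimate, regulon calling from log2 fold-change tables,
    strand-aware promoter-window extraction and direct-target assignment,
    promoter AT-composition tests against random promoter backgrounds,
    cross-condition regulon comparison, and the Ra surface-roughness statistic
    for AFM line profiles with a pooled-SD two-sample t-test. A synthetic-data
    generator produces desk-scale genomes, annotations, binding sites,
    expression tables and roughness profiles with a machine-readable truth
    object so every stage of the pipeline can be scored end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
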