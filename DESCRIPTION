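Package: ervmine
Title: Mining and Dating Endogenous Retrovirus Envelope Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discovers endogenous retrovirus (ERV) envelope (env) genes in
    genome assemblies and dates their insertions. Long open reading frames
    are screened against retroviral protein profile HMMs (HMMER3 ASCII
    profiles, local Viterbi scoring with Gumbel E-values), candidate
    proviruses are delimited by their flanking long terminal repeat (LTR)
    direct repeats, LTR pairs are aligned and converted to insertion ages
    under a neutral substitution rate, env-ORF families are clustered and
    summarised by plurality consensus, and envelope proteins are annotated
    for furin cleavage and receptor-binding motifs. A fully seeded
    synthetic-genome generator plants proviruses of known age, family and
    ORF intactness so that every stage can be validated against ground
    truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    ape,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
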