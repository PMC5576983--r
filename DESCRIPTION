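Package: gbgcCodon
Title: GC-Biased Gene Conversion and Synonymous Codon Usage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of synonymous codon usage (SCU) in relation to
    GC-biased gene conversion (gBGC): relative synonymous codon usage
    (RSCU) and GC3 from coding sequences, intronic and flanking GC from
    gene models, genetic-map interval arithmetic (crossover rates in
    cM/Mb, DSB hotspot densities, strand-aware metagene profiles),
    a tRNA mono/multi-isoacceptor test of translational selection,
    expression-stratified contrasts and a sequential (Type-I) variance
    partition of GC3. Includes a synthetic-genome simulator with an
    isochore-like recombination/GC landscape, meiotic-expression-dependent
    intragenic crossover suppression and two switchable generative regimes
    (gBGC-driven versus tRNA-coadapted codon usage) so that every stage of
    the analysis can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
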