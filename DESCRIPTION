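Package: strainmet
Title: Strain-Level Chemical and Genomic Heterogeneity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing how much specialized-metabolite diversity is
    hidden below the species level in bacterial strain collections. Implements
    MS/MS molecular networking with modified-cosine spectral similarity,
    diagnostic tag-fragment classification of compound groups, exact-mass
    molecular-formula decomposition with ppm error control, semi-quantification
    of extracted-ion-chromatogram peak areas relative to a reference strain,
    metabolite-profile clustering with generalized-log and Pareto scaling,
    pan-BGC (biosynthetic gene cluster) presence/absence statistics, and
    silent/non-silent mutation profiling of conserved-cluster coding
    sequences. A seeded synthetic-data generator produces spectra,
    chromatograms, abundance matrices, BGC matrices and mutated CDS sets with
    known ground truth so every stage is testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    ape,
    Biostrings,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'formula.R'
    'genome.R'
    'network.R'
    'pipeline.R'
    'profiles.R'
    'quantify.R'
    'spectra-io.R'
    'synthetic-data.R'
    'tags.R'
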