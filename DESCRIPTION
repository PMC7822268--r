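Package: oligofunnel
Title: Enumeration, Annotation and Selection of siRNA and Antisense Oligonucleotides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline toolkit for rational design of antisense
    oligonucleotides (ASOs) and small interfering RNAs (siRNAs) against a
    target transcript. Enumerates every candidate k-mer tiling the primary
    transcript, annotates each candidate with GC content, SNP overlap,
    exon-junction spanning, cross-species/splice-variant conservation,
    nearest-neighbor duplex thermodynamics and distinct-gene off-target
    counts at 0-2 mismatches (via an internal pigeonhole seed-and-verify
    search), scores candidates with a point-based siRNA checklist and a
    motif/thermodynamics ASO score, and drives a configurable selection
    funnel with a positional-diversity final pick. Includes a HELM-style
    monomer notation for chemically modified oligos and a seeded synthetic
    fixture generator so complete workflows run with no network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    vcfR,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    withr
Config/testthat/edition: 3
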