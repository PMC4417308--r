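Package: cpmap
Title: Linkage Mapping, Scaffold Anchoring and Immunity-Gene Cataloguing
    for Outcrossed Full-Sib Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds genetic linkage maps from biallelic SNP genotypes of a
    cross-pollinated (CP) full-sib F1 family: segregation classification and
    chi-square filtering of markers, two-point recombination-fraction and LOD
    estimation with parental phase inference, LOD-threshold grouping, marker
    ordering with ripple refinement, and Kosambi map distances.  Anchors and
    orients genome-assembly scaffolds onto the map, compares maps through
    shared scaffolds, places external loci, classifies immunity-related
    proteins (NB-ARC, TIR, LRR, kinase, LysM, WRKY architectures) from HMMER
    domain hits, and detects physical clusters of resistance genes.  Includes
    a synthetic-data generator with a fully known ground truth so every stage
    is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
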