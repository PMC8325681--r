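Package: paleowgd
Title: Whole-Genome Duplication Inference from Synteny, Ks Distributions and
    Gene-Tree Topologies
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and dates ancient whole-genome duplications (WGD) from
    gene order and coding sequence divergence, following the evidence chain
    used in paleopolyploidy studies of the tea plant and its relatives:
    collinear synteny block detection in gene-rank space with syntenic-depth
    ratios, duplicate-pair mode classification (WGD, tandem, proximal,
    dispersed), Nei-Gojobori (NG86) Ka/Ks estimation with Jukes-Cantor
    correction, Ks-distribution peak location by kernel density or Gaussian
    mixtures with cross-species substitution-rate correction, molecular dating
    by Ks = 2rt, rooted gene-tree topology classification of shared versus
    lineage-specific WGD, and ancestral karyotype reconstruction with
    fission/fusion bookkeeping. A fully seeded simulator generates genomes,
    codon-aligned sequence pairs and gene trees with recorded ground truth so
    every stage is testable without external genome assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    mclust,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
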