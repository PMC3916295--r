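Package: detsv
Title: Deterministic Structural Variant Detection from Overlapping Paired-End Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects structural variants (SVs) from long overlapping paired-end
    reads at single-base resolution, independently of the library fragment-size
    distribution. Mate pairs are merged through their central overlap to recover
    the exact fragment sequence and length; 5'-end seeds are placed uniquely on
    the reference and each pair is classified as concordant or discordant by an
    exact mapping-distance rule; discordant fragments are aligned to a minimal
    reference with affine gap penalties to localize breakpoints; breakpoints and
    read-pair connections form a directed weighted multigraph whose connected
    components are typed by isomorphism against a catalog of sixteen prototype
    signatures (insertions, deletions, tandem duplications, inversions,
    insertional duplications and cut-and-paste translocations). Includes
    concordant/discordant coverage tracks with zygosity inference, two-sample
    call intersection and sequence-context analyses, and a simulator that
    plants SVs, generates overlapping read pairs and scores recall against the
    planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    graphics,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
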