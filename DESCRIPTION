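Package: rmeshalign
Title: Reconfigurable-Mesh Parallel Progressive Multiple Sequence Alignment Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the reconfigurable-mesh (r-mesh) parallel computing model
    and the mesh components built on it for constant-time dynamic-programming
    sequence alignment: unary (1UN) bit arithmetic, max switches, an
    adder/subtractor, and an on/off switch, composed into alignment meshes for
    Needleman-Wunsch, Smith-Waterman and longest-common-subsequence dynamic
    programming with optional affine gap costs.  On top of the pairwise engine
    it provides counting-form sum-of-pairs column scoring, neighbor-joining
    guide trees, and an end-to-end progressive multiple sequence aligner, each
    cross-validated against independent sequential reference implementations.
    Resource accounting reports the processing-unit counts of the mesh
    constructions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
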