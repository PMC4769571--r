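Package: hmmstripe
Title: Striped Profile-HMM Filter Pipeline with Saturating Integer Arithmetic
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implementation of the three heuristic filter stages of the
    hmmsearch homology-search pipeline (SSV, MSV and the Plan-7 Viterbi
    filter) on a striped multi-lane layout with saturating 8-bit and 16-bit
    integer arithmetic, closed-cycle lane reordering, warp-style
    max-reduction and Lazy-F evaluation of the Delete-Delete recursion.
    Every striped kernel is verified bit-exactly against a naive sequential
    dynamic-programming oracle on the same quantized integers. Also models
    warp work scheduling, shared-memory occupancy and kernel-variant
    selection for the GPU execution scheme the layout is designed for, and
    ships generators for random profiles, random sequences and
    planted-motif benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
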