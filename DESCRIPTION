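Package: mscosine
Title: Batched Greedy and Modified Cosine Scoring for Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Exact, match-limit-aware greedy and modified (precursor-shift)
    cosine similarity for MS/MS spectral library matching. Spectra are packed
    into zero-padded batches with per-spectrum metadata (peak counts, cosine
    norms, precursor m/z), the reference-by-query grid is tiled into
    independent blocks, and every pair yields a (score, match count,
    overflow) triple, assembled densely or as a threshold-filtered sparse
    coordinate list. Includes MGF and MSP readers, a single/double precision
    compiled kernel, a brute-force reference scorer, a Hungarian-cosine
    bound for small instances, a synthetic spectral-library generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
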