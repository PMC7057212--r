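Package: phasemerge
Title: Phase-Set Comparison, Origin-Shift Search and Referential
    Clustering for Fragment-Based Crystallographic Phasing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares crystallographic phase sets in reciprocal space under
    the origin shifts allowed by the space group, clusters consistent partial
    solutions by referential clustering on the weighted mean phase difference
    (wMPD), and merges each cluster into an averaged phase set whose phases
    carry more information than any single member.  Includes SHELXE-style
    .phs reading and writing, direct structure-factor summation from toy
    coordinate models, discrete, sparse (layer-1) and FFT origin-shift search
    algorithms for nonpolar and polar space groups, parallel chunked
    clustering rounds, pairwise map correlation matrices with an eigenvector
    embedding, and a synthetic solution-landscape generator for benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
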