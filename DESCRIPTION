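Package: msabench
Title: Synthetic Multiple Sequence Alignment Annotation Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic multiple-sequence-alignment (MSA) benchmark
    corpora with exact region ground truth, renders them as annotated raster
    images, drives interchangeable annotators (a parametric simulated
    annotator, vision-language-model response parsing, and human TSV import),
    and scores extracted region names and residue-range boundaries with
    pooled precision/recall/F1 and per-endpoint mean absolute error,
    including signed-error histograms for diagnosing row-offset mistakes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
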