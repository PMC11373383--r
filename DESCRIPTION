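Package: dafsweep
Title: Sample-Size-Invariant Selective Sweep Classification with 1D
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies genomic windows as neutral or containing a hard
    selective sweep from a compact, sample-size-invariant representation:
    the per-locus derived allele frequency vector fused with the vector of
    inter-SNP distances.  Provides a small 1D convolutional network family
    with an exhaustive grid architecture search, 2D raw-genotype reference
    baselines with early/late position fusion, a bit-packed binary window
    format, a coalescent-simulation harness (driven by msprime) emulating
    sweep detection under confounding demographies (bottlenecks, ancient
    structure, recombination hotspots), and a sliding-window genome scanner
    for ms-style simulator output and VCF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
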