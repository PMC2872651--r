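Package: pairedCNA
Title: Paired Tumor/Germline SNP-Array Copy-Number and LOH Profiling with
    Printable Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes copy-number and loss-of-heterozygosity (LOH) profiles
    from paired tumor and germline reference SNP-array genotyping tables.
    Provides PCR fragment-size filtering, median-centered log2 intensity
    ratios, Gaussian-kernel genomic smoothing, hidden Markov model
    segmentation of both copy-number and LOH tracks with distance-dependent
    transitions, merging of nearby LOH areas, classification of altered
    regions (gain, loss, homozygous deletion, copy-neutral LOH), UCSC Genome
    Browser annotation, and a printable PDF report with genome-wide and
    per-chromosome profile plots. Includes a paired-sample simulator with
    injected ground-truth alterations (including glioma-like 1p/19q-codeleted
    and chr7-amplified archetypes) for end-to-end validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
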