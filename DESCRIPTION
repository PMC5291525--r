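Package: zccurve
Title: Z-Curve Correlation Analysis of Strand Composition Bias in Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Windowless quantification of the correlation between AT and GC
    compositional biases along bacterial chromosomes using the Z-curve
    decomposition. Computes cumulative Z-curve components and AT/GC disparity
    tracks, the Z-curve correlation coefficient (ZCC) and the analogous RY-MK
    index, infers replication origin and terminus from detrended disparity
    extrema or accepts curated oriC tables, partitions circular chromosomes
    into replichores, assigns genes to leading or lagging strands, and
    aggregates per-genome results into phylum-level summaries (sign
    percentages, Tukey-fence outliers, polymerase-class cross-tabulations).
    Includes a synthetic generator of strand-asymmetric circular genomes with
    annotated genes so every stage can be exercised without downloads.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
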