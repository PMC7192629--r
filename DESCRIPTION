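Package: s3norm
Title: Simultaneous Normalization of Sequencing Depth and Signal-to-Noise
    Ratio in Epigenomic Signal Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalizes binned epigenomic signal tracks (ChIP-seq, ATAC-seq)
    across samples by a monotone two-factor power-law transformation that
    simultaneously matches the mean signal in common peak regions and the
    non-zero mean signal in common background regions between each target
    and a reference. Includes a dynamic negative-binomial background model
    with MACS-style local-lambda control scaling for producing -log10
    p-value tracks, Benjamini-Hochberg region calling, FRiP-based reference
    selection, baseline normalizers (total-signal, quantile, simplified
    MA-plot), a synthetic multi-sample track simulator with known ground
    truth, and an end-to-end pipeline over bedgraph input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
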