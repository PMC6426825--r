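Package: karyoflow
Title: Karyotype Analysis and Flow-Cytometric Genome Size Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing and classifying animal karyotypes from
    chromosome arm-length measurements and for estimating nuclear DNA content
    and genome size from flow-cytometry fluorescence data. Karyotype analysis
    covers Levan centromere classification, optimal homologous-chromosome
    pairing, cross-cell aggregation (mean +/- SEM), the fundamental number,
    karyotype formula, asymmetry indices (AsK, L/S, proportion of arm ratios
    above 2:1), Stebbins classification and idiogram construction. Genome size
    estimation implements histogram peak detection with doublet rejection and
    coefficient-of-variation quality control, the internal-standard ratio
    equation Y = N/M * X, and the picogram-to-base-pair conversion
    (0.978 x 10^9 bp per pg). Seeded synthetic-data generators for arm
    measurements and propidium-iodide-style fluorescence histograms make every
    pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
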