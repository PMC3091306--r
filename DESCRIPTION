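Package: lipidscan
Title: Shotgun Lipidomics Spectra Alignment, Fragmentation Queries and
    Isotopic Correction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Informatics pipeline for direct-infusion (shotgun) lipidomics
    on tandem mass spectrometers. Averages repeated scans into representative
    spectra by resolution-dependent mass binning, aligns MS and MS/MS spectra
    of many acquisitions into a flat-file MasterScan database with
    per-acquisition intensity vectors, identifies and quantifies lipid
    species de novo with a molecular fragmentation query language (sum
    compositions, compositional constraints, double-bond equivalents and
    fragment patterns), corrects intensities of partially overlapping
    isotopic clusters in both MS and MS/MS modes, and ships synthetic-data
    generators reproducing the validation experiments end to end. Reads
    mzXML and plain peak lists; no external data required.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
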