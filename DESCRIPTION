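Package: dicomflow
Title: DICOM Retrieval, Metadata Extraction and Scanner Analytics for Research Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for moving radiology imaging from a PACS into a
    research store and working with it there. Provides a real-time
    storage-class listener that files incoming DICOM instances into a
    hierarchical store, an on-demand extractor that expands query CSVs into
    C-FIND-filtered C-MOVE batches with retry and halt-and-resume, a
    profile-driven extractor that writes PHI-free header metadata into
    per-profile document collections, nightly storage cleanup with safety
    interlocks, and operational analytics: scanner utilization from exam
    timestamps and clock-miscalibration detection from receipt-versus-
    acquisition skew. A synthetic multi-scanner fleet generator and an
    embedded mock PACS make the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
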