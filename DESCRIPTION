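Package: mzcurate
Title: Headless Curation Engine for MS1 Feature Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A headless engine for creating, editing, storing, and serving
    manually curated MS1 feature annotations. Stores (m/z, retention time,
    intensity) point clouds in an alternating-dimension spatial index,
    answers budget-limited window queries with a deterministic
    peak-preserving representative subset (weighted striding), and
    implements the editing semantics of isotopic-trace and
    isotopic-envelope curation: rectangle point selection, proximity and
    segment-sweep trace grouping, noise marking behind a visibility guard,
    and charge-state ruler geometry. Reads mzML MS1 spectra, round-trips an
    annotated CSV dialect and a bookmark TSV dialect, exposes the store
    through a JSON request API, and ships a synthetic LC-MS generator with
    known trace and envelope ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    mzR,
    stats,
    utils
Suggests:
    httpuv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
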