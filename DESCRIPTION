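Package: dicomvault
Title: Desk-Scale Management of DICOM Imaging Studies with Deterministic
    Asset Identifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for organizing raw magnetic-resonance imaging data and its
    derivatives at desk scale: deterministic (name-based) 128-bit asset
    identifiers, immutable single-file DICOM archives with a three-domain JSON
    descriptor and per-file checksums, acquisition-protocol compliance
    validation gating image extraction, a transactional registry of projects,
    individuals, timepoints, assets and quality ratings, convention-based
    import of scalar variables at three attachment levels with cross-level
    wide-table querying, and a provenance-tracking activity/job subsystem with
    precomputed output identifiers. A seedable synthetic DICOM study generator
    makes every component testable without any external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    digest,
    dplyr,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    tools,
    utils,
    stats
Suggests:
    openssl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
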