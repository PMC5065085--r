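Package: specdx
Title: Parse, Decompress and Convert JCAMP-DX Spectral Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for ingesting JCAMP-DX spectral files (UV/Vis, IR, MS):
    a full codec for the ASDF compressed numeric forms (FIX, PAC, SQZ, DIF,
    DIFDUP), a staged ingestion pipeline (clean, uncomment, record
    extraction, validation, standardization, decompression) that annotates
    every discrepancy instead of failing, a JCAMP writer, exporters to a
    pseudo-JCAMP XML dialect and to SciData JSON-LD, a chemical identifier
    catalog with multi-identifier search plus offline request builders for
    PubChem, Wikidata and Splash integrations, and a seeded generator of
    realistic synthetic spectra for testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
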