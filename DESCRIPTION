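Package: plateparse
Title: Declarative Positional Parsing of Multiwell Plate Reader Exports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plate readers export measurements in esoteric, instrument-specific
    layouts; analysis packages expect tidy tables with metadata attached.
    'plateparse' bridges the two with declarative parser specifications that
    locate measurement blocks purely by position (1-based row/column
    coordinates, as a user sees the file in a spreadsheet), extract and coerce
    the values, reshape them into tidy long format, and join them to
    user-supplied metadata keyed on well. Raw files in CSV, semicolon/decimal-
    comma CSV2, TSV, plain text and Excel are supported; parser specifications
    serialize to portable JSON (or YAML) for reuse. A deterministic fixture
    generator fabricates instrument-style exports with known ground truth so
    that every parsing path is testable without proprietary instrument files,
    and a command-line interface exposes the build/validate/run workflow for
    scripting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cellranger,
    data.table,
    dplyr,
    jsonlite,
    purrr,
    readr,
    readxl,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
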