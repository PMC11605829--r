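Package: thermoscreen
Title: Thermostability Screening of Annotated LC-MS/MS Metabolite Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative metabolome screen that separates heat-stable from
    heat-sensitive compounds by contrasting annotated LC-MS/MS feature tables
    of a filter-sterilized versus an autoclaved fermentation medium. Reads and
    validates delimited compound tables, computes per-treatment relative
    abundances (peak area divided by mean peak area), partitions compounds
    into shared and treatment-exclusive sets, classifies shared compounds by
    the Rf/Ra stability ratio into heat-stable anti-aging candidates and
    heat-sensitive growth-inhibiting candidates, and summarizes them by
    chemical superclass. Includes a synthetic paired-table generator with
    known ground truth for end-to-end validation, and a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
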