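Package: virallometry
Title: Allometric Scaling of Viral Capsid Volume, DNA Packing Density,
    and Virion Energy Budgets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of virus capsid geometry and
    genome size. Reads and curates virus trait tables (capsid shape and
    dimensions, genome type and length), computes capsid volumes, inner
    volumes corrected for wall thickness, DNA packing fractions, and fits
    the allometric power law Vc = a*Lg^m per virus group by log-log
    ordinary least squares. Includes the derived biophysical models:
    ATP-denominated genome replication and capsid translation costs as a
    function of capsid radius, thin-shell hoop stress and the
    pressure-density scaling implied by the allometric exponent, and a
    seeded synthetic-population generator for end-to-end validation of
    the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
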