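Package: ebusbenefits
Title: Health and Climate Benefits of School Bus Electrification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A benefit assessment pipeline for replacing diesel school buses
    with electric ones. Converts per-mile emission factors into ambient PM2.5
    concentration changes through a sparse source-receptor matrix, applies
    log-linear concentration-response functions to obtain attributable adult
    mortality and childhood asthma onset, monetizes impacts with a value of
    statistical life updated for income growth and inflation, a cessation lag
    and discounting, and accounts for lifetime greenhouse-gas flows valued
    with a social-cost-of-carbon schedule. A deterministic synthetic-domain
    generator provides grid cells, counties, populations, baseline rates and
    a pseudo source-receptor matrix so the whole pipeline is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
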