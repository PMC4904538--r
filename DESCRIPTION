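Package: mesoapportion
Title: Apportionment of Asbestos-Related Mesothelioma Risk Across Exposures
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the relative contribution of each above-background
    asbestos exposure period to an individual's mesothelioma, from an
    exposure history (year, months, relative 8-hour TWA concentration,
    relative fiber potency) and the year of diagnosis.  Each entry's
    absolute mesotheliogenic risk is concentration x potency x months/12
    x (lagged time since exposure)^2, with a configurable latency lag,
    time exponent and optional plateau cap; risks are normalized to
    percentage contributions and subtotaled by product or workplace
    group.  Includes literature-derived relative potency presets for
    chrysotile and amphibole fibers, a mixed-fiber potency calculator,
    CSV input/output, text/CSV/JSON report rendering and a seeded
    exposure-history generator for simulation studies.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
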