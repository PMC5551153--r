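Package: citrusvol
Title: Volume Rate Adjustment for Pesticide Applications in Citrus Orchards
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decision support for adjusting the spray mix volume rate (L/ha)
    of plant protection product applications in citrus orchards treated with
    airblast sprayers. Computes a recommended volume rate from canopy geometry
    (ellipsoid model), leaf area density, the pest or disease target class and
    the product mode of action, following the CitrusVol methodology. Includes
    the cube-sampling estimator of leaf area density, savings calculators for
    paired conventional/adjusted field applications (mix reduction, product
    savings, tank refill time), and the classical dose-expression systems
    (Tree Row Volume, Leaf Wall Area, Unit Canopy Row) as comparators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    tibble,
    dplyr,
    readr,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
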