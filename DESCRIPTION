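Package: focalspot
Title: Focal Spot Position Measurement for Bore-Type Linacs from Bar-Shadow Beam Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Measures the lateral x-ray focal spot position of bore-type linear
    accelerators (e.g. helical tomotherapy machines) from ionization-chamber
    beam profiles acquired through a suspended metal bar at two heights. The
    bar's shadow produces a dip in each profile; the dip center is located as
    the zero crossing of the derivative of current with respect to chamber
    position, and the difference between the dip-center deviations at the two
    bar heights is inverted through the projection magnification geometry to
    give the signed lateral focal-spot offset. Includes a seeded forward
    simulator of the measurement (ray-traced cylindrical-bar attenuation,
    focal-spot blur, chamber aperture averaging, reading noise, repeat and
    between-session variability), a GUM-style Type A / Type B uncertainty
    budget with root-sum-square combination, delimited-text profile I/O, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
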