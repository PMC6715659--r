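Package: gelmob
Title: Enzyme Mobility in Polysaccharide Gels from Time-Lapse
    Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies enzyme mobility in pectin/cellulose gels from
    time-lapse deep-UV autofluorescence image stacks: camera background
    and flat-field (shading) correction by morphological filtering,
    region-of-interest geometry along the enzyme migration axis,
    random-line and circle intensity sampling with z-averaging,
    normalized kinetic and spatial profiles, and penetration-depth
    summaries.  Includes a ground-truthed synthetic acquisition
    simulator (finite-reservoir reaction-diffusion with non-fluorescent
    obstacles, vignetting, shot and read noise, defocus) so the whole
    chain is testable at desk scale, plus hydrodynamic-radius scaling
    laws and effective-diffusivity recovery from extracted profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
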