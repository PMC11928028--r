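Package: biofilmwave
Title: Ion-Channel Electrical Signalling Models for E. coli Biofilms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models and analysis tools for ion-channel-mediated electrical
    signalling in Escherichia coli biofilms under blue-light stress. Provides
    a two-channel Hodgkin-Huxley-type membrane-potential model with a
    reactive-oxygen-species stress variable and knockout variants, a 3D
    agent-based fire-diffuse-fire simulator of potassium wavefronts in
    spherical biofilms with a critical-radius estimator, anomalous-transport
    wavefront analysis (power-law fits of R(t)^2 = Rc^2 + b*t^gamma,
    transport classification, velocity-curvature relations), Thioflavin-T
    fluorescence trace analysis (peak calling and latency statistics), and
    synthetic-data generators for trace ensembles, wavefront tracks and
    rendered 3D image stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
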