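Package: rotifd
Title: Trait-Based Functional Diversity and Beta-Diversity Partitioning for
    Zooplankton Communities Along Eutrophication Gradients
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how eutrophication restructures and
    homogenizes zooplankton (rotifer) communities. Implements the weighted
    composite trophic level index (TLIc) from lake water chemistry,
    categorical trait tables and functional-group composition, distance-based
    functional diversity indices (FRic, FEve, FDiv) in a corrected principal
    coordinate trait space, and partitioning of total beta diversity into
    species replacement and richness-difference components with triangular
    (triad) coordinates. A Gaussian-niche synthetic community generator
    emulates a monthly multi-site survey along a mesotrophic-to-eutrophic
    gradient so the whole pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    ape,
    vegan
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
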