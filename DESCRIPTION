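Package: osteoROM
Title: Automated Osteological Range-of-Motion Analysis for Vertebral Chains
Version: 0.1.0
Authors@R: person("osteoROM", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exhaustive, automated assessment of intervertebral osteological
    range of motion (ROM) from watertight triangle meshes of vertebrae.
    Builds hierarchical vertebral chains in an osteological neutral pose,
    fits sphere-based centres of rotation to zygapophyseal facets, samples
    the full interacting roll/yaw/pitch Euler grid per joint, classifies
    poses by bone-bone collision and zygapophyseal articulation criteria,
    and summarises mobility with cosine-corrected pose spaces, alpha-shape
    volumes and whole-chain summed rotations. Includes a parametric
    generator of stylised, watertight synthetic vertebrae with ground-truth
    geometry so the entire pipeline is testable without specimen scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    data.table,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
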