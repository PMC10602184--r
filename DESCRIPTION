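Package: roctscan
Title: Robotic Large-Area OCT Scanning Simulation and En-Face Parameter Maps
Version: 0.1.0
Authors@R: person("roctscan", "maintainers", email = "roctscan@example.org",
    role = c("aut", "cre"))
Description: Simulates a robotic optical coherence tomography (OCT) scanning
    rig for large-area tissue imaging: scanline planning, probe landing and
    closed-loop normalized-surface-depth altitude regulation over virtual
    samples (letter-extrusion phantoms, layered kidney-like tissue with
    tubular lumens), with B-scans synthesized from the single-scattering
    attenuation model. Provides the post-scan reconstruction stack:
    pose-based pixel-to-world transforms and voxelization, depth-encoded
    surface maps, extinction-coefficient maps via log-linear fits,
    lumen segmentation with centerline diameter mapping, overlap-averaged
    stitching of per-scanline maps, and velocity-sweep quality-degradation
    analysis based on structural similarity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
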