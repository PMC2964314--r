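Package: HexaTrack
Title: Assisted 3D Kinematic Tracking of Multi-Marker Insect Legs from
    Stereo High-Speed Video
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing full leg-joint kinematics of tethered
    walking insects from synchronized stereo high-speed video of painted
    joint markers. Provides pinhole camera calibration from a jig of known
    geometry, ray back-projection and midpoint triangulation with the
    associated error metrics, background-subtraction image preprocessing,
    semi-automatic marker tracking through exponentially scaled ellipsoid
    search volumes with triangulation and segment-length gating and
    bidirectional propagation from user keyframes, normalization into an
    animal-centered body frame, joint-angle computation for the full
    thorax-coxa / coxa-trochanter / trochanter-femur / femur-tibia kinematic
    chain, and dual-method stride segmentation (anterior/posterior extreme
    positions and foot-height clustering). A synthetic stereo-video
    generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    signal,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'HexaTrack-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils-geometry.R'
    'stereo.R'
    'topology.R'
    'image.R'
    'ellipsoid.R'
    'tracking.R'
    'bodyframe.R'
    'kinematics.R'
    'strides.R'
    'synthetic.R'
    'io.R'
    'cli.R'
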