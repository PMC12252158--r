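Package: fallwatch
Title: Skeleton-Based Fall Detection from Keypoint Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for rule-based human fall detection from 2D pose
    keypoint tracks.  Provides a per-frame pose data model with derived
    torso landmarks (neck, centroid, ground projection), the three
    kinematic fall discriminants (bounding-box aspect ratio, centroid
    descent speed, trunk-ground angular change), a frame-sampled fall
    judgment state machine with latched alerts, random-erasing occlusion
    augmentation for rasters (whole-image, keypoint-box, and combined
    modes), contract-tested building blocks of lightweight detection and
    high-resolution keypoint networks (channel shuffle units, serial
    spatial pyramid pooling, shuffle attention, bottleneck attention,
    multi-scale fusion) implemented as plain array operations, and a
    synthetic trajectory simulator emulating walking, lying, and falling
    behaviours so the whole stack can be exercised without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
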