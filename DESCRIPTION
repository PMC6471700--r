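Package: nirdr
Title: Near-Infrared Diffuse-Reflectance Imaging Pipeline for Occlusion Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multiplexed-LED near-infrared (NIR) diffuse
    reflectance videos acquired with a smartphone-class camera. Provides a
    synthetic acquisition simulator (multiplexed white/690/800/840 nm source
    states, low-rank specular surface layer, smooth subsurface absorption,
    venous-occlusion response, fiducial marker, sensor noise), red-channel
    intensity-profile demultiplexing into per-wavelength images, singular value
    decomposition (SVD) eigen-band reconstruction for surface-noise removal,
    intensity-based rigid coregistration onto a white-light anatomical image,
    and box-sampled paired t-test statistics with a 0/1/2 hypothesis counter
    for rest/occlusion/release comparisons.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
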