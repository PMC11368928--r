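Package: roctscan
Title: Robotic Large-Area Optical Coherence Tomography Scanning Simulator and Parameter Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses robotic large-area optical coherence
    tomography (OCT) scans of ex-vivo tissue. Provides raster scanline
    planning with lateral overlap, an image-feedback probe-altitude
    controller that regulates the normalized surface depth of the tissue in
    each B-scan, a virtual scanner that renders single-scattering B-scans
    from synthetic scenes (letter phantoms and kidney-like tissue with
    tubule lumens), pose-based voxelization of tracked B-scans into a
    base-frame tissue volume, and three large-area two-dimensional
    parameter maps: surface depth (DEPM), extinction coefficient (ATCM)
    and tubule-lumen diameter (DIAM). Includes elevational-downsampling
    speed-sweep analysis with a structural-similarity quality score and a
    file-based pipeline with deterministic, manifest-driven reruns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
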