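Package: breastvol
Title: Breast Volume from 3D Torso Surface Scans via Simulated Chest Walls
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes breast volumes from 3D stereophotogrammetry surface
    meshes (Wavefront OBJ) by simulating the hidden chest wall behind the
    breast. Five anatomical landmarks define a reference frame and an
    eight-point breast boundary; a framework of vertical cubic Bezier curves,
    tuned by a single handle-length fraction (BCHL), is lofted into the
    simulated chest wall; the breast is cut from the torso and capped into a
    watertight solid whose enclosed volume is reported in millilitres.
    Includes validation utilities (signed distance maps against a true
    breastless chest wall, the area-times-distance volume-error statistic,
    landmark repeatability measures with classical t-tests), a voxelization
    oracle for volume cross-checks, and a parametric synthetic-torso
    generator with analytically known breast volume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
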