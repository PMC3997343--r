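Package: insecthull
Title: Natural-Colour 3D Digitization of Insect Specimens from Multi-View
    Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multi-view photogrammetry pipeline for building textured,
    watertight 3D surface models of pinned insect specimens from turntable
    image sets. Implements shape-from-silhouette visual hull carving on a
    voxel grid (dense and octree-accelerated), extended depth-of-field
    focus stacking for macro-mode capture, chroma-key silhouette
    extraction, turntable kinematics and fiducial-mat camera pose
    estimation, per-face texture atlas baking, mounting-pin removal in 2D
    masks or on the 3D mesh, and mesh export to OBJ, PLY, STL and X3D. A
    bundled synthetic-scene ray-cast renderer stands in for the physical
    camera rig, providing calibrated views, focus stacks, ground-truth
    mattes, depth maps and analytic volumes so that every pipeline stage
    can be validated on one CPU.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    yaml,
    jsonlite,
    xml2,
    igraph,
    mgcv,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
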