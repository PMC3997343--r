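---
title: "Methods: multi-view digitization of pinned insect specimens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-view digitization of pinned insect specimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the reconstruction model and its assumptions, the parameters that matter,
the design decisions that were genuinely open, and what the synthetic
test bed does and does not establish about real captures.

## The reconstruction model

A pinned specimen sits at the origin of a right-handed, specimen-centred
frame with +Z up along the pin axis; all lengths are millimetres, and
angles are degrees at API boundaries (radians internally). A two-axis
turntable pans the specimen about +Z and tilts the whole stage about +X
under a fixed camera that looks at the origin. Rotating the specimen by a
rotation S under a fixed camera pose (R_rig, t_rig) is the same as
leaving the specimen fixed and orbiting the camera: the world-to-camera
map becomes (R_rig S, t_rig). Camera axes are +X right, +Y down, +Z
forward, so pixel coordinates grow right and down; pixel (row r, col c)
has centre (c − 0.5, r − 0.5). Lenses are assumed distortion-free (or
pre-rectified) with square pixels — telecentric enough that macro-rail
frames need no mutual alignment or rescaling, which is what a rail (as
opposed to refocusing the lens) provides.

The geometric engine is shape-from-silhouette. A binary silhouette in a
calibrated view back-projects to a cone containing the specimen; the
visual hull is the intersection of those cones, always a superset of the
true surface and blind to concavities. We realize it on a voxel grid:

* a voxel survives iff, in **every** view, at least one of its sample
  points (default: the centre; optionally the 8 corners) projects inside
  that view's silhouette;
* a silhouette is dilated by `dilatePx` (default 1 px) before carving —
  an over-large silhouette only inflates the hull, never truncates the
  specimen, so errors stay on the safe side;
* voxels that project outside a view's image, or behind its camera, are
  **not** carved by that view. Physically the mat occludes the specimen's
  underside, so "unseen" must not mean "absent".

The octree carver (`carveOctree`) prunes nodes using the fact that a box
wholly in front of the camera projects inside the convex hull of its
corner projections: if that pixel rectangle contains no silhouette pixel
(and lies fully inside the image) the node is empty; if it is entirely
silhouette in every view the node is fully occupied. Both tests are
conservative, so the octree result is bit-identical to dense carving at
the same resolution — and the equality is asserted in the tests rather
than assumed.

Photo-consistency refinement of concavities is deliberately out of
scope: strong specular reflection and fine structures (legs, antennae,
setae) limit what colour-consistency can add for insect surfaces, and
the hull alone carries the geometry this pipeline targets.

## Surface extraction

The occupancy field is padded with one empty voxel layer and sampled at
voxel centres; each lattice cube is split into six tetrahedra along its
main diagonal, and each tetrahedron contributes 0–2 triangles with
vertices at the midpoints of its sign-changing edges (the iso-0.5
crossing of a 0/1 field). We chose marching **tetrahedra** over
table-driven marching cubes because the 16-case tetrahedral table is
derived programmatically in a dozen lines and is easy to verify, whereas
the 256-entry cube tables must be transcribed and trusted; the two yield
equivalent surfaces for binary fields at this resolution. Triangles are
wound so normals point from occupied to empty, which makes the
divergence-theorem volume positive and lets watertightness be checked as
"zero boundary edges". A single occupied voxel meshes to a closed
surface with Euler characteristic 2.

One consequence of binary-field extraction is a staircase surface whose
raw face normals take only a few diagonal directions. Texture view
selection and sampling therefore use smoothed normals (face → vertex →
face averaging, two rounds, `smoothedFaceNormals`).

## Focus stacking

Macro lenses leave a sub-millimetre slab in focus, so macro mode captures
a rail sweep of typically 31 frames at 0.25 mm per view. Stacking is
deliberately simple and auditable:

* sharpness = local variance of the Laplacian of luminance (ITU-R BT.601
  weights), window 9 px — parameter-light and invariant to constant
  illumination offsets;
* per-pixel argmax across frames, ties to the lower index; the index map
  is median-filtered (radius 5 px) so isolated misfires vanish, and
  textureless pixels (sharpness below 1e-6 in every frame) inherit their
  smoothed neighbourhood index, having no evidence of their own;
* hard selection: each output pixel is copied verbatim from one frame,
  so the composite's colours are exactly input colours and an
  all-identical stack returns its frame bit-exactly.

Laplacian-pyramid blending would hide seams better but breaks the
colour-conservation invariant; it is noted as an extension, not a
default.

## Silhouettes and pin handling

Synthetic captures use a uniform chroma-key background; extraction
thresholds the per-pixel RGB distance (normalized so black-vs-white is 1;
default threshold 0.12), closes with a 3 px brush, drops components below
`minBlobPx`, and by default keeps the largest component plus whatever
touches it — on a real capture everything belonging to the specimen is
physically connected, and stray blobs are debris. Synthetic phantoms
whose parts are deliberately separated (a detached pin, floating legs)
set `keepAll = TRUE`; the pipeline default does, because its default
scene is such a phantom.

The mounting pin can be edited out at two points, with different costs:

* **2D masking before carving** (`applyExclusions`): polygons force pin
  pixels to background in each mask. Carving then removes every voxel
  that projects into an excluded region in any view — the pin, but also
  the specimen surface in the pin's "shadow", and any pin pixels left in
  the images contaminate the texture of faces reconstructed where the
  pin stood. The tests reproduce this trade-off explicitly.
* **3D editing after reconstruction** (`removePin`): component mode
  deletes everything but the largest connected component (the usual case
  when the pin reconstructs as its own hull component); cylinder mode
  deletes faces inside a user-given cylinder around the known pin axis
  and reports the hole as a boundary-edge count. No hole-filling is
  attempted.

## Texturing

Each face is assigned the single view that sees it most frontally among
the views where its centroid is unoccluded and front-facing; ties go to
the lower view id, and faces seen nowhere are flagged unseen and filled
with magenta (recorded in metadata). Occlusion is a depth-buffer test:
the whole mesh is rasterized per view at a configurable buffer width
(default 256 px) and a face is visible when its centroid depth matches
the buffer within a tolerance (default 3× the median edge length).
Single-view assignment leaves visible seams but keeps every texel
traceable to one photograph; multi-view blending is an extension.

The atlas packs two faces per square cell as right triangles (default
atlas 1024²); each texel's barycentric coordinates map to a 3D point on
the face, which is projected into the assigned image and sampled
bilinearly. Because the carved hull lies slightly **outside** the true
surface (dilation plus voxel quantization), sampling exactly on the
staircase can land on background at oblique faces; sample points are
therefore pulled inward along the smoothed normal by `sampleInsetMm`
(default 2× the median edge length). Texels at cell corners just outside
the UV triangle are clamped onto it so every sample stays on the face —
keeping the invariant that every texel is a bilinear combination of
source-image pixels from the assigned view.

## The fiducial mat

Commercial reconstruction software calibrates poses from a proprietary
printed mat, which cannot be reproduced; this package defines its own
printable design. `markerCount` black discs (default 12, diameter 8 mm)
sit evenly on a ring (default 50 mm); marker k is punched with k small
holes. Hole **count** is a topological property of the disc, preserved
under any projective view of the plane, so identity decoding needs no
pose estimate, no local orientation recovery, and survives steep tilts —
this robustness is why a count code was chosen over a binary satellite-
dot ring, which requires orientation decoding that degrades at 60° tilt.
Centroids of the hole-filled discs are sub-pixel. Pose follows from the
planar homography (normalized DLT) between known marker positions and
detected centroids, decomposed to a rotation and translation and refined
by Levenberg–Marquardt on the reprojection error (cost-change tolerance
1e-10, at most 100 iterations); collinear detections raise a degenerate-
configuration error. Joint refinement across views decouples per view
(intrinsics fixed, mat geometry known) and accepts a refined pose only
when its RMS does not increase, so the total RMS is non-increasing by
construction. When detection fails for a view the turntable kinematics
are the fallback — the rig angles are always known — and the pipeline
driver uses turntable poses as its baseline for the same reason.

## The synthetic rig

`renderView` ray-casts scenes of spheres, ellipsoids, cylinders and
boxes with exact analytic intersections: silhouettes, depth maps and
primitive volumes come with ground truth, and rendering is deterministic
bit-for-bit. Defocus is emulated by blurring the sharp render with a
Gaussian whose sigma is `blurGain · |depth − focal plane|` px, the depth
map quantized into 16 bins (error bounded by bin width × gain); the
default gain of 2 px/mm makes a ±1 mm defocus visibly soft at the
raster scales used here — the shallow macro depth of field that the
rail sweep exists to overcome. The default specimen phantom
(`weevilScene`) is a 3 mm body-length weevil — ellipsoid body, sphere
head, six 0.2 mm-diameter legs, 0.2 mm pin — at the small end of the
target range, with 0.2 mm gaps between parts so that the closed-form
volume oracle (which refuses overlapping bounding boxes) applies and the
pin forms its own hull component.

What the renderer does **not** emulate: specular and iridescent
reflectance, transparency (wings, membranes), soft shadows, sensor noise,
lens distortion, and background clutter. Passing tests therefore
establish the correctness of the geometry and the processing chain, not
robustness to those photometric effects; silhouette extraction on real
captures will need threshold tuning and possibly a reference background
image, both supported.

## Problem sizes and numerical choices

The validation suite runs the sphere-hull check at its full condition
(72 views, 128³ grid, 480 px images: volume within 5% of 4/3·πr³, with
the superset and monotonicity invariants asserted exactly) and scales
other scenes to 32³–96³ grids and 128–480 px images, sizes chosen so the
whole suite runs in minutes on a single core while every assertion keeps
a comfortable margin. End-to-end runs on exact synthetic masks set
`dilatePx = 0`: the 1 px dilation exists to keep noisy real segmentation
on the conservative side, and exact mattes need no such guard — with it,
the hull volume would carry a systematic positive bias of one pixel's
worth of metric thickness over the whole surface. Iso-level is fixed at
0.5; any level in (0,1) gives the same midpoint surface on a binary
field. Ties everywhere break to the lower index (frames, views, mesh
components) so reruns are bit-stable; the pipeline is deterministic
given its configuration, and the manifest records every parameter plus
the seed.

## Known limitations

* Concavities are unrecoverable by construction; the hull is an outer
  approximation.
* Structures thinner than about two voxels (fine setae, antennae tips)
  carve unreliably at default resolutions.
* Single-view texturing shows seams at view boundaries; unseen faces
  (deep underside when the mat blocks low views) stay magenta.
* Hole boundaries left by cylinder-mode pin removal are reported, not
  filled.
* The acquisition model assumes an ideal rig: exact angles, shared
  intrinsics, no hand-shake between focus frames.
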