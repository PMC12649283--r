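---
title: "Defacing head-and-neck radiotherapy data: method and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defacing head-and-neck radiotherapy data: method and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Surface renderings of head CT scans can be matched to a person by automated
facial recognition, which makes publicly shared head-and-neck (HNC)
radiotherapy datasets a re-identification risk. Generic defacing tools built
for neuroimaging remove or deform exactly the anatomy HNC research needs:
organs at risk (OARs) near the face, planning target volumes (PTVs), and the
body surface used for replanning studies. They also ignore the DICOM-RT
Structure Set and Dose objects, which carry enough 3D surface information to
render a face on their own.

`rtdeface` implements a landmark-based defacing rule for CT-simulation data
that removes the identifiable upper face while guaranteeing — by
construction, not post hoc repair — that every PTV voxel and every brain
voxel survives, and that the same removal is propagated consistently to the
Structure Set and the Dose grid.

## The defacing rule

All geometry is in DICOM LPS patient coordinates, head-first-supine:
anterior is decreasing $y$, superior is increasing $z$. Two scalars derived
from the clinically contoured eyes define the crop:

* $z_\mathrm{inf}$ — the position of the inferior-most CT slice containing
  any eye contour, snapped to the nearest slice position;
* $y_\mathrm{mid}$ — the anterior–posterior midpoint of the eyes, computed
  as the unweighted mean over eye ROIs of each ROI's vertex-centroid $y$.

A voxel $v$ is retained iff

$$ z(v) < z_\mathrm{inf} \;\lor\; y(v) \ge y_\mathrm{mid} \;\lor\;
   v \in \mathrm{PTV} \;\lor\; v \in \mathrm{Brain}. $$

Everything else — the eyes, eyebrows and forehead region — is removed. The
inferior-most eye slice itself is part of the cropped region (the crop
starts *at* that slice). Removed image voxels are set to a configurable fill
value, by default −1000 HU (air): pixels are removed rather than blurred or
deformed, because additive or deformation approaches retain recoverable
facial structure.

Design points that were genuinely open, and the choices made:

* **One global midpoint plane.** $y_\mathrm{mid}$ is a single coronal plane
  from the mean of the per-eye centroids, not a per-slice or per-eye
  threshold. A single planar cut is the simplest faithful reading of
  "anterior to the midpoint of the eye", and it makes the mask analytic in
  patient coordinates (which the dose resampler exploits).
* **Missing eyes are a hard error.** If no eye ROI with contour data is
  present the pipeline stops with a dedicated error (CLI exit code 2). No
  automatic eye segmentation fallback is attempted; contouring is a
  prerequisite, as it is in clinical practice.
* **Multiple eye ROIs** all contribute to $z_\mathrm{inf}$, and
  $y_\mathrm{mid}$ averages the per-ROI centroids; a single contoured eye is
  accepted with a warning. **Multiple PTVs** are preserved as a union.
* **Structure roles from names.** ROI roles (eye, lens, cornea, brain, ptv,
  body, other) are assigned from an ordered case-insensitive regex table
  (`default_role_patterns()`, editable via a plain-text config). Clinical
  naming varies between centres, so the table is a convention, not a fact
  about the data; notably `brainstem` must not match the brain pattern.

## Structure set and dose propagation

The defaced Structure Set drops the eye, lens and cornea ROIs outright;
keeps PTV and brain contour data byte-for-byte untouched; rebuilds the body
contour to follow the defaced surface; and clips any other ROI that
protrudes into the cropped region. Clipping happens in voxel space
(rasterize → intersect with the retain-mask → polygonize) rather than by
analytic polygon–plane clipping, because the PTV/brain carve-outs make the
kept region non-convex; voxel space handles every case uniformly at the
cost of sub-voxel fidelity. An ROI left with no voxels is kept with an
empty contour list and a warning rather than silently deleted.

For the dose, the crop rule is analytic in millimetres, so it is evaluated
directly at each dose voxel centre — no interpolation of a resampled mask.
PTV/brain membership, which is not analytic, is looked up at the nearest CT
voxel; nearest-neighbour (rather than trilinear) lookup keeps the
membership binary so preserved dose can neither leak nor erode at structure
edges. Removed dose voxels are set to 0 Gy and the grid extent is kept, so
the object remains valid for downstream DVH tooling; the writer re-derives
the dose-grid scaling so retained values round-trip within one quantization
step (32-bit stored values; quantization ≈ 3×10⁻⁸ of the maximum dose).

## Rasterization and polygonization

A voxel belongs to an ROI iff its centre lies inside an odd number of the
slice's polygons (pixel-centre even-odd rule) — deterministic and
independent of vertex order and winding, matching common RT rasterizers.
The inverse operation traces the 0.5-level iso-contours of each slice
(zero-padded so contours always close). Rasterize∘polygonize reproduces a
mask up to a one-voxel boundary band; the tests assert Dice ≥ 0.95 on random
blobs and exact agreement away from the band.

## DICOM handling

The package includes a deliberately minimal DICOM codec: Explicit VR Little
Endian, uncompressed, defined-length sequences, covering exactly the CT
Image, RT Structure Set and RT Dose attributes the pipeline touches.
Written objects get fresh series/instance identifiers (so they cannot
collide with the originals in an archive) while the frame-of-reference UID
is preserved; the structure set's image references point at the new CT
instances. Identifier generation can be seeded (`set_uid_seed()`) for
bit-reproducible outputs. Orientation support is restricted to axis-aligned
head-first-supine; anything else is rejected with an explicit error rather
than silently mis-cropped. The test suite cross-reads every written object
with an independent DICOM implementation (pydicom) to guard against
self-consistent-but-wrong encoding.

## The synthetic phantom

Patient CT-sim data cannot be shared, so validation runs on a synthetic
head phantom: an ellipsoidal head on a cylindrical neck, two spherical eyes
(radius 12 mm, centred 100 mm above the grid origin) near the anterior
surface with lens and cornea spheres anterior to the eye midpoint, a
posterior brain ellipsoid whose frontal edge reaches anterior of the eye
midpoint (so brain preservation is actually exercised), two parotid-like
and one mandible-like OAR inferior to the eyes, and a PTV placed per
`ptv_mode`:

* `below` — entirely inferior to the crop region,
* `same_slice` — on crop slices but posterior to the eye midpoint,
* `overlap` — protruding into the cropped region (a sinonasal-like target).

The dose is a Gaussian blob (70 Gy peak, 18 mm width) centred on the PTV,
on its own coarser grid. Default grid: 128×128×80 voxels at 2 mm. Per-tissue
HU values are plausible but arbitrary; the algorithm is purely geometric, so
only the contours matter. Seeded jitter rigidly shifts the whole anatomy and
perturbs the eye radii — this varies the induced landmarks for parameter-
recovery tests without ever breaking the declared PTV mode. After
generation the phantom recomputes the landmarks from its own structure set
and asserts its declared mode (infeasible geometry is an error).

One convention deserves note: eye contours are drawn on every slice whose
slab (one slice gap thick) intersects the eye sphere, with the circle
radius evaluated at the in-slab point nearest the sphere centre. This
partial-volume convention contours the sphere's full superior–inferior
extent, as clinical contours do, and it places the inferior-most contoured
slice at the slice nearest $z_\mathrm{centre} - r$ (88 mm for the default
eye) rather than one slice higher.

What the phantom does *not* emulate: realistic tissue texture and noise
structure, skull/sinus anatomy, contouring variability beyond rigid jitter,
and non-spherical target shapes. Passing tests therefore demonstrate the
geometric correctness of the pipeline — the preservation guarantees, the
mask algebra, the file round trips — not robustness to the full variability
of clinical contours.

## Numerical choices

* Landmark snapping: $z_\mathrm{inf}$ snaps to the nearest slice; contours
  are matched to slices within half a slice gap (beyond that they are
  skipped with a warning).
* Fill value: −1000 HU, mapped through the inverse rescale (slope 1,
  intercept −1024 gives stored value 24) and clamped to the stored-value
  range.
* Dice is computed on rasterized masks, not polygon areas; two empty masks
  score 1 (identical empty structures are not a mismatch), one empty mask
  scores 0.
* The PTV location category is evaluated against the *initial* crop region,
  before PTV/brain preservation.
* Youden-index threshold selection scans midpoints of consecutive sorted
  unique pooled distances plus sentinels; a pair matches when distance ≤
  threshold (the boundary counts as a match — the convention is fixed for
  determinism); ties in $J$ resolve to the smallest threshold. Statistical
  significance testing of distance distributions is delegated to standard
  routines (`wilcox.test`) and is not part of this package's surface.

## Problem sizes used in validation

The shipped tests run the anatomy on a 64×64×54 grid at 3 mm (the same
anatomy in mm as the default), with brute-force voxel oracles on grids up
to 32³ (100 random trials for the retain rule), 12 randomized specs for
landmark recovery, and 50 random instances for threshold selection. The
acceptance script regenerates the default-resolution phantom (128×128×80 at
2 mm), runs the full pipeline through DICOM files on disk, and recomputes
the two headline Dice values (below-crop OAR → 1; removed lens/cornea → 0)
from the written outputs.

## Known limitations

* Head-first-supine, axis-aligned volumes only; other orientations are
  rejected rather than handled.
* Co-registered volumes (e.g. CBCT) must already be resampled onto the
  planning-CT grid; the package applies the mask but does not register or
  resample images.
* The DICOM codec reads the dialect it writes (Explicit VR LE,
  uncompressed); clinical archives with other transfer syntaxes need
  conversion first.
* Re-identification through non-facial cues (dental work, contour-shape
  fingerprints) is out of scope, as is any face detection/embedding
  computation: recognition metrics operate on externally supplied distance
  lists.
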