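# rtdeface

Automated defacing of head-and-neck radiotherapy CT data and the DICOM-RT
objects that accompany it.

## Why

Surface renderings of head CT scans can be matched back to a person by
facial-recognition software, so publicly shared head-and-neck (HNC)
radiotherapy datasets carry a re-identification risk. Defacing tools built
for neuroimaging protect the brain but remove or deform the structures HNC
research depends on — organs at risk near the face, planning target volumes
(PTVs), the body surface — and they leave the RT Structure Set and RT Dose
untouched even though those objects contain enough 3D surface information
to render a face on their own.

`rtdeface` is for researchers curating HNC radiotherapy datasets for
sharing. It removes the identifiable upper face while guaranteeing, by
construction, that every PTV voxel and every brain voxel survives, and it
propagates the same removal to the Structure Set and the Dose grid.

## The rule

In LPS patient coordinates (anterior = smaller *y*, superior = larger *z*),
two scalars derived from the clinically contoured eyes define the crop:
*z*<sub>inf</sub>, the inferior-most CT slice containing an eye contour, and
*y*<sub>mid</sub>, the mean anterior–posterior centroid of the eyes. A voxel
*v* is retained iff

> *z*(*v*) &lt; *z*<sub>inf</sub> &nbsp;or&nbsp; *y*(*v*) ≥ *y*<sub>mid</sub>
> &nbsp;or&nbsp; *v* ∈ PTV &nbsp;or&nbsp; *v* ∈ Brain.

Removed image voxels become air (−1000 HU, configurable). In the Structure
Set, eye/lens/cornea ROIs are dropped, the body contour is rebuilt to follow
the defaced surface, protruding ROIs are clipped, and PTV/brain contours
pass through byte-identical. On the dose grid the (analytic) rule is
evaluated directly at each dose voxel centre, with PTV/brain membership
looked up at the nearest CT voxel; removed dose voxels become 0 Gy.

The package also ships a synthetic head phantom (CT + RTSTRUCT + RTDOSE,
with the PTV placeable below / beside / inside the crop region) so the whole
pipeline is testable without patient data, plus validation metrics: Dice
overlap, PTV-location classification, retained fractions, and Youden-index
threshold selection for face-recognition distance lists.

## Worked example

Generate an `overlap`-mode phantom (a sinonasal-like PTV protruding into the
crop region), write it as DICOM, and deface it:

```r
library(rtdeface)

spec <- phantom_spec("overlap", grid_shape = c(64L, 64L, 54L), spacing = c(3, 3, 3))
ph <- generate_phantom(spec)

td <- tempfile(); set_uid_seed(1)
paths <- write_outputs(ph$volume, ph$structures, ph$dose, file.path(td, "orig"))
report <- run_deface(paths$ct_dir, paths$rtstruct, paths$rtdose,
                     file.path(td, "defaced"), uid_seed = 2)
print(report)
#> <deface_report> z_inf=87.0 mm, y_mid=-45.0 mm; 27050/221184 voxels removed
#>   PTV category: overlap
#>   BODY             rebuilt   Dice 0.980
#>   Eye_L            removed   Dice 0.000
#>   Eye_R            removed   Dice 0.000
#>   Lens_L           removed   Dice 0.000
#>   Lens_R           removed   Dice 0.000
#>   Cornea_L         removed   Dice 0.000
#>   Cornea_R         removed   Dice 0.000
#>   Brain            kept      Dice 1.000
#>   Parotid_L        untouched Dice 1.000
#>   Parotid_R        untouched Dice 1.000
#>   Mandible         untouched Dice 1.000
#>   PTV70            kept      Dice 1.000
```

Reading the report: the crop starts at the slice 87 mm above the grid origin
(the inferior-most contoured eye slice) and removes everything anterior to
the eye-midpoint plane at *y* = −45 mm — 27 050 of 221 184 voxels. The six
facial ROIs are gone (Dice 0 against their original rasterizations), the
brain and the overlapping PTV are untouched (Dice 1 — every one of their
voxels was preserved even inside the crop), the OARs inferior to the eyes
are vertex-for-vertex unchanged, and the body contour was rebuilt to the
defaced surface (Dice 0.98 against the original: exactly the cropped face is
missing). `defaced/` now holds a re-readable CT series, Structure Set, Dose
and `report.json`.

The same pipeline is available from a shell:

```sh
Rscript inst/cli/rtdeface.R simulate --mode overlap --seed 1 --out /tmp/ph
Rscript inst/cli/rtdeface.R deface --ct /tmp/ph/ct --rtstruct /tmp/ph/rtstruct.dcm \
    --rtdose /tmp/ph/rtdose.dcm --out /tmp/defaced
Rscript inst/cli/rtdeface.R evaluate --original /tmp/ph --defaced /tmp/defaced
```

Exit codes: 0 ok, 2 eyes not contoured, 3 I/O error, 4 geometry error.

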