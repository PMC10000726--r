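# colonmri

Quantitative assessment of colonic content and morphology from unprepared
abdominal MRI, for researchers studying gut physiology, dietary
interventions and functional digestive disorders.

Unprepared MRI (no contrast, no gas/liquid infusion, no antiperistaltic
drugs) preserves the physiological state of the colon, but no single
sequence tells the whole story: T2-weighted images show the colon outline
(dark lumen against bright peri-colonic fat) while T1-weighted fat-saturated
(T1-FS) images discriminate the content (bright feces, dark gas — with fat
also dark, so the colon boundary vanishes wherever the lumen holds gas).
The two series are acquired in different breath-holds, so a non-rigid
deformation separates their coordinate spaces.

`colonmri` implements the complete analysis chain:

1. **T2 segmentation** — from ≥ 5 anatomical marker points: minimum-cost
   medial-path estimation through the dark lumen, a probabilistic tissue
   model `P(colon | intensity, path distance)` (kernel-density likelihood ×
   logistic distance prior), and exact binary MRF minimization by multigrid
   3D graph cuts (`segment_t2()`), with include/exclude refinement markers
   (`apply_refinement()`).
2. **T1-FS segmentation** — multiresolution non-rigid registration on
   modality-independent self-similarity descriptors
   (`register_t2_to_t1fs()`), then shape-preserving surface adaptation
   driven by a two-Gaussian fecal-content posterior, with expansion
   clamped to a 6 mm corridor (`adapt_colon_to_t1fs()`).
3. **Synchronized correspondence** — the displacement field
   `p ↦ p + d(p)` and its fixed-point inverse map any point or slice
   between the two spaces (`map_t2_to_t1fs()`, `map_t1fs_to_t2()`,
   `corresponding_slice()`).
4. **Quantification** — exact 1-D k-means classification of in-mask
   intensities into gas/mixed/solid with per-segment volumes
   (`classify_content()`, `quantify_content()`), and morphology (length,
   cross-sectional perimeter and radius per colon segment) from the T2
   side (`compute_morphology()`).
5. **Validation** — Dice coefficient and fecal-content containment R
   (`dice()`, `containment_r()`), plus a fully synthetic paired-acquisition
   phantom with complete ground truth (`generate_phantom()`) and a suite
   harness (`evaluate_phantom_suite()`).

Volumes are NIfTI-1 (`read_volume()` / `write_volume()`), markers a small
JSON dialect (`read_markers()`), deformation fields 3-component NIfTI, and
reports JSON/CSV. A command-line front end over the same functions is in
`inst/cli/colonmri.R`.

## Worked example

```r
library(colonmri)

# a synthetic subject: paired T2 / T1-FS volumes with known ground truth
phantom <- generate_phantom(phantom_spec(seed = 7))
#> <colon_phantom seed 7> 96x96x64 voxels; colon 16602 voxels (T2), 17270 (T1-FS)

# marker-guided colon segmentation in T2
seg_t2 <- segment_t2(phantom$t2, phantom$markers)
dice(seg_t2, phantom$mask_t2)
#> [1] 0.9888557

# transfer to T1-FS: non-rigid registration + surface adaptation
field <- register_t2_to_t1fs(phantom$t2, phantom$t1fs)
seg_t1fs <- adapt_colon_to_t1fs(seg_t2, field, phantom$t1fs)
containment_r(phantom$content_truth == 2, seg_t1fs)   # % feces contained
#> [1] 100

# content quantification
cmap <- classify_content(phantom$t1fs, seg_t1fs, k = 3)
quantify_content(cmap, seg_t1fs)
#>      segment gas_ml mixed_ml solid_ml total_ml solid_equivalent_ml
#> 1  ascending 26.640   16.056   16.332   59.028            31.08713
#> 2 transverse 17.472   25.140   27.396   70.008            50.49914
#> 3 descending 16.968   19.284   19.932   56.184            37.65360
#> 4     pelvic 20.460    3.576    3.564   27.600             6.85027
#> 5      total 81.540   64.056   67.224  212.820           126.09014

# morphology from the T2 segmentation
compute_morphology(seg_t2, attr(seg_t2, "medial_path"))
#>      segment length_mm mean_perimeter_mm mean_radius_mm n_stations skipped_stations
#> 1  ascending 111.90124         102.41300       12.21482         11                0
#> 2 transverse 129.85040         101.40912       11.70249         13                0
#> 3 descending 113.46120          86.63608       11.57693         11                0
#> 4     pelvic  61.71339          82.03961       11.31716          6                0
#> 5      total 416.92624          94.88039       11.74987         41                0
```

Reading the output: the subject carries ~213 mL of colonic content, of
which ~82 mL is gas; per-segment volumes localize it (the pelvic colon here
is mostly gas). This phantom's content has two intensity modes, so the
mixed/solid split subdivides the bright (fecal) mode — on clinical images
intermediate intensities populate the mixed class. Morphology recovers the
generator's tube: mean radius ≈ 11.7 mm against a ground-truth mean of
12 mm, perimeter ≈ 95 mm ≈ 2π × radius, and a 417 mm path from cecum to
pelvic end. The containment value is the fraction of ground-truth feces
voxels captured by the automatic T1-FS segmentation.

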