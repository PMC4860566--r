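# ezdetect

Automatic three-dimensional detection and quantification of photoreceptor
**ellipsoid zone (EZ) disruption** in macular SD-OCT volumes.

The EZ (formerly the IS/OS junction) is the second hyper-reflective band of
the outer retina; its integrity is a marker of photoreceptor health, and its
focal loss after blunt ocular trauma (commotio retinae) correlates with
visual outcome. Quantifying the *3D extent* of EZ disruption by hand is slow
and subjective. `ezdetect` implements a fully automatic pipeline for
ophthalmic-imaging researchers who want a reproducible, voxel-level
disruption volume from a raw OCT scan:

1. **Denoising** — each B-scan is smoothed with a fast (grid-based) bilateral
   filter, which suppresses multiplicative speckle while keeping layer edges.
2. **Layer segmentation** — 11 intra-retinal surfaces are found by
   coarse-to-fine column-wise dynamic programming on a polarity-signed axial
   gradient cost, under hard smoothness and layer-separation constraints;
   surfaces are then smoothed with (robust) thin-plate splines.
3. **Flattening and VOI** — A-scans are shifted so the bottom of the retinal
   pigment epithelium (surface 11) is flat; the EZ slab between surfaces 7
   and 8 becomes the volume of interest (VOI).
4. **Per-voxel description** — every VOI voxel gets a 57-dimensional
   descriptor: normalized intensity; 5×5×5 block mean and standard
   deviation; mean absolute intensity difference over 13 3D directions at
   steps 1 and 2; and grey-level co-occurrence (GLCM) contrast, correlation,
   energy and homogeneity over the same 13 directions
   (`contrast = Σ p(x,y)(x−y)²`, `correlation = Σ (x−μₓ)(y−μᵧ)p(x,y)/σₓσᵧ`,
   `energy = Σ p²`, `homogeneity = Σ p/(1+|x−y|)`).
5. **Feature selection** — PCA on the standardized descriptors; the first 10
   components are kept.
6. **Classification** — disrupted vs non-disrupted voxels are far out of
   balance, so training data are balanced by random under-sampling of the
   majority class and classified with discrete AdaBoost over decision stumps
   (`α = ½·ln((1−ε)/ε)`), evaluated with leave-one-out cross-validation
   (PCA refitted inside each training fold).
7. **Post-processing** — retinal vessels cast dark shadows on the outer
   retina that mimic disruption; a KNN vessel detector on the EZ→RPE en face
   projection removes them, and morphological opening/closing with a
   radius-5 disk removes isolated detections.
8. **Quantification** — disruption volume = voxel count × physical voxel
   volume (mm³), with sensitivity (SEN), specificity (SPE), balanced
   accuracy (`BAR = (SEN+SPE)/2`), Pearson correlation against ground truth,
   Bland–Altman limits of agreement, and a trauma-vs-normal t-test.

Because clinical OCT scans cannot be redistributed, the package ships a
first-class **synthetic phantom generator**: ten stacked layers with
realistic reflectivities and geometry (foveal dip, tilt), a thin bright EZ
band, planted dark disruption blobs, vessel shadow paths, and multiplicative
gamma speckle — all with exact ground truth, so every stage of the pipeline
is testable end to end.

## Worked example

```r
library(ezdetect)

res <- run_pipeline(pipeline_config(
  simulate = list(n_trauma = 4L, n_normal = 2L),
  seed     = 20260920L))
print(res)
```

which prints (abridged):

```
<ez_pipeline_result> config 1baf4b2c
<ez_eval_report>
        id  group   tp  fp    tn  fn      sen       spe      bar
 trauma-01 trauma 2020 411 11590 301 87.03145  96.57529 91.80337
 trauma-02 trauma 2073 409 11598 109 95.00458  96.59365 95.79912
 trauma-03 trauma 1696 449 12110 226 88.24142  96.42487 92.33314
 trauma-04 trauma 2574 562 11468   6 99.76744  95.32835 97.54789
 normal-05 normal    0   0 14163   0       NA 100.00000       NA
 normal-06 normal    0   0 14133   0       NA 100.00000       NA
 detected_volume truth_volume  ez_volume
     0.009348714  0.009921713 0.05507704
     0.009544841  0.009175661 0.05456557
     0.008248866  0.008060430 0.05568850
     0.012059880  0.010621616 0.05618458
     0.000000000  0.000000000 0.05446559
     0.000000000  0.000000000 0.05435022
trauma: SEN 92.51% SPE 96.23% BAR 94.37%
normal: SPE 100.00%
detected vs truth volume: r = 0.8803 (p = 0.12)
trauma vs normal volume t-test: t = 8.114, p = 0.00125
```

Each row is one held-out eye of the leave-one-out protocol: `tp/fp/tn/fn`
are voxel counts inside that eye's EZ VOI, `sen/spe/bar` the per-eye rates in
percent (SEN and BAR are undefined on normal eyes, which have no disrupted
voxels), and the volumes are physical disruption volumes in mm³. The
correlation line compares detected and ground-truth disruption volumes
across trauma eyes; the t-test contrasts detected volumes between groups.

Lower-level functions are exported individually (`bilateral_filter_volume`,
`segment_surfaces`, `smooth_surfaces_tps`, `flatten`, `extract_voi`,
`extract_features`, `fit_pca`, `undersample`, `train_adaboost`, `loo_cv`,
`en_face_projection`, `detect_vessels`, `remove_vessel_detections`,
`morphological_cleanup`, `confusion`, `sen_spe_bar`, ...), so each stage can
be run, inspected and replaced in isolation. A thin command-line wrapper
lives at `inst/cli/ezdetect.R` with `simulate`, `run-all` and `evaluate`
subcommands. Volumes and masks are read and written as multipage TIFF or
NIfTI with a JSON voxel-size sidecar.

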