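# tumorhet

Tumors are metabolically heterogeneous: glucose uptake varies across a
lesion, and hypoxic subregions take up more of it than the tumor as a whole.
**tumorhet** quantifies that heterogeneity in 3D molecular-imaging volumes
(¹⁸F-FDG PET, fluorescence molecular tomography) the way an imaging lab
would: delineate the tumor from image gradients, shave off the
partial-volume-corrupted rim, and summarize the voxel intensities inside.
It is aimed at imaging scientists who want a scripted, reproducible version
of that workflow — plus digital tumor phantoms with known ground truth so
every stage can be validated without any patient or animal data.

## The statistics at the core

* **Coefficient of variation.** For the voxel intensities *x* inside an ROI,
  `CV = SD(x) / mean(x)` (sample SD, *n* − 1). A dimensionless heterogeneity
  measure: a uniform tumor has CV ≈ 0 regardless of uptake level.
* **ROI-E → ROI-C contraction.** The gradient-delineated tumor ROI (ROI-E)
  is contracted circumferentially by the scanner's spatial resolution
  (default 5 mm) into ROI-C, excluding boundary voxels whose values are
  depressed by partial-volume mixing with background. On an anisotropic
  grid the contraction is metric: a voxel survives iff its center is at
  least the contraction distance (in mm) from every voxel center outside
  the ROI. A spherical ROI of radius 5 cm contracts to one of radius
  4.5 cm.
* **Fold enrichment.** `mean(x | subregion) / mean(x | whole tumor)` — how
  much hotter a marker-positive subregion (e.g. a hypoxic hotspot) runs
  than the tumor overall.
* **IHC expression score.** Per stained region,
  `score = staining intensity × positive-area %`; per marker,
  heterogeneity is the mean/SD/CV of the 20 region scores.

## Worked example

Simulate a hypoxic tumor phantom, measure hotspot enrichment and
whole-tumor heterogeneity, then run the resolution-matched contraction
analysis:

```r
library(tumorhet)

ph <- generate_phantom(standard_suite_spec(seed = 1, multiplier = 2))
ph$channels
#> <channel_set> 2 channel(s) on a 48x48x48 grid: glucose, hypoxia

# hotspot detection on the hypoxia channel, enrichment on glucose
hs <- detect_hotspots(ph$channels$hypoxia, ph$truth$tumor_mask)
fe <- fold_enrichment(ph$channels$glucose,
                      transfer_roi(hs[[1]], ph$channels$glucose),
                      ph$truth$tumor_mask)
round(fe$fold, 3)
#> [1] 1.751

# whole-tumor heterogeneity
st <- region_stats(ph$channels$glucose, ph$truth$tumor_mask)
round(st$cv, 2)
#> [1] 0.33

# ROI-E -> ROI-C contraction on a gradient-delineated boundary
# (hotspot-free phantom: the single-tracer analysis arm)
ph0 <- generate_phantom(standard_suite_spec(seed = 1, hotspot = FALSE))
roi_e <- segment_gradient_edge(
  ph0$channels$glucose,
  segmentation_params(seed_point_mm = c(23.5, 23.5, 23.5),
                      max_radius_mm = 20, smoothing_fwhm_mm = 2))
roi_c <- contract_roi(roi_e, 5)
round(c(E = region_stats(ph0$channels$glucose, roi_e)$cv,
        C = region_stats(ph0$channels$glucose, roi_c)$cv), 2)
#>    E    C
#> 0.32 0.06
```

The detected hotspot runs 1.75-fold hotter than the whole tumor; the
threshold keeps its core, so the measured fold sits above the 10%-volume
no-blur mixture value (1.82) minus the partial-volume loss the 6 mm PSF
inflicts. The phantom's whole-tumor CV of 0.33 reflects the hotspot — the
same suite without one yields ≈ 0.23. In the contraction arm, ROI-E still
contains the blurred low-intensity rim (CV 0.32); contracting by the 5 mm
scanner resolution removes exactly those partial-volume voxels and the CV
of this uniform-interior phantom collapses to 0.06.

Batch analyses (`run_fmt_analysis()`, `run_pet_analysis()`) wrap these
stages and return tidy tables; `autoplot()` methods display histograms and
group comparisons. A thin CLI over the same functions ships in
`inst/cli/tumorhet.R` (subcommands `simulate`, `segment`, `hotspots`,
`contract`, `stats`, `enrich`, `ihc`, `run`).

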