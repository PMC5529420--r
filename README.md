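# microscreen

High-content image analysis for 3D microtissue co-cultures.

Patient-derived tumor cells grown with stromal fibroblasts in extracellular
matrix form complex microtissues: compact multicellular **organoids**
(tumor) surrounded by a meshwork of thin, branching **fibroblasts**.
Confocal maximum projections of such wells — 8-bit grayscale, dark
background, strongly varying brightness — are the raw material of phenotypic
drug screens.  `microscreen` implements the full analysis chain that turns
these images into per-well growth and morphology measurements and starred
treatment-effect tables, for screening labs that need a fast, reproducible,
desk-scale pipeline.

## What it does

1. **Stitching** — the four overlapping tiles of a well are collated by FFT
   phase correlation (`collate_well`), integer-pixel only, so 8-bit texture
   is never interpolated.
2. **Thresholding** — the standardized local entropy filter
   $e^*_i = -\sum_v p_v \log_2 p_v \,/\, \log_2 \#w_i$ (7×7 windows, border
   windows standardized by their reduced size) turns texture into the
   foreground cue; Otsu's or Tsai's global threshold on the entropy image is
   followed by bright-pixel rescue (> 0.2), topology-preserving thinning,
   removal of structures under 10 px diameter, and filling of holes under
   100 px (`threshold_mask`).  Masks are scored against (multi-expert,
   continuous) references with the continuous rates
   $\mathrm{FPR} = \frac1N\sum_i (f_i - r_i)_+$,
   $\mathrm{FNR} = \frac1N\sum_i (f_i - r_i)_-$ (`fpr_fnr`).
3. **Region classification** — rounded single cells (diameter < 30 px,
   roundness ≥ 0.5) are set aside; the remaining foreground is split into
   ~350-px Voronoi regions grown geodesically from a hexagonal seed lattice
   (`hex_seeds`, `propagate_regions`); each region yields 37
   brightness-invariant texture features (standardized entropy, SD, 9
   rotation-invariant uniform LBP frequencies, 26 co-occurrence statistics),
   reduced by PCA to 95% explained variance; logistic regression, random
   forests, Gaussian-kernel SVMs and a bundling ensemble are compared by
   stratified 10-fold cross-validation, with decisions at the
   equal-sensitivity/specificity threshold (`cross_validate`,
   `classify_well`).
4. **Morphometry** — each class mask is split into structures by watershed
   on its distance transform; per structure the area $A$, maximum (Feret)
   diameter $D$, and roundness $4\pi A/(\pi D)^2$ are recorded
   (`watershed_split`, `structure_morphometrics`).
5. **Statistics** — every endpoint × treatment × concentration is tested
   against the pooled vehicle control with the two-sample Van der Waerden
   normal-scores test (exact permutation below 15 per group), starred at
   0.05/0.01/0.001 (`van_der_waerden`, `treatment_tests`).

A synthetic well generator (`generate_well`, `generate_plate`) renders the
documented image characteristics with per-pixel ground truth, so the whole
chain is testable without microscope data; `run_pipeline` chains everything
over a plate with plain-file handoffs and a fully seeded, byte-reproducible
run.

## Worked example

```r
library(microscreen)

params <- synthetic_well_params(seed = 1)   # 512 x 672 well, ~9% covered
w      <- generate_well(params)             # $image and $truth

mask  <- threshold_mask(w$image, threshold_config(method = "otsu"))
attr(mask, "threshold")
#> [1] 0.5647059
round(fpr_fnr(mask, matrix(as.numeric(w$truth > 0), nrow(w$truth))), 4)
#>    FPR    FNR
#> 0.0027 0.0249

sp      <- extract_rounded_single_cells(mask)
regions <- propagate_regions(sp$remaining, hex_seeds(sp$remaining, 350))
length(attr(regions, "sizes")); median(attr(regions, "sizes"))
#> [1] 52
#> [1] 342.5

head(well_structures(w$truth, "demo")[, c("structure_id", "area_px",
                                          "max_diameter_px", "roundness")], 3)
#>   structure_id area_px max_diameter_px roundness
#> 1            1    4642        84.24062 0.8328604
#> 2            2    1988        52.41984 0.9211601
#> 3            3    2099        55.74486 0.8600285

set.seed(1)
v <- van_der_waerden(rnorm(20, 0), rnorm(20, 1))
c(statistic = round(v$statistic, 2), p = signif(v$p, 3))
#> statistic         p
#>   7.75000   0.00537
```

The entropy+Otsu mask misses only 2.5% of the true foreground and marks
0.3% of the image as spurious foreground; the partition lands on the
350-px region scale; the organoid structures read out as large and round;
and a unit shift between two groups of 20 is detected at p ≈ 0.005.

For a full plate, build a design and run the pipeline:

```r
effects <- data.frame(treatment = "docetaxel", area_effect = 0.5,
                      roundness_shift = 0.4, single_cell_rate = 2)
design  <- screen_design(patients = "P1", effects = effects,
                         concentrations = 10, replicates = 3,
                         control_wells = 3)
res <- run_pipeline(pipeline_config(out_dir = "run", design = design,
                                    n_training_wells = 3, seed = 42))
res$tests   # starred endpoint x treatment table, also written as tests.csv
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/microscreen-cli.R` (subcommands `simulate`, `stitch`,
`threshold`, `evaluate`, `regions`, `segment`, `stats`, `pipeline`).

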