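# tilscore

Efficient tumor-infiltrating lymphocyte (TIL) density scoring for
hematoxylin-and-eosin (H&E) whole-slide images, for computational
pathology researchers who need a tested, inspectable pipeline from raw
slide to prognostic score.

TILs are a prognostic biomarker in non-small cell lung cancer: denser
lymphocyte infiltration in tumor and tumor-associated stroma predicts
longer disease-specific survival. Scoring them by hand across gigapixel
slides is slow and subjective; scoring them exhaustively by machine
wastes most of its compute on glass and non-informative tissue.
`tilscore` implements a staged pipeline that concentrates computation
where the prognostic signal lives:

1. **Patch extraction** — tissue masking by grayscale thresholding
   (BT.601 luma < 170) on a downsampled overview, a non-overlapping
   768 px patch grid, and hematoxylin-component filtering after
   Ruifrok–Johnston stain separation (mean H ≥ 0.017 keeps a patch).
2. **Randomized sampling** — an optional uniform subsample
   (`m = max(1, round(ratio × N))`) of the candidate set; unbiased for
   the slide score, it trades variance against compute.
3. **Patch classification** — a pluggable four-class contract (tumor,
   stroma, necrosis, normal); only tumor and stroma are retained.
4. **Cell quantification and scoring** — a pluggable nucleus detector
   counts lymphocytes per patch; counts are normalized to densities

   d_i = c_i / (patch_size × mpp)² × 10⁶  [cells/mm²],

   averaged into a slide score (mean over patches) and a patient score
   (mean of slide means over k slides).
5. **Evaluation and visualization** — Harrell's concordance index,
   quartile grouping, Kaplan–Meier curves and the log-rank test for
   survival analyses, plus per-patch density heatmaps clipped at
   10,000 cells/mm².

A synthetic-slide generator plants nuclei of known class and count in
H&E-like tissue (with matched censored survival outcomes at cohort
level), so every stage is testable against exact ground truth — see the
methods vignette (`vignettes/tilscore-methods.Rmd`) for the model,
conventions, and limitations.

## Worked example

```r
library(tilscore)

# a 1536x1536 px slide at 0.5 um/px: tumor left half, stroma right
# half, both planted with 1500 lymphocytes/mm^2
sp <- slide_spec(1536, 1536, mpp = 0.5,
  regions = list(region_rect(0, 0, 768, 1536, "tumor"),
                 region_rect(768, 0, 768, 1536, "stroma")),
  nuclei_density = list(tumor  = c(lymphocyte = 1500, other = 500),
                        stroma = c(lymphocyte = 1500, other = 500)),
  seed = 42)
sl <- generate_slide(sp)

run <- run_pipeline(sl$path, oracle_classifier(sl$truth),
                    oracle_quantifier(sl$truth))
run
#> <til_slide_result> file...: TIL score 1498.8 cells/mm^2 (n_patches = 4)
#>   stages:  grid=4 -> h_filter=4 -> classified=4 -> prognostic=4 -> quantified=4
```

The slide decomposes into four 768 px patches, all pass the tissue and
hematoxylin filters, all are labeled tumor or stroma, and the recovered
score of 1498.8 cells/mm² sits within 0.1% of the planted 1500 — the
residual comes only from rounding the planted count to whole nuclei.

Swap in the image-based models (`heuristic_classifier()`,
`reference_quantifier()`) to run without ground truth, or adapt a
trained model to the `til_classifier` / `til_quantifier` contracts.

A command-line front end covers the common operations:

```sh
Rscript inst/cli/tilscore.R simulate --out slide.tif --lymph 1200 --seed 3
Rscript inst/cli/tilscore.R extract  --slide slide.tif --out patches.tsv
Rscript inst/cli/tilscore.R run      --slide slide.tif --outdir results/
Rscript inst/cli/tilscore.R evaluate --cohort cohort.csv --out eval.json
```

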