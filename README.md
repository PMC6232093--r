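# slidequant

Region-based immune-cell quantification for whole-slide immunofluorescence,
in R.

`slidequant` re-implements, as an open and fully testable pipeline, the
semi-automated workflow used to quantify immunofluorescence-stained immune
cells on whole colon sections: detect the tissue, partition it into small
*primitive objects*, classify those objects into immune regions of interest
(iROIs — mucosa, lymphoid follicle, tumor), detect nuclei from the DAPI
channel, grow a cell model around each nucleus, phenotype cells by
co-staining thresholds, and report marker-positive cell densities per
region. A synthetic-slide generator with exact ground truth makes every
stage verifiable without any external image data.

## The science, briefly

Manual counting of immune cells on whole slides is slow and subjective;
fully manual region outlining does not scale to cohorts. The workflow
implemented here follows the object-based image analysis (OBIA) paradigm:

1. **Tissue detection** (`detect_tissue`) — a brightness/homogeneity
   threshold on the nuclear channel, with small-component removal
   (`min_area`, default 10 µm²), yields a binary tissue mask.
2. **Primitive segmentation** (`segment_primitives`) — edge-respecting
   superpixels (seeded propagation at a fixed scale parameter, default 4)
   partition the mask exactly: every tissue pixel belongs to exactly one
   primitive, no primitive leaves the mask.
3. **Region classification** (`train_classifier`, `classify_objects`) — a
   random forest on per-object intensity, texture, shape and contextual
   features, trained from exemplar annotations, assigns each primitive a
   region class. Ordered conditional reclassification rules
   (`default_ruleset`, e.g. "a follicle-labeled object ≥ 10⁴ µm² becomes
   tumor") and neighbor-majority regularization clean up the labeling;
   programmatic manual correction (`manual_correct`) covers the
   "semi-automated" step. Touching same-class primitives merge into ROI
   objects; optional border strips ("bis" classes) model region margins.
4. **Cellular analysis** (`detect_nuclei`, `simulate_cells`,
   `classify_cells`) — nuclei come from a smoothed Otsu threshold plus
   distance-map watershed with a mean-nucleus-area prior (35 µm²); a cell
   is simulated around each nucleus either by growth into membrane
   staining or isotropically to a target area (38 µm²). Phenotypes are
   inclusive intensity thresholds on per-cell channel means — single CD45
   (DAPI ≥ 1000, FITC ≥ 1300) or double CD3/CD4 schemes. Artifacts are
   excluded at region borders and below a minimum area.
5. **Quantification** (`summarize_density`, `compare_rois`,
   `correlate_manual`) — density = positive cells × 10⁶ / region area in
   µm² (cells/mm²), compared across regions by one-way ANOVA and validated
   against manual scores by Pearson correlation.

The synthetic generator (`generate_slide`) renders 16-bit multichannel
slides at 0.161028 µm/px under pinned study conditions (positive densities:
follicle 2.10 × 10⁴, mucosa 2.97 × 10³, tumor 3.22 × 10³ cells/mm²), with
hard-core nucleus placement, membrane rings, autofluorescent aggregates,
and an exact cell-level ground truth. `generate_negative_control` renders
the matching no-primary-antibody control.

## Worked example

A full run on a 1024-px synthetic section, training the region classifier
from exemplars sampled off the ground-truth mask:

```r
library(slidequant)

cfg <- synth_config(size = 1024L, seed = 11L)
g   <- generate_slide(cfg)

res <- run_pipeline(g$slide, g$truth$roi, pipeline_config(seed = 11L),
                    slide_id = "demo")
#> region classifier trained on 332 exemplars, 5 classes; training accuracy 100.0%

res$report[, c("slide", "roi_class", "area_mm2", "total_cells",
               "positive_positive", "density_positive")]
#>   slide         roi_class area_mm2 total_cells positive_positive density_positive
#> 1  demo lymphoid_follicle 0.002029          40                37            18234
#> 2  demo            mucosa 0.014191         114                49             3453
#> 3  demo      other_tissue 0.004551           0                 0                0
#> 4  demo             tumor 0.001825          14                 8             4383
```

The follicle stands out at ~18 × 10³ positive cells/mm² against ~3.5 × 10³
in mucosa and tumor, reproducing the expected ordering.

To validate cell detection itself (independently of region-classification
borders), run the cellular stages against the ground-truth regions of a
full-size default slide and match detections to the truth:

```r
g   <- generate_slide(synth_config())        # default study conditions, 2048 px
cfg <- pipeline_config()
iroi <- c("lymphoid_follicle", "mucosa", "tumor")

nuclei <- detect_nuclei(g$slide, g$truth$roi, iroi_classes = iroi,
                        params = cfg$nucleus)
cells  <- simulate_cells(nuclei, g$slide, params = cfg$cell, roi = g$truth$roi)
cells  <- classify_cells(cells, cfg$thresholds, cfg$scheme)
kept   <- exclude_artifacts(cells, g$truth$roi,
                            min_cell_area = cfg$min_cell_area)$cells

match_cells_to_truth(kept, g$truth)
#>              region gt_positive det_positive precision recall    f1 count_error
#> 1 lymphoid_follicle         184          175     0.994  0.946 0.969     0.04891
#> 2            mucosa         183          184     0.995  1.000 0.997     0.00546
#> 3             tumor          21           21     1.000  1.000 1.000     0.00000
```

A command-line interface for batch use ships at
`inst/scripts/slidequant.R` (subcommands `synthesize`, `detect-tissue`,
`segment`, `classify-roi`, `analyze-cells`, `quantify`, `run`, `batch`).

## Reproduction

Unit, property and acceptance tests (testthat, 3rd edition) cover every
module; the acceptance suite pins the headline claims — exactly zero
positives on negative controls, per-region F1 ≥ 0.95 with ≤ 5% count
error, follicle > mucosa/tumor density ordering across 18 sections with
ANOVA p < 10⁻⁴, formula exactness against brute-force oracles, threshold
monotonicity, exact mask partitioning, and rule-engine correctness on
hand-built toys:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "slidequant",
                               load_package = "installed")'
```

The standalone acceptance run recomputes the headline quantities for any
seed and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 42 --out acceptance.json
```

The whole synthetic study is seeded; every number above is reproduced
exactly by the commands shown.
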