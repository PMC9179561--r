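# microgliaq

Quantification of microglial activation in anti-IBA1 immunohistochemical
stains, with a synthetic ground-truth benchmark.

## The problem

Microglia — the resident immune cells of the CNS — shift from a ramified
"resting" morphology (small soma, long thin processes) to an amoeboid
"activated" one (hypertrophic soma, retracted processes) under pathology
such as cuprizone-induced demyelination. Histology labs quantify this
activation from anti-IBA1 (ionized calcium-binding adaptor protein-1)
stains with three standard read-outs:

1. **Cell density** — IBA1⁺ cells counted inside a region of interest
   (ROI), reported as cells/mm².
2. **Densitometric staining intensity** — the image is converted to
   grayscale, thresholded into a two-class binary image, and the positive
   fraction of the ROI is reported as % area.
3. **Cellular morphology via the ramification index (RI)** — for a sampled
   cell with silhouette area *A_c* and convex-hull ("projection") area
   *A_p*,

   RI = *A_c* / *A_p* ∈ (0, 1],

   where a ramified resting cell has a large hull relative to its
   silhouette (low RI) and an activated amoeboid cell approaches RI = 1.
   Cells are sampled by superimposing a rectangular grid with uniform X/Y
   line spacing and measuring every cell that crosses a grid line.

`microgliaq` implements all three read-outs, the accompanying group
statistics (Grubbs' single-outlier screening of the densitometric values,
Kruskal–Wallis omnibus test, Dunn's post hoc z-comparisons against control
with Bonferroni-type adjustment, `*`/`**`/`***`/`n.s.` symbols), and — since
real stained tissue with known ground truth does not exist — a synthetic
DAB-like scene generator that renders cohorts of dark-on-bright microglia
fields with exactly known density, positive-pixel fraction and per-cell RI,
so every stage of the pipeline can be validated by parameter recovery.

Package conventions: pixel (0,0) at the top-left, x rightward, y downward,
pixel centres at integer + 0.5; masks are pixel sets, *A_c* counts pixels ×
pixel area, and *A_p* is the convex hull of the pixel-square corner points,
which guarantees *A_p* ≥ *A_c* and hence RI ≤ 1.

## Worked example

Simulate a control vs. 5-week-cuprizone white-matter cohort (5 animals per
group) and push it through the full pipeline:

```r
library(microgliaq)

spec <- cohort_spec(
  list(group_spec("Ctrl", 5, target_mean_ri = 0.66, sd_ri = 0.04,
                  target_density = 87.79, sd_density = 20.52),
       group_spec("5w",   5, target_mean_ri = 0.88, sd_ri = 0.04,
                  target_density = 420, sd_density = 50)),
  seed = 42)
res <- run_pipeline(generate_cohort(spec), control = "Ctrl", seed = 43)

res$recovery
#>         metric      seeded  recovered relative_error
#> 1      density 257.2222222 256.944444    0.001079914
#> 2 percent_area   6.8205556   6.820556    0.000000000
#> 3      mean_ri   0.7776359   0.775987    0.002120313

res$stats$mean_ri
#> <test_result> metric mean_ri: H = 6.8182 (df 1), p = 0.009023
#>   comparison        z       p_raw  p_adjusted symbol
#> 1 5w vs Ctrl 2.611165 0.009023439 0.009023439     **
```

The recovery table compares the generator's ground truth (cohort means)
with what the pipeline measured back from the rendered images: density and
percent area are recovered essentially exactly, the mean RI to ~0.002. The
statistics block shows the activated group separating from control
(`**`, p ≤ 0.01). Per-animal control values land around the seeded
conditions (e.g. percent area 1.4–2.4 %, density 61–103 cells/mm², mean RI
0.58–0.71 from 10–19 grid-sampled cells per animal).

## The analysis workflow

Numbered drivers under `analysis/` reproduce the full study design over
three brain regions (medial corpus callosum, medial retrosplenial cortex,
hippocampus; Ctrl/1w/3w/5w, n = 5):

```sh
Rscript analysis/01_simulate_cohorts.R    # scenes + ground truth -> scratch/cohorts/
Rscript analysis/02_quantify_cohorts.R    # three read-outs + stats -> results/<region>/
Rscript analysis/03_significance_pattern.R # Monte-Carlo significance pattern -> results/
```

Step 3 reproduces the qualitative progression reported for white-matter
RI — non-significant at 1 week, significant at 3 and 5 weeks vs control
(observed rates ≈ 0.06 / 0.96 / 0.98 over 100 replicate cohorts).

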