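# chromsep

Objective, reproducible assessment of how well an endoscopic imaging
modality separates cancerous from non-cancerous mucosa **by color alone**.

Judging whether a chromoendoscopy dye (indigo carmine, or acetic acid plus
indigo carmine) improves the visibility of an early gastric cancer is
usually left to the endoscopist's eye. chromsep replaces that judgment with
two per-image numbers computed from the pixels themselves, given a still
image and a binary mask of the cancerous area:

* **Mahalanobis color-separation distance.** With 2000 luminance-matched
  pixels sampled per region, class means μ₁, μ₂ and covariances Σ₁, Σ₂ are
  estimated in RGB space and

  D = √( (μ₁ − μ₂)ᵀ Σ̄⁻¹ (μ₁ − μ₂) ),  Σ̄ = (Σ₁ + Σ₂)/2.

  Luminance matching (equal per-bin luminance histograms between the two
  samples) removes brightness as a confounder, so D reflects chromatic
  difference only.

* **SVM diagnosability (F1).** An RBF-kernel support vector machine is
  trained on 100 pixels per class and classifies the 3800 held-out pixels
  (1900 per class); performance is the F1 measure, the harmonic mean of
  sensitivity tp/(tp+fn) and positive predictive value tp/(tp+fp).

Per-lesion results are then compared across modalities (WL / Indigo / AIM)
with paired Wilcoxon signed-rank tests, each lesion being imaged under all
three techniques. Because clinical image sets are rarely shareable, the
package includes a fully seeded synthetic study generator with known
ground-truth color models, so every stage can be validated against
closed-form oracles. Intended users: groups evaluating imaging modalities
or dye protocols who want an objective, replayable pixel-level comparison.

## Worked example

Simulate a 6-lesion study, run the full pipeline, and aggregate:

```r
library(chromsep)

study   <- generate_study(study_spec(n_lesions = 6, seed = 42))
records <- run_study(study, pipeline_config(), seed = 42)
dplyr::select(records, lesion_id, modality, mahalanobis_distance, sensitivity, ppv, f1)
#> # A tibble: 18 × 6
#>   lesion_id modality mahalanobis_distance sensitivity   ppv    f1
#>   <chr>     <chr>                   <dbl>       <dbl> <dbl> <dbl>
#> 1 L01       WL                       1.42       0.765 0.758 0.761
#> 2 L01       Indigo                   1.29       0.751 0.726 0.738
#> 3 L01       AIM                      2.45       0.916 0.870 0.892
#> 4 L02       WL                       1.55       0.773 0.789 0.781
#> 5 L02       Indigo                   1.35       0.749 0.755 0.752
#> 6 L02       AIM                      2.65       0.897 0.917 0.907
#> # ℹ 12 more rows

report <- aggregate_study(records)
report
#> <study_report> 6 lesions x 3 modalities
#>
#> Per-modality means (SD):
#>   WL     distance 1.557 (0.170)   F1 0.780 (0.025)
#>   Indigo distance 1.362 (0.149)   F1 0.747 (0.027)
#>   AIM    distance 2.624 (0.302)   F1 0.897 (0.027)
#>
#> Paired Wilcoxon signed-rank (two-sided, uncorrected):
#>   mahalanobis_distance   WL-Indigo    p = 0.031
#>   mahalanobis_distance   WL-AIM       p = 0.031
#>   mahalanobis_distance   Indigo-AIM   p = 0.031
#>   f1                     WL-Indigo    p = 0.031
#>   f1                     WL-AIM       p = 0.031
#>   f1                     Indigo-AIM   p = 0.031
```

Each record row is one image: its color-separation distance and its SVM
test scores. The report shows that in this simulated study AIM separates
cancer from background most strongly on both measures (ground truth: the
generator's separation scales are AIM 2.5 > WL 1.5 > Indigo 1.3), and the
paired tests flag every contrast at the resolution 6 lesions allow.
`tidy(report)` returns the comparison table, `glance(report)` the one-row
summary, `autoplot(report, metric = "f1")` the bar chart, and
`write_report(report, dir)` the JSON + CSV outputs.

Real image files are analyzed the same way: list them in a manifest CSV
(`lesion_id, modality, image, mask`) and call `run_study_files()`, or use
the command-line front end in `inst/cli/chromsep.R`
(`simulate` / `run` / `report` subcommands).

## Learning more

The methods vignette (`vignettes/color-separability.Rmd`) documents the
model and its assumptions, the luminance-matching algorithm, the SVM
conventions, what the synthetic generator does and does not emulate, and
the package's numerical edge-case policies.
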