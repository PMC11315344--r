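# frostgrade

Grading wheat freeze-injury severity (0 = none, 1 = mild, 2 = severe) from
the color information in digital canopy images.

## The problem

Overwinter freeze injury is the main weather hazard for winter wheat in
northern growing regions; severe events cut yields by 30–50%. The standard
assessment — trained agrometeorological observers scoring leaf color and
frozen leaf area in the field — is accurate but slow and hard to scale,
while meteorological indicators measured at distant stations miss the field
microclimate. A fixed RGB camera over the canopy offers a cheap alternative:
freeze injury turns wheat leaves from concentrated bright green through
yellow-green to neutral yellow, and that change is visible in the color
histograms of the frames as a shift toward lighter values, a flattening,
and a change of skew, all increasing with severity.

frostgrade turns that observation into a classification pipeline:

1. **CGSD features.** Each frame is split into four equal quadrant samples
   (upper-left = modeling, rest = validation). After filtering
   pure-black/pure-white pixels, the 0–255 histograms of the R, G, B and
   gray-level (Y) channels are summarized by mean, median, mode, skewness
   and excess kurtosis — the 20 color-gradation skewness-distribution
   (CGSD) parameters.
2. **Key-parameter selection.** The 20 parameters are screened (KMO > 0.7,
   Bartlett p < 0.05), factored (PCA extraction of the correlation matrix,
   varimax rotation, regression-method score coefficients `SC = R⁻¹Λ`), and
   ranked by the combined principal-component score
   `FSC_i = Σ_j SC_ij · VDR_j / CDR_m`, where `VDR_j` is factor *j*'s
   variance contribution and `CDR_m` the cumulative contribution of the
   retained set. The `k = 6` parameters with the largest `|FSC|` become the
   model inputs.
3. **Classification.** A Gaussian naive Bayes model trained on the
   observers' manual grades (the prior data) — configurations F5 (all 20
   parameters) and F5_Optimized (the 6 key parameters) — benchmarked
   against hierarchical (Ward) and K-means clustering baselines on either
   CGSD parameters (F2/F4) or 31 derived meteorological factors (F1/F3).
4. **Evaluation.** 3×3 confusion matrices and exact-match accuracy, overall
   and per grade (`100 · trace / n`, `100 · diagonal / row sum`).

Since no field imagery is distributed, the package includes a synthetic
canopy-image generator (three-population color mixture with grade-dependent
weights) and a synthetic weather-series generator, so the whole pipeline is
reproducible and testable end to end. See the vignette
(`vignettes/freeze-injury-grading.Rmd`) for the model details and design
decisions.

## Worked example

```r
library(frostgrade)

# one synthetic severely injured canopy frame and its color features
img <- generate_canopy_image(grade = 2, width = 128, height = 128, seed = 11)
extract_cgsd(img, sample_id = "demo_q1", grade = 2)[
  , c("sample_id", "grade", "R_Mean", "R_Kurtosis", "G_Mean", "G_Skewness")]
#> # A tibble: 1 × 6
#>   sample_id grade R_Mean R_Kurtosis G_Mean G_Skewness
#>   <chr>     <int>  <dbl>      <dbl>  <dbl>      <dbl>
#> 1 demo_q1       2   136.      -1.38   153.     -0.120

# end-to-end optimized Bayesian run on a synthetic campaign:
# 47 modeling / 141 validation / 124 applied-testing quadrant samples
run <- run_model(run_config("F5_Optimized",
                            dataset = dataset_config(width = 64, height = 64),
                            seed = 1))
#> [F5_Optimized] screening: KMO 0.851, Bartlett p 0
#> [F5_Optimized] selected key parameters: Y_Kurtosis, R_Kurtosis, G_Kurtosis,
#>   R_Skewness, Y_Skewness, B_Kurtosis
#> [F5_Optimized] trained on 47 modeling samples, 6 features
#> [F5_Optimized] modeling accuracy: 100.00% (n = 47)
#> [F5_Optimized] validation accuracy: 100.00% (n = 141)
#> [F5_Optimized] testing accuracy: 100.00% (n = 124)
```

The high accuracies reflect the generator's deliberately strong
between-grade color separation; the interesting outputs are the screening
values (a KMO of 0.85 confirms the CGSD parameters are factorable), the
selected key-parameter set (kurtosis/skewness parameters dominate here),
and the per-split confusion matrices in `run$confusion`. A lower grade
separation — see `severity_color_model()` — degrades accuracy smoothly.

A command-line interface with `simulate`, `extract`, `screen`, `select`,
`train`, `classify`, `evaluate` and `run` subcommands wraps the same
functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "frostgrade.R", package = "frostgrade"))') \
  run --model F5_Optimized --seed 1 --out results/run1
```

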