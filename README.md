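# scleraSHG

Quantitative analysis of scleral tissue crosslinking from
second-harmonic-generation (SHG) micrographs, for researchers evaluating
therapeutic crosslinking (e.g. sub-Tenon's injection of sodium
hydroxymethylglycinate) in paired-eye animal studies.

SHG microscopy images fibrillar collagen directly. Crosslinking changes two
things that can be read off a micrograph of a treated eye versus the paired
(contralateral, mock-injected) control eye:

* **Brightness** — the mean of the image's intensity histogram ("mean pixel
  density") rises with crosslinking. Paired differences are tested with
  paired t-tests; dose comparisons use a linear mixed model with a random
  intercept per animal,
  `mean ~ condition + (1 | rabbit)`.
* **Fiber straightening** — collagen fiber bundles are wavy. For a traced
  bundle, waviness is the arc-to-chord ratio
  `W = L_curve / L_linear >= 1`, and the treated condition is summarized
  relative to its control as

  ```
  Waviness-% = 100 * (W_treated - 1) / (W_control - 1)
  ```

  with `W` averaged hierarchically: 10 fibers per image field, 10 fields
  per condition. Values below 100% mean crosslinking straightened the
  fibers.

A third analysis localizes the effect: the globe is divided into 16
anatomical sectors (sector 2 = injection site) and the shift in collagen
thermal denaturation temperature, ΔTm (treated minus paired control), is
tested per sector with paired t-tests, yielding a "zone of effect" map.

Because the original tissue images are not deposited, the package includes
a first-class synthetic-data generator (`generate_condition_set()`,
`generate_tm_table()`) that emulates the statistical structure of the
study — paired eyes with a shared per-animal brightness intercept,
condition-dependent brightness and centerline waviness with exact known
ground truth, zero-mean noise, localized Tm shifts — so the whole pipeline
(TIFF I/O, seeded automated fiber tracing, waviness statistics, histogram
statistics, mixed model, sector map) is testable end-to-end.

## Worked example

Generate a synthetic per-sector Tm table for the 40 mM condition (sectors
1–3 shifted by 3.4 °C, three animals, 0.5 °C measurement noise), run the
sector analysis, and map the zone of effect:

```r
library(scleraSHG)

tab <- generate_tm_table(tm_preset("cfg-tm-40-map", seed = 7))
res <- sector_tests(tab)
head(res[res$sector %in% 1:4, ], 4)
#>   sector n delta_mean delta_sd p_value degenerate significant
#> 1      1 3      3.579    0.843 0.01800      FALSE        TRUE
#> 2      2 3      3.028    0.465 0.00778      FALSE        TRUE
#> 3      3 3      3.892    0.525 0.00602      FALSE        TRUE
#> 4      4 3     -0.292    0.716 0.55372      FALSE       FALSE

zone_of_effect(res)
#> zone of effect (significant sectors): 1, 2, 3, 11
#> [ 1:  3.6±0.8*] [ 2:  3.0±0.5*] [ 3:  3.9±0.5*]
#> [ 4: -0.3±0.7 ] [ 5: -0.3±1.5 ] [ 6:  0.1±0.5 ] [ 7:  0.4±0.7 ] [ 8:  0.6±0.3 ] [ 9: -1.2±0.9 ]
#> [10:  0.4±0.3 ] [11: -0.6±0.2*] [12:  0.0±0.3 ] [13:  0.3±0.6 ]
#> [14: -0.2±0.5 ] [15: -0.5±0.6 ] [16: -0.1±0.7 ]
```

The injected region (sectors 1–3) carries ΔTm ≈ 3–3.9 °C and is flagged
significant; the remaining sectors scatter around zero (sector 11 here is a
type-I error of the uncorrected per-sector testing — at α = 0.05 across 16
sectors, about one false flag per table is expected; `sector_tests(...,
p_adjust = "bonferroni")` removes it).

Averaging over 20 replicate seeds recovers planted shifts accurately, e.g.
for the 400 mM injection-site preset (13 °C at sector 2):

```r
run_tm_roundtrip("cfg-tm-400-insitu", n_seeds = 20, seed = 1)
#> delta-Tm round trip [cfg-tm-400-insitu]: 20 tables
#>   majority-significant sectors: 2
#>   sector 1: delta-Tm 0.14 (truth 0.00)
#>   sector 2: delta-Tm 12.98 (truth 13.00)
#>   sector 16: delta-Tm 0.18 (truth 0.00)
```

The image-based round trips work the same way: `run_intensity_roundtrip()`
renders paired image sets, computes histogram means, and recovers the
planted brightness difference; `run_waviness_roundtrip()` renders wavy
fiber bundles, traces them with the seeded ridge follower
(`trace_fiber()`), applies the hierarchical averaging, and recovers the
planted Waviness-%. See the vignette
(`vignettes/scleraSHG-methods.Rmd`) for the model, parameter and design
details, and `inst/scripts/shg-pipeline.R` for the command-line front end
(`simulate | intensity | waviness | sectors | reproduce`).

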