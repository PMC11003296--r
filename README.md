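# phosphenes

Quantitative analysis of phosphene drawings from epiretinal prostheses.

Users of epiretinal implants (e.g. the Argus II, a 6 × 10 grid of 200 µm
electrodes at 575 µm pitch) perceive electrically elicited flashes of light
— *phosphenes* — and can trace their shapes on a touchscreen. Because
epiretinal electrodes also stimulate passing retinal ganglion-cell axons,
percept shape depends on the local nerve-fiber-bundle geometry in addition
to stimulus amplitude and frequency. This package provides the full
analysis pipeline for such drawings, for researchers studying prosthetic
vision psychophysics:

* **Shape description.** Binary drawing masks are decomposed into
  8-connected phosphene regions; each region gets moment-based descriptors:
  area `A = M00`, centroid `(M10/M00, M01/M00)`, major/minor axis lengths
  `4√λ₁, 4√λ₂` from the eigenvalues of the central-moment covariance matrix
  `[[µ′20, µ′11], [µ′11, µ′02]]`, and a border-polyline perimeter
  (orthogonal steps 1, diagonal steps √2, with corner correction).
* **Axonal distance decomposition.** A simulated nerve-fiber-bundle map
  (Jansonius-type trajectories `φ(r) = φ₀ + b(r − r₀)^c` traced from the
  optic disc and trimmed at the raphe) splits the retinal separation of an
  electrode pair into the *between-axon* distance (nasal electrode center →
  the temporal electrode's closest bundle) and the *along-axon* distance
  (arc length along that bundle between the two foot points).
* **Normalization.** Descriptors are expressed as multiples of each
  participant's standard-pulse response (2 × threshold, 20 Hz), averaged
  over trials of the same electrode/stimulus combination, screened at
  2.5 SD, and power-transformed (`area^(1/3)`, square roots elsewhere).
* **Inference.** Standardized multiple regression with partial
  correlations, random-intercept mixed models across participants, Welch's
  t, VIF, Bonferroni correction; a no-intercept *summation regression*
  (paired descriptor ~ sum of the two single-electrode descriptors) whose
  slope is the summation gain; and AIC/BIC comparison of
  between-axon vs along-axon models of the phosphene count.
* **Synthetic cohorts.** `generate_cohort()` renders drawing datasets with
  planted ground truth (descriptor growth laws, a summation gain g, a
  logistic phosphene-split rule in between-axon distance) so every stage of
  the pipeline is verifiable end to end.

## Worked example

Generate a synthetic three-participant cohort (amplitude and frequency
sweeps on eight electrodes, twelve electrode pairs, three trials per
condition), then run the complete analysis:

```r
library(phosphenes)

map <- build_axon_map(n_bundles = 300)
coh <- generate_cohort(cohort_config(n_trials = 3), seed = 42, map = map)
ana <- run_cohort_analysis(coh$manifest, coh$masks, coh$positions, coh$map)

ana$summation$fits
#>   descriptor  beta     r        p  n
#> 1       area 0.409 0.981 4.03e-59 48
#> 2  perimeter 0.608 0.960 3.11e-56 48
#> 3      major 0.626 0.977 6.55e-62 48
#> 4      minor 0.534 0.652 4.39e-33 48
```

The paired-electrode descriptors are proportional to the *sum* of the
constituent single-electrode descriptors with slope ≈ 0.63 for the
linear-extent descriptors: paired percepts are larger than the average of
their parts but smaller than their sum. The generator planted a linear
summation gain of 0.65 (area, a squared quantity, sums with ≈ 0.65² ≈ 0.42);
the pipeline recovers it.

```r
ana$model_comparison$table[, c("model", "aic_along", "aic_between",
                               "delta_aic", "preferred", "verdict_aic")]
#>   model aic_along aic_between delta_aic preferred     verdict_aic
#> 1    S1     19.97       9.823     10.15         B strong evidence
#> 2    S2     35.07      -5.068     40.14         B strong evidence
#> 3    S3     27.04       5.362     21.67         B strong evidence
#> 4   all     70.94      10.569     60.37         B strong evidence
```

Model B (phosphene count ~ between-axon distance + amplitude + EFD)
decisively beats Model A (along-axon distance) — the planted mechanism was
between-axon, and the comparison detects it in every participant and in the
pooled mixed model.

```r
st <- ana$single_tables
st[st$model == "all" & st$response == "area",
   c("term", "beta", "r", "p_adj", "stars")]
#>             term   beta     r    p_adj stars
#> 1 amplitude_x_th 0.0786 0.851 1.99e-38   ***
#> 2   frequency_hz 0.0555 0.753 2.69e-25   ***
#> 3         efd_um 0.1465 0.950 8.21e-69   ***
```

Single-electrode phosphene area grows with stimulus amplitude and with
retinal eccentricity (electrode-fovea distance, EFD), as planted.

Cohorts can also be written to disk (`generate_cohort(..., out_dir = d)`) as
a manifest CSV, PNG masks, per-participant implant YAML and a ground-truth
JSON, and ingested back through `read_manifest()` /
`extract_drawing_descriptors()`.

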