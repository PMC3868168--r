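# paslquant

Quantitative cerebral perfusion from pulsed arterial spin labeling (ASL),
with the downstream composites and regression models used to relate
cerebral blood flow (CBF) to cognition and brain structure in older
adults with cardiovascular disease.

ASL measures perfusion noninvasively by magnetically inverting arterial
blood water (the "tag") and subtracting tagged from control images: the
mean difference signal ΔM is proportional to CBF. `paslquant` implements
the full analysis chain for a PICORE Q2TIPS acquisition:

1. **Kinetics** — average the control/tag pairs into a ΔM map, take the
   unprepared first frame as the equilibrium magnetization M0, and invert
   the single-compartment kinetic expression per voxel:

   ```
   f = λ ΔM / (2 α M0 TI1 exp(-TI2 / T1a) q)
   ```

   where α is inversion efficiency, TI1 the tagged-bolus width, TI2 the
   inversion-to-readout time (incremented per slice to the actual
   acquisition time), T1a the arterial-blood T1, λ the blood–brain water
   partition coefficient, and q a dimensionless water-exchange correction.
   q models the tagged water relaxing at the arterial rate until a fixed
   exchange lag Tex after delivery and at the (faster) tissue rate
   thereafter; it is applied per voxel from the gray/white segmentation
   (0.93 / 0.84 at the default tissue constants).
2. **Masks and atlas** — threshold gray/white posterior-probability maps
   at a minimum probability of 0.70 into binary masks, resample an
   integer-labeled lobar parcellation to the perfusion grid by nearest
   neighbour, and form whole-brain perfusion =
   (gray mask + white mask) × (perfusion data).
3. **Composites** — per-region mean/SD of perfusion values between 1 and
   100 mL/100g/min, lobar composites (hemispheres averaged), total brain
   perfusion (mean of the four lobes, tolerating one missing lobe), total
   brain volume and mean cortical thickness from per-region morphometry
   tables, BMI and cardiac index.
4. **Cohort statistics** — standard-score conversion (mean 100, SD 15),
   listwise exclusion, a bivariate correlation screen, and two-block
   hierarchical regression: demographics/medical covariates in block 1,
   perfusion in block 2, tested by the F statistic for the R² change,

   ```
   F = [(R²₂ − R²₁) / Δk] / [(1 − R²₂) / (n − k₂ − 1)]
   ```
5. **Synthetic data** — a digital phantom whose control/tag frames are
   generated by the *same* kinetic expression the quantifier inverts, and
   a cohort generator with configurable covariate correlations and a
   configurable (possibly zero) standardized perfusion effect, so every
   stage is testable without scanner data.

## Worked example

```r
library(paslquant)
p <- acquisition_params()               # TR 2500, TI1 700, TI2 1800, alpha 0.95 ...
compute_q(p, "gray", 1800)              # 0.9276
compute_q(p, "white", 1800)             # 0.8384

# phantom at difference-signal SNR 5, quantified and reduced to lobes
spec <- phantom_spec(noise_sd = noise_sd_for_snr(phantom_spec(), p, snr = 5))
ph   <- simulate_asl_series(spec, p, seed = 42)
tm   <- tissue_masks((ph$tissue == 2) + 0L, (ph$tissue == 1) + 0L)
f    <- quantify_perfusion(compute_delta_m(ph$series), extract_m0(ph$series), p, tm)
lb   <- simulate_labels(spec)
lobar_perfusion(region_stats(f, lb$values, lb$lut))
#>        lobe perfusion n_hemispheres
#> 1   frontal     44.21             2
#> 2  parietal     36.20             2
#> 3  temporal     36.21             2
#> 4 occipital     44.20             2
```

Lobar means sit between the gray (60) and white (20) ground truth because
each lobe mixes both tissues; recovery per region is within 2% of the
same reduction applied to the true CBF map.

```r
co  <- simulate_cohort(cohort_spec(), seed = 1)   # n = 52, true beta = 0.35
fit <- hierarchical_fit(co, "rbans_total",
                        c("age", "sex", "wtar", "cardiac_index", "heart_rate",
                          "htn", "dm", "afib"), "perfusion_total")
fit
#> Block 1  R^2 = 0.291, F(8, 43) = 2.202*
#> Block 2  perfusion_total beta = 0.434 (SE b 0.0378)
#>          R^2 = 0.441, F(9, 42) = 3.674**
#>   Delta R^2 = 0.150, F(1, 42) for Delta R^2 = 11.251** (p = 0.0017)
```

The block-2 standardized β estimates the perfusion effect after
adjustment for the block-1 covariates; the ΔR² F-test asks whether
perfusion adds predictive validity beyond them. (A single n = 52 draw is
noisy: β̂ here is 0.43 against a generating value of 0.35; across 1,000
replicates the mean estimate is unbiased — see the test suite.)

`run_pipeline(config, out_dir, seed)` chains all stages
(simulate → mask → quantify → extract → analyze) and writes a JSON run
manifest with MD5 checksums of every artifact; reruns with the same
config and seed are checksum-identical.

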