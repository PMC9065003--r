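# ramansalt

Chemometric analysis of plant salt (salinity) stress from Raman spectra.

Elevated NaCl in the growth medium changes leaf biochemistry — cell-wall
polysaccharides, pigments, amino acids, and protein amide bands all
respond — and those changes are visible in Raman spectra. `ramansalt`
implements a complete pipeline that turns leaf spectra into a
quantitative stress readout:

- **Preprocessing**: boxcar denoising, fluorescence baseline subtraction
  by concatenated linear fits between consecutive local minima, L2
  (vector) normalization, and quantile-based outlier elimination
  (keep the 0.5%–99.5% central score range).
- **Band-component analysis**: sub-peak counting from the
  Savitzky–Golay second derivative and multi-Gaussian deconvolution of
  spectral windows (the Amide I region, 1590–1720 cm⁻¹, by default),
  reporting per-band center, height, FWHM, and area, plus intensity and
  center trends across weeks and salt concentrations.
- **Concentration regression**: exact Gaussian process regression with
  the rational quadratic kernel

  k_RQ(r) = σ_f² (1 + r² / (2αl²))^(−α),   r = ‖x − x′‖,

  a constant (profiled) mean basis, and marginal-likelihood
  hyperparameter optimization; squared-exponential, Matérn-5/2, and
  exponential kernels, ridge-linear and regression-tree comparators;
  stratified 80/20 evaluation, 5-fold CV, RMSE/R², residual analysis,
  leave-one-concentration-out, and minimum-residual week inference.
- **Synthetic data**: a generator with concentration- and week-dependent
  band structure, broad fluorescence, per-spectrum heterogeneity, and
  raster-scan simulation, so every stage is testable without instrument
  data.

## Worked example

Simulate the default study design (weeks 2–4, 0/50/100/150 mM NaCl,
150 spectra per group), preprocess it, and train a week-3 model:

```r
library(ramansalt)

cfg <- synth_config(seed = 1)
dataset <- generate_dataset(cfg)
pp <- preprocess_pipeline(dataset$set)$set
pp
#> <raman_set: 1782 spectra x 1501 points, 300.0-1800.0 cm-1, with metadata>

m <- pp$meta$week == 3
X <- pp$intensities[m, ]
y <- pp$meta$concentration_mM[m]
sp <- split_train_test(y, 0.2, seed = 4)

fit <- fit_gpr(X[sp$train, ], y[sp$train], kernel = "rq", seed = 4)
fit
#> <gpr_model kernel=rq: n=475, l=1.097, alpha=0.2681, sigma_f=117.5,
#>  sigma_n=0.0006529, beta=3.29 mM>

evaluate(fit, X[sp$test, ], y[sp$test], week = 3)
#> <eval_report week 3: n=119, RMSE=6.220 mM, R2=0.9875>
```

1,800 generated spectra survive outlier elimination as 1,782; the fitted
kernel has a short length scale relative to the unit-norm spectral
inputs and a near-zero noise floor, and the held-out test set of 119
spectra is predicted with an RMSE of 6.2 mM and R² = 0.99. On this
clean synthetic design the GP is nearly exact; ridge linear regression
on the same features trails at ~30 mM RMSE. Band chemistry is available
through `band_trends()` and `fit_gaussian_bands()`, and
`run_pipeline()` orchestrates all stages end to end with a reproducible
manifest.

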