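# Shared synthetic-recovery experiment (generator defaults, weeks 2-4,
# 600 spectra/week). Computed once per test run and cached: several
# regression checks look at different facets of the same experiment.

.recovery_cache <- new.env(parent = emptyenv())

recovery_experiment <- function() {
  if (!is.null(.recovery_cache$res)) return(.recovery_cache$res)
  cfg <- synth_config(seed = 42L)
  pp <- preprocess_pipeline(generate_dataset(cfg)$set)$set
  weeks <- sort(unique(pp$meta$week))
  per_week <- list()
  for (w in weeks) {
    m <- pp$meta$week == w
    X <- pp$intensities[m, , drop = FALSE]
    y <- pp$meta$concentration_mM[m]
    sp <- split_train_test(y, 0.2, seed = 100L + w)
    gpr <- fit_salt_model(X[sp$train, , drop = FALSE], y[sp$train],
                          "gpr-rq", seed = 100L + w)
    ridge <- fit_salt_model(X[sp$train, , drop = FALSE], y[sp$train],
                            "ridge", seed = 100L + w)
    per_week[[as.character(w)]] <- list(
      X_test = X[sp$test, , drop = FALSE], y_test = y[sp$test],
      gpr = gpr, ridge = ridge,
      gpr_eval = evaluate(gpr, X[sp$test, , drop = FALSE], y[sp$test],
                          week = w),
      ridge_eval = evaluate(ridge, X[sp$test, , drop = FALSE], y[sp$test],
                            week = w))
  }
  .recovery_cache$res <- list(set = pp, weeks = weeks, per_week = per_week)
  .recovery_cache$res
}
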