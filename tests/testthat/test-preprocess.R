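test_that("boxcar smoothing averages with truncated edges and is linear", {
  s <- raman_spectrum(1:3, c(1, 2, 3))
  expect_equal(boxcar_smooth(s, 3)$intensity, c(1.5, 2.0, 2.5))
  # window 1 and constant input are identities
  s2 <- raman_spectrum(1:7, rnorm(7))
  expect_equal(boxcar_smooth(s2, 1)$intensity, s2$intensity)
  expect_equal(boxcar_smooth(raman_spectrum(1:7, rep(4, 7)), 5)$intensity,
               rep(4, 7))
  # agrees with a direct windowed-mean oracle
  set.seed(11)
  x <- rnorm(31)
  sm <- boxcar_smooth(raman_spectrum(1:31, x), 5)$intensity
  oracle <- sapply(1:31, function(i) mean(x[max(1, i - 2):min(31, i + 2)]))
  expect_equal(sm, oracle)
  # linear operator
  y <- rnorm(31)
  lhs <- boxcar_smooth(raman_spectrum(1:31, 2 * x + 3 * y), 7)$intensity
  rhs <- 2 * boxcar_smooth(raman_spectrum(1:31, x), 7)$intensity +
    3 * boxcar_smooth(raman_spectrum(1:31, y), 7)$intensity
  expect_equal(lhs, rhs)
  expect_error(boxcar_smooth(s2, 4), class = "ramansalt_parameter_error")
  expect_error(boxcar_smooth(s2, -3), class = "ramansalt_parameter_error")
})

test_that("baseline anchors follow the strict-left/tied-right minimum rule", {
  expect_equal(find_baseline_anchors(raman_spectrum(1:3, c(2, 1, 2))),
               c(1L, 2L, 3L))
  expect_equal(find_baseline_anchors(raman_spectrum(1:6, 1:6)), c(1L, 6L))
  # valley between two peaks found by the brute-force oracle rule
  nu <- 1:41
  y <- gauss_curve(nu, 2, 12, 6) + gauss_curve(nu, 2, 30, 6) + 1
  got <- find_baseline_anchors(raman_spectrum(nu, y))
  expect_equal(got, c(1L, 21L, 41L))
  # plateau: strict-left, non-strict-right picks the first plateau point
  expect_equal(find_baseline_anchors(raman_spectrum(1:5, c(3, 1, 1, 1, 3))),
               c(1L, 2L, 5L))
})

test_that("baseline correction interpolates anchors and reconstructs input", {
  # a straight line is its own baseline
  nu <- seq(400, 500, by = 2)
  line <- raman_spectrum(nu, 0.3 * nu + 7)
  expect_equal(baseline_correct(line)$corrected, rep(0, length(nu)))
  # hand-evaluated sawtooth
  r <- baseline_correct(raman_spectrum(1:5, c(5, 1, 5, 1, 5)))
  expect_equal(r$baseline, c(5, 1, 1, 1, 5))
  expect_equal(r$corrected, c(0, 0, 4, 0, 0))
  expect_equal(r$anchor_indices, c(1L, 2L, 4L, 5L))
  # Gaussian on constant offset: corrected is zero at anchors, and
  # baseline + corrected reconstructs the input exactly
  sp <- raman_spectrum(nu, gauss_curve(nu, 2, 450, 15) + 3)
  b <- baseline_correct(sp)
  expect_equal(b$corrected[b$anchor_indices],
               rep(0, length(b$anchor_indices)))
  expect_identical(b$corrected + b$baseline, sp$intensity)
})

test_that("baseline matches the independent interpolation oracle", {
  set.seed(21)
  for (i in 1:100) {
    sp <- random_peaky_spectrum()
    got <- baseline_correct(sp)
    oracle <- oracle_baseline(sp$shift, sp$intensity)
    expect_lt(max(abs(got$baseline - oracle)), 1e-9)
  }
})

test_that("L2 normalization yields unit norm and is idempotent", {
  # 3-4-5 triangle needs a 3-point minimum axis; embed a zero
  s <- l2_normalize(raman_spectrum(1:3, c(3, 4, 0)))
  expect_equal(s$intensity, c(0.6, 0.8, 0))
  expect_equal(l2_normalize(s)$intensity, s$intensity)
  set.seed(5)
  x <- raman_spectrum(1:50, rnorm(50))
  n1 <- l2_normalize(x)
  expect_equal(sqrt(sum(n1$intensity^2)), 1, tolerance = 1e-12)
  expect_error(l2_normalize(raman_spectrum(1:3, c(0, 0, 0))),
               class = "ramansalt_normalization_error")
})

test_that("quantile filter keeps the closed central interval of scores", {
  set.seed(7)
  n <- 1000
  mat <- matrix(rnorm(n * 5, mean = rep(1:n, 5)), nrow = n)
  rownames(mat) <- paste0("s", 1:n)
  s <- raman_set(1:5, mat)
  # full range keeps everything
  expect_equal(n_spectra(quantile_filter(s, 0, 1)$set), n)
  # matches the brute-force type-7 quantile oracle
  fl <- quantile_filter(s, 0.005, 0.995, score = "total_intensity")
  sc <- rowSums(mat)
  lo <- oracle_quantile7(sc, 0.005)
  hi <- oracle_quantile7(sc, 0.995)
  expect_equal(sort(fl$report$kept_ids),
               sort(rownames(mat)[sc >= lo & sc <= hi]))
  # kept/removed partition the ids
  expect_setequal(c(fl$report$kept_ids, fl$report$removed_ids),
                  rownames(mat))
  expect_length(intersect(fl$report$kept_ids, fl$report$removed_ids), 0)
  # kept count is monotone as the interval widens
  k1 <- n_spectra(quantile_filter(s, 0.05, 0.95)$set)
  k2 <- n_spectra(quantile_filter(s, 0.01, 0.99)$set)
  expect_lte(k1, k2)
  # degenerate equal scores keep everything
  eq <- raman_set(1:5, matrix(1, nrow = 10, ncol = 5,
                              dimnames = list(paste0("e", 1:10), NULL)))
  expect_equal(n_spectra(quantile_filter(eq, 0.25, 0.75)$set), 10)
  expect_error(quantile_filter(s, 0.9, 0.1),
               class = "ramansalt_parameter_error")
})

test_that("per-group filtering computes quantiles within groups", {
  set.seed(8)
  mat <- matrix(rnorm(200 * 4), nrow = 200)
  mat[1:100, ] <- mat[1:100, ] + 100  # two well-separated score groups
  rownames(mat) <- paste0("g", 1:200)
  meta <- data.frame(spectrum_id = rownames(mat),
                     week = rep(c(2, 3), each = 100),
                     concentration_mM = 0)
  s <- raman_set(1:4, mat, meta = meta)
  fl <- quantile_filter(s, 0.05, 0.95, per_group = TRUE)
  kept_week <- s$meta$week[match(fl$report$kept_ids, s$meta$spectrum_id)]
  # both groups lose the same tail fraction
  expect_equal(sum(kept_week == 2), sum(kept_week == 3))
  expect_equal(nrow(fl$report$group_counts), 2)
})

test_that("resampling interpolates linearly and refuses extrapolation", {
  nu <- seq(400, 500, by = 1)
  sp <- raman_spectrum(nu, 2 * nu + 1)
  expect_equal(resample_to_grid(sp, nu)$intensity, sp$intensity)
  g <- seq(410.5, 490.5, by = 7)
  expect_equal(resample_to_grid(sp, g)$intensity, 2 * g + 1)
  expect_error(resample_to_grid(sp, seq(390, 450)),
               class = "ramansalt_extrapolation_error")
  # dense -> coarse -> dense on a smooth curve: error bounded by curvature
  f <- function(x) sin(x / 10)
  dense <- raman_spectrum(nu, f(nu))
  coarse <- resample_to_grid(dense, seq(400, 500, by = 4))
  back <- resample_to_grid(coarse, nu)
  expect_lt(max(abs(back$intensity - f(nu))), (4 / 10)^2 / 8 + 1e-12)
})

test_that("preprocess pipeline applies stages in order", {
  set.seed(9)
  mat <- matrix(abs(rnorm(20 * 50, 5)), nrow = 20,
                dimnames = list(paste0("p", 1:20), NULL))
  s <- raman_set(seq(400, 449), mat)
  # all stages disabled -> identity
  off <- preprocess_config(boxcar_window = NULL, baseline = FALSE,
                           normalize = FALSE, quantile_filter = FALSE)
  expect_identical(preprocess_pipeline(s, off)$set$intensities, mat)
  # every surviving spectrum has unit norm (filter never rescales)
  res <- preprocess_pipeline(s, preprocess_config(lower_q = 0.1,
                                                  upper_q = 0.9))
  norms <- sqrt(rowSums(res$set$intensities^2))
  expect_equal(unname(norms), rep(1, n_spectra(res$set)), tolerance = 1e-12)
  # kept set matches a brute-force reapplication of the stages
  manual <- t(apply(mat, 1, function(row) {
    sp <- boxcar_smooth(raman_spectrum(s$shift, row), 3)
    v <- baseline_correct(sp)$corrected
    v / sqrt(sum(v^2))
  }))
  sc <- rowSums(manual)
  lo <- oracle_quantile7(sc, 0.1)
  hi <- oracle_quantile7(sc, 0.9)
  expect_setequal(res$report$kept_ids, rownames(mat)[sc >= lo & sc <= hi])
})
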