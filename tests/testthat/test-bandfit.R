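amide_spectrum <- function(noise_sd = 0, seed = 1,
                           centers = c(1619, 1657, 1686),
                           heights = c(0.8, 1.0, 0.9), fwhm = 20) {
  set.seed(seed)
  nu <- seq(1550, 1760, by = 1)
  y <- rowSums(sapply(seq_along(centers), function(j) {
    gauss_curve(nu, heights[j], centers[j], fwhm)
  }))
  raman_spectrum(nu, y + rnorm(length(nu), 0, noise_sd), id = "amide")
}

test_that("Savitzky-Golay second derivative is exact for polynomials", {
  nu <- seq(300, 400, by = 1)
  quad <- raman_spectrum(nu, 3 * nu^2)
  expect_equal(second_derivative(quad), rep(6, length(nu)),
               tolerance = 1e-8)
  line <- raman_spectrum(nu, 5 * nu - 2)
  expect_equal(second_derivative(line), rep(0, length(nu)),
               tolerance = 1e-8)
  # non-uniform grids are refused
  expect_error(second_derivative(raman_spectrum(c(1, 2, 4, 8, 16, 32, 64,
                                                  128, 256, 512, 1024, 2048),
                                                rnorm(12))),
               class = "ramansalt_parameter_error")
  expect_error(second_derivative(quad, sg_window = 10),
               class = "ramansalt_parameter_error")
})

test_that("a Gaussian gives one negative second-derivative lobe at center", {
  nu <- seq(1000, 1200, by = 1)
  sp <- raman_spectrum(nu, gauss_curve(nu, 1, 1100, 30))
  d2 <- second_derivative(sp)
  neg <- nu[d2 < -1e-10]
  # analytic: d2 < 0 exactly for |nu - c| < fwhm / (2 sqrt(2 ln 2))
  half <- 30 / (2 * sqrt(2 * log(2)))
  expect_true(all(abs(neg - 1100) < half + 2))
  expect_equal(length(unique(diff(which(d2 < -1e-10)))), 1)  # contiguous
})

test_that("sub-peak counting finds the constructed bands", {
  one <- amide_spectrum(centers = 1657, heights = 1)
  c1 <- count_subpeaks(one, c(1590, 1720))
  expect_equal(c1$count, 1)
  expect_lt(abs(c1$centers - 1657), 1.5)

  three <- amide_spectrum(centers = c(1600, 1650, 1700), heights = rep(1, 3))
  expect_equal(count_subpeaks(three, c(1560, 1750))$count, 3)

  flat <- raman_spectrum(seq(1550, 1760), rep(0, 211))
  expect_equal(count_subpeaks(flat, c(1590, 1720))$count, 0)
  expect_error(count_subpeaks(one, c(1590, 1592)),
               class = "ramansalt_parameter_error")
})

test_that("counting is invariant to positive rescaling", {
  sp <- amide_spectrum(noise_sd = 0.01, seed = 4)
  a <- count_subpeaks(sp, c(1590, 1720))
  sp2 <- raman_spectrum(sp$shift, 37.5 * sp$intensity)
  b <- count_subpeaks(sp2, c(1590, 1720))
  expect_equal(a$count, b$count)
  expect_equal(a$centers, b$centers)
})

test_that("noiseless self-fit recovers parameters to optimizer precision", {
  sp <- amide_spectrum(centers = 1657, heights = 1)
  fit <- fit_gaussian_bands(sp, c(1600, 1720), 1, init_centers = 1650)
  expect_true(fit$converged)
  expect_equal(fit$components$height, 1, tolerance = 1e-6)
  expect_equal(fit$components$center, 1657, tolerance = 1e-6)
  expect_equal(fit$components$fwhm, 20, tolerance = 1e-6)
  # area/height/width relation for a Gaussian line
  expect_equal(fit$components$area,
               fit$components$height * fit$components$fwhm *
                 sqrt(pi / (4 * log(2))), tolerance = 1e-6)
})

test_that("three overlapping bands at 1% noise are resolved", {
  sp <- amide_spectrum(noise_sd = 0.01, seed = 2)
  cs <- count_subpeaks(sp, c(1590, 1720))
  expect_equal(cs$count, 3)
  fit <- fit_gaussian_bands(sp, c(1590, 1720), 3, init_centers = cs$centers)
  expect_true(fit$converged)
  expect_equal(fit$components$center, c(1619, 1657, 1686), tolerance = 1e-3)
  expect_lt(max(abs(fit$components$height - c(0.8, 1.0, 0.9)) /
                  c(0.8, 1.0, 0.9)), 0.05)
  expect_lt(fit$residual_rms, 0.02)
})

test_that("flat data fits to zero height and residual at the noise level", {
  set.seed(6)
  nu <- seq(1550, 1760, by = 1)
  sp <- raman_spectrum(nu, rnorm(length(nu), 0, 0.01))
  fit <- fit_gaussian_bands(sp, c(1590, 1720), 1)
  expect_true(fit$converged)
  expect_lt(fit$components$height, 0.02)
  expect_lt(fit$residual_rms, 0.02)
})

test_that("residual rms does not increase with more bands (nested models)", {
  sp <- amide_spectrum(noise_sd = 0.005, seed = 3)
  rms <- sapply(1:4, function(k) {
    fit_gaussian_bands(sp, c(1590, 1720), k)$residual_rms
  })
  expect_true(all(diff(rms) <= 1e-8))
})

test_that("band intensity extracts window maxima and preserves ordering", {
  cfg <- synth_config(n_per_group = 5, weeks = c(2), noise_sd = 0,
                      het_sd_late = 0, seed = 31)
  d <- generate_dataset(cfg)
  # no normalization: raw amplitudes carry the concentration signal
  vals <- band_intensity(d$set, 1515, half_window = 8)
  meta <- d$set$meta
  means <- tapply(vals[meta$spectrum_id], meta$concentration_mM, mean)
  # carotenoid amplitude decreases with concentration by construction
  expect_true(all(diff(means) < 0))
  # degenerate window: nearest grid point
  one <- get_spectrum(d$set, 1)
  v0 <- band_intensity(d$set, 1515.4, half_window = 0)
  expect_equal(unname(v0[one$id]),
               one$intensity[which.min(abs(one$shift - 1515.4))])
  expect_error(band_intensity(d$set, 9999),
               class = "ramansalt_parameter_error")
})

test_that("band trends aggregate intensities and recover center shifts", {
  cfg <- synth_config(n_per_group = 6, weeks = c(2, 3), noise_sd = 0.01,
                      het_sd_late = 0.05, seed = 32)
  pp <- preprocess_pipeline(generate_dataset(cfg)$set,
                            preprocess_config(quantile_filter = FALSE))$set
  bands <- data.frame(label = c("carotenoid_1515", "chlorophyll_1563"),
                      shift = c(1515, 1563), half_window = 8)
  tr <- band_trends(pp, bands, mode = "intensity")
  expect_equal(nrow(tr), 2 * 2 * 4)  # bands x weeks x concentrations
  # equals direct groupwise aggregation of band_intensity
  v <- band_intensity(pp, 1515, 8)
  direct <- mean(v[pp$meta$spectrum_id[pp$meta$week == 2 &
                                         pp$meta$concentration_mM == 50]])
  expect_equal(tr$value[tr$band_label == "carotenoid_1515" &
                          tr$week == 2 & tr$concentration_mM == 50], direct)

})

test_that("center-mode trends recover a constructed concentration red-shift", {
  # three amide components; only the 1619 band moves (-4 cm-1 at 150 mM)
  bands <- rbind(
    band_spec("methionine_1619", 1619, 20, 0.8, center_shift = -4),
    band_spec("amide1_1657", 1657, 20, 1.0),
    band_spec("amide1_1686", 1686, 20, 0.9))
  cfg <- synth_config(bands = bands, n_per_group = 6, weeks = c(2),
                      noise_sd = 0.005, het_sd_late = 0, seed = 34)
  pp <- preprocess_pipeline(generate_dataset(cfg)$set,
                            preprocess_config(quantile_filter = FALSE))$set
  ctr <- band_trends(pp, mode = "center")
  lab <- unique(ctr$band_label)[1]  # lowest-center component
  b <- ctr[ctr$band_label == lab, ]
  kappa <- b$value[b$concentration_mM == 150] -
    b$value[b$concentration_mM == 0]
  expect_lt(abs(kappa - (-4)), 1)
  # the stationary components stay put
  st <- ctr[ctr$band_label != lab, ]
  drift <- tapply(st$value, st$band_label, function(v) diff(range(v)))
  expect_lt(max(drift), 1)
})

test_that("groups with no spectra are omitted with a warning", {
  cfg <- synth_config(n_per_group = 4, weeks = c(2, 3), noise_sd = 0,
                      het_sd_late = 0, seed = 33)
  d <- generate_dataset(cfg)$set
  # empty one cell of the week x concentration design, keep the margin
  keep <- !(d$meta$concentration_mM == 100 & d$meta$week == 2)
  sub <- subset_spectra(d, d$meta$spectrum_id[keep])
  bands <- data.frame(label = "x", shift = 1515, half_window = 8)
  expect_warning(tr <- band_trends(sub, bands, mode = "intensity"),
                 "omitted")
  expect_false(any(tr$week == 2 & tr$concentration_mM == 100))
  expect_true(any(tr$week == 3 & tr$concentration_mM == 100))
})
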