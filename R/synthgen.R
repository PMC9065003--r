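# Synthetic leaf-Raman generator. Each spectrum is
#   I(nu) = fluor(nu) + h * sum_b A_b(week, c) * G(nu; mu_b(c), fwhm_b) + eps
# with A_b = base_amplitude * max(0, 1 + week_slope*week + conc_slope*c/cmax),
# mu_b = center0 + center_shift * c/cmax, h lognormal (per-spectrum
# heterogeneity), eps iid N(0, noise_sd), fluor a broad Gaussian plus a
# linear offset. Line shapes are Gaussian by default (matched to the
# fitting model); a Lorentzian switch exists to probe misspecification.

#' One synthetic band definition
#'
#' @param label Band name.
#' @param center0 Unstressed center, cm^-1.
#' @param fwhm Full width at half maximum, cm^-1, > 0.
#' @param base_amplitude Amplitude at week 0 / 0 mM, >= 0.
#' @param conc_slope Relative amplitude change per unit `c/c_max`
#'   (negative = band decreases with salt).
#' @param week_slope Relative amplitude change per week.
#' @param center_shift Center displacement, cm^-1, per unit `c/c_max`
#'   (negative = red-shift with salt).
#' @param center_week_shift Center displacement, cm^-1, per week
#'   (negative = the band drifts red as the plant ages).
#' @return One-row data.frame.
#' @export
band_spec <- function(label, center0, fwhm, base_amplitude,
                      conc_slope = 0, week_slope = 0, center_shift = 0,
                      center_week_shift = 0) {
  stopifnot(fwhm > 0, base_amplitude >= 0)
  data.frame(label = label, center0 = center0, fwhm = fwhm,
             base_amplitude = base_amplitude, conc_slope = conc_slope,
             week_slope = week_slope, center_shift = center_shift,
             center_week_shift = center_week_shift)
}

#' Default synthetic band table
#'
#' The reference band set with trend slopes encoding the qualitative
#' biology: cell-wall (cellulose/pectin/serine) and pigment
#' (carotenoid/chlorophyll) bands decrease with medium salt; amide-region
#' and free-amino-acid bands increase with salt within a week but decay
#' across weeks; the 1619/1669/1686 cm^-1 centers red-shift both with salt
#' and, consistently, from week to week as the plant matures.
#' Slope magnitudes are plausible placeholders, not biological estimates.
#'
#' @return Data frame of [band_spec()] rows.
#' @export
default_bands <- function() {
  rbind(
    band_spec("cellulose_522",   522, 18, 0.9, conc_slope = -0.35,
              week_slope = -0.03),
    band_spec("pectin_747",      747, 16, 0.7, conc_slope = -0.30,
              week_slope = -0.03),
    band_spec("serine_855",      855, 16, 0.6, conc_slope = -0.25,
              week_slope = -0.03),
    band_spec("carotenoid_1515", 1515, 22, 1.2, conc_slope = -0.40,
              week_slope = -0.05),
    band_spec("chlorophyll_1563", 1563, 20, 0.8, conc_slope = -0.30,
              week_slope = -0.05),
    band_spec("methionine_1619", 1619, 24, 0.7, conc_slope = 0.20,
              week_slope = -0.04, center_shift = -4,
              center_week_shift = -1),
    band_spec("water_1646",      1646, 26, 0.6, conc_slope = 0.10,
              week_slope = -0.02),
    band_spec("amide1_1657",     1657, 22, 1.0, conc_slope = 0.25,
              week_slope = -0.04, center_shift = -1),
    band_spec("amide1_1669",     1669, 24, 0.8, conc_slope = 0.15,
              week_slope = -0.03, center_shift = -3,
              center_week_shift = -1),
    band_spec("amide1_1686",     1686, 24, 0.7, conc_slope = 0.20,
              week_slope = -0.03, center_shift = -3,
              center_week_shift = -1))
}

#' Synthetic dataset configuration
#'
#' Defaults emulate the study design at desk scale: 4 medium
#' concentrations (0/50/100/150 mM) x weeks 2-4, 150 spectra per group
#' (600 per week), a broad fluorescence background, higher
#' spectrum-to-spectrum heterogeneity in weeks 0-1 than in later weeks,
#' and additive Gaussian noise.
#'
#' @param shift Shift axis, cm^-1 (default 300-1800 step 1).
#' @param bands Band table ([default_bands()]).
#' @param concentrations NaCl levels, mM.
#' @param weeks Weeks simulated.
#' @param n_per_group Spectra per (week, concentration) group.
#' @param fluorescence List: `amplitude`, `center`, `fwhm` of the broad
#'   background Gaussian plus linear `offset` and `slope` (per cm^-1).
#' @param het_sd_early,het_sd_late Lognormal sd of the per-spectrum
#'   multiplicative factor for weeks < 2 and >= 2.
#' @param noise_sd Additive noise sd, intensity units.
#' @param lineshape `"gaussian"` (matched to the band-fit model) or
#'   `"lorentzian"` (misspecification probe).
#' @param seed Integer root seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(shift = seq(300, 1800, by = 1),
                         bands = default_bands(),
                         concentrations = c(0, 50, 100, 150),
                         weeks = 2:4, n_per_group = 150L,
                         fluorescence = list(amplitude = 5, center = 1200,
                                             fwhm = 1500, offset = 0.5,
                                             slope = 3e-4),
                         het_sd_early = 0.3, het_sd_late = 0.08,
                         noise_sd = 0.02, lineshape = "gaussian",
                         seed = 1L) {
  stopifnot(n_per_group >= 1L, noise_sd >= 0, all(weeks >= 0),
            all(concentrations >= 0))
  structure(list(shift = shift, bands = bands,
                 concentrations = concentrations, weeks = weeks,
                 n_per_group = as.integer(n_per_group),
                 fluorescence = fluorescence,
                 het_sd_early = het_sd_early, het_sd_late = het_sd_late,
                 noise_sd = noise_sd,
                 lineshape = match.arg(lineshape,
                                       c("gaussian", "lorentzian")),
                 seed = as.integer(seed)),
            class = "synth_config")
}

het_sd_for_week <- function(config, week) {
  if (week < 2) config$het_sd_early else config$het_sd_late
}

fluor_profile <- function(config) {
  f <- config$fluorescence
  nu <- config$shift
  f$offset + f$slope * (nu - nu[1]) +
    f$amplitude * exp(-4 * log(2) * (nu - f$center)^2 / f$fwhm^2)
}

lineshape_eval <- function(nu, height, center, fwhm, shape) {
  if (shape == "gaussian") {
    gauss_fwhm(nu, height, center, fwhm)
  } else {
    height / (1 + (2 * (nu - center) / fwhm)^2)
  }
}

# latent band amplitudes/centers for one (week, concentration) condition
band_latents <- function(config, week, concentration) {
  b <- config$bands
  cmax <- max(config$concentrations)
  crel <- if (cmax > 0) concentration / cmax else 0
  data.frame(label = b$label,
             amplitude = b$base_amplitude *
               pmax(0, 1 + b$week_slope * week + b$conc_slope * crel),
             center = b$center0 + b$center_shift * crel +
               b$center_week_shift * week,
             fwhm = b$fwhm)
}

#' Generate a single synthetic spectrum
#'
#' Draws from the generative model at the given condition using the
#' current RNG state (seed management belongs to [generate_dataset()]).
#' The latent heterogeneity factor and band table are attached as the
#' `"truth"` attribute.
#'
#' @param config A `synth_config`.
#' @param week,concentration Condition; must be in the config lists.
#' @param id Spectrum id.
#' @return A `raman_spectrum` with attribute `truth` = list(`h`, `bands`).
#' @export
generate_spectrum <- function(config, week, concentration, id = "synth") {
  stopifnot(inherits(config, "synth_config"))
  if (!week %in% config$weeks || !concentration %in% config$concentrations) {
    stop_ramansalt("parameter",
                   "week/concentration not in the configured design")
  }
  nu <- config$shift
  lat <- band_latents(config, week, concentration)
  sig <- numeric(length(nu))
  for (j in seq_len(nrow(lat))) {
    sig <- sig + lineshape_eval(nu, lat$amplitude[j], lat$center[j],
                                lat$fwhm[j], config$lineshape)
  }
  hsd <- het_sd_for_week(config, week)
  h <- if (hsd > 0) stats::rlnorm(1, 0, hsd) else 1
  eps <- if (config$noise_sd > 0) {
    stats::rnorm(length(nu), 0, config$noise_sd)
  } else 0
  sp <- raman_spectrum(nu, fluor_profile(config) + h * sig + eps, id = id)
  attr(sp, "truth") <- list(h = h, bands = lat)
  sp
}

#' Generate a full synthetic dataset
#'
#' `n_per_group` spectra for every (week, concentration) pair, fully
#' reproducible from `config$seed`; metadata and the latent truth table
#' (per-spectrum heterogeneity factor plus per-band amplitude and center)
#' are returned alongside the spectra.
#'
#' @param config A `synth_config`.
#' @return List with `set` (a `raman_set` with metadata) and `truth`
#'   (data.frame: spectrum_id, week, concentration_mM, h, band_label,
#'   amplitude, center).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_total <- length(config$weeks) * length(config$concentrations) *
    config$n_per_group
  mat <- matrix(NA_real_, nrow = n_total, ncol = length(config$shift))
  meta <- vector("list", n_total)
  truth <- vector("list", n_total)
  i <- 0L
  for (w in config$weeks) for (cc in config$concentrations) {
    for (r in seq_len(config$n_per_group)) {
      i <- i + 1L
      id <- sprintf("w%d_c%03d_r%04d", w, cc, r)
      sp <- generate_spectrum(config, w, cc, id = id)
      mat[i, ] <- sp$intensity
      tr <- attr(sp, "truth")
      meta[[i]] <- data.frame(spectrum_id = id, week = w,
                              concentration_mM = cc,
                              replicate = sprintf("r%04d", r),
                              x_um = NA_real_, y_um = NA_real_)
      truth[[i]] <- data.frame(spectrum_id = id, week = w,
                               concentration_mM = cc, h = tr$h,
                               band_label = tr$bands$label,
                               amplitude = tr$bands$amplitude,
                               center = tr$bands$center)
    }
  }
  rownames(mat) <- vapply(meta, `[[`, character(1), "spectrum_id")
  set <- raman_set(config$shift, mat, meta = do.call(rbind, meta))
  list(set = set, truth = do.call(rbind, truth))
}

#' Simulate a raster scan of one condition
#'
#' One spectrum per grid node, both edges inclusive:
#' `(width/step + 1) * (height/step + 1)` spectra with `x_um`/`y_um`
#' metadata. A 300 x 300 um region at 5 um steps gives 61 x 61 = 3721
#' spectra.
#'
#' @param config A `synth_config`.
#' @param region_um Numeric `c(width, height)`, um; must be multiples of
#'   `step_um`.
#' @param step_um Step size, um, > 0.
#' @param week,concentration Condition simulated.
#' @return A `raman_set` with scan-position metadata.
#' @export
generate_scan <- function(config, region_um = c(300, 300), step_um = 5,
                          week = NULL, concentration = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (step_um <= 0) stop_ramansalt("parameter", "step_um must be positive")
  k <- region_um / step_um
  if (any(abs(k - round(k)) > 1e-9)) {
    stop_ramansalt("parameter",
                   "region dimensions must be multiples of step_um")
  }
  week <- week %||% config$weeks[1]
  concentration <- concentration %||% config$concentrations[1]
  xs <- seq(0, region_um[1], by = step_um)
  ys <- seq(0, region_um[2], by = step_um)
  set.seed(config$seed)
  n <- length(xs) * length(ys)
  mat <- matrix(NA_real_, nrow = n, ncol = length(config$shift))
  meta <- vector("list", n)
  i <- 0L
  for (yy in ys) for (xx in xs) {
    i <- i + 1L
    id <- sprintf("scan_x%04d_y%04d", as.integer(xx), as.integer(yy))
    sp <- generate_spectrum(config, week, concentration, id = id)
    mat[i, ] <- sp$intensity
    meta[[i]] <- data.frame(spectrum_id = id, week = week,
                            concentration_mM = concentration,
                            replicate = "scan", x_um = xx, y_um = yy)
  }
  rownames(mat) <- vapply(meta, `[[`, character(1), "spectrum_id")
  raman_set(config$shift, mat, meta = do.call(rbind, meta))
}
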