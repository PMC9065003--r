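# Band component analysis: second-derivative sub-peak counting and
# multi-Gaussian least-squares deconvolution of a spectral window.
# Gaussians are parameterized by FWHM because band "width" is reported as
# full width at half maximum; area = height * fwhm * sqrt(pi / (4 ln 2)).

GAUSS_AREA_CONST <- sqrt(pi / (4 * log(2)))

gauss_fwhm <- function(nu, height, center, fwhm) {
  height * exp(-4 * log(2) * (nu - center)^2 / fwhm^2)
}

multi_gauss <- function(nu, par) {
  k <- length(par) / 3
  h <- par[seq_len(k)]
  cn <- par[k + seq_len(k)]
  w <- par[2 * k + seq_len(k)]
  y <- numeric(length(nu))
  for (j in seq_len(k)) y <- y + gauss_fwhm(nu, h[j], cn[j], w[j])
  y
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' Smoothed second derivative of intensity with respect to Raman shift,
#' exact for polynomials up to the filter order. Requires a (near-)uniform
#' shift grid.
#'
#' @param spectrum A `raman_spectrum` on a uniform axis.
#' @param sg_window Odd filter window length in points (default 11).
#' @param sg_order Polynomial order, >= 2 and < `sg_window` (default 3).
#' @return Numeric vector, d2 intensity / d shift^2, same length as input.
#' @export
second_derivative <- function(spectrum, sg_window = 11L, sg_order = 3L) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  n <- length(spectrum$shift)
  sg_window <- as.integer(sg_window)
  if (sg_window %% 2L == 0L || sg_order < 2L || sg_window <= sg_order ||
      sg_window > n) {
    stop_ramansalt("parameter",
                   "need odd sg_window with 2 <= sg_order < sg_window <= n")
  }
  d <- diff(spectrum$shift)
  if (diff(range(d)) > 1e-6 * mean(d)) {
    stop_ramansalt("parameter",
                   "second_derivative requires a uniform shift grid; resample first")
  }
  as.numeric(signal::sgolayfilt(spectrum$intensity, p = sg_order,
                                n = sg_window, m = 2, ts = mean(d)))
}

#' Count sub-peaks in a window from the second derivative
#'
#' Each underlying band produces a negative lobe in the second derivative;
#' the lobe minima whose depth reaches `prominence_frac` of the deepest
#' lobe are counted as sub-peaks, and their shift positions are returned
#' as initial centers for [fit_gaussian_bands()]. The count is invariant
#' to positive rescaling of the spectrum.
#'
#' @param spectrum A `raman_spectrum` (preprocessed).
#' @param window Numeric `c(lo, hi)` in cm^-1, inside the axis.
#' @param prominence_frac Fraction of the deepest lobe required (default 0.1).
#' @param sg_window,sg_order Passed to [second_derivative()].
#' @return List with `count` and `centers` (cm^-1, sorted).
#' @export
count_subpeaks <- function(spectrum, window, prominence_frac = 0.1,
                           sg_window = 11L, sg_order = 3L) {
  stopifnot(inherits(spectrum, "raman_spectrum"), length(window) == 2)
  idx <- which(spectrum$shift >= window[1] & spectrum$shift <= window[2])
  if (length(idx) < sg_window) {
    stop_ramansalt("parameter", "window contains too few points")
  }
  d2 <- second_derivative(spectrum, sg_window, sg_order)[idx]
  # one candidate per contiguous negative lobe: its deepest point
  neg <- d2 < 0
  if (!any(neg)) return(list(count = 0L, centers = numeric(0)))
  run <- rle(neg)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  lobes <- which(run$values)
  mins <- vapply(lobes, function(k) {
    seg <- starts[k]:ends[k]
    seg[which.min(d2[seg])]
  }, integer(1))
  depth <- -d2[mins]
  keep <- depth >= prominence_frac * max(depth)
  centers <- sort(spectrum$shift[idx][mins[keep]])
  list(count = length(centers), centers = centers)
}

#' Fit a sum of Gaussian bands to a spectral window
#'
#' Levenberg-Marquardt least squares of
#' `sum_i h_i * exp(-4 ln2 (nu - c_i)^2 / w_i^2)` against the windowed
#' intensity, iterated until the relative cost change drops below `tol` or
#' `max_iter` iterations. Non-convergence is reported via the `converged`
#' flag, never silently; two fitted centers closer than twice the grid
#' step trigger a degeneracy warning.
#'
#' @param spectrum A `raman_spectrum` (baseline-corrected).
#' @param window Numeric `c(lo, hi)` in cm^-1.
#' @param n_bands Number of Gaussian components, >= 1.
#' @param init_centers Optional starting centers (cm^-1, inside the
#'   window); defaults to [count_subpeaks()] candidates padded with
#'   equally spaced positions.
#' @param init_fwhm Starting FWHM, cm^-1 (default 15).
#' @param max_iter Iteration cap (default 500).
#' @param tol Relative cost-change convergence tolerance (default 1e-10).
#' @return A `band_fit` object: `window`, `components` (data.frame with
#'   `center`, `height`, `fwhm`, `area`, sorted by center), `residual_rms`,
#'   `n_iterations`, `converged`, and `fitted` values.
#' @export
fit_gaussian_bands <- function(spectrum, window, n_bands,
                               init_centers = NULL, init_fwhm = 15,
                               max_iter = 500L, tol = 1e-10) {
  stopifnot(inherits(spectrum, "raman_spectrum"), length(window) == 2,
            n_bands >= 1)
  idx <- which(spectrum$shift >= window[1] & spectrum$shift <= window[2])
  if (length(idx) < 3 * n_bands) {
    stop_ramansalt("parameter", "window too small for ", n_bands, " bands")
  }
  nu <- spectrum$shift[idx]
  y <- spectrum$intensity[idx]
  step <- stats::median(diff(nu))

  centers <- init_centers
  if (is.null(centers)) {
    cand <- tryCatch(count_subpeaks(spectrum, window)$centers,
                     error = function(e) numeric(0))
    centers <- utils::head(cand, n_bands)
  }
  if (length(centers) < n_bands) {  # pad with equally spaced positions
    pad <- seq(window[1], window[2],
               length.out = n_bands - length(centers) + 2)[-c(1, n_bands -
                                                              length(centers) + 2)]
    centers <- sort(c(centers, pad))
  }
  centers <- sort(centers[seq_len(n_bands)])
  if (any(centers < window[1] | centers > window[2])) {
    stop_ramansalt("parameter", "init_centers must lie inside the window")
  }
  h0 <- pmax(y[vapply(centers, function(cc) which.min(abs(nu - cc)),
                      integer(1))], 1e-8)
  par0 <- c(h0, centers, rep(init_fwhm, n_bands))
  lower <- c(rep(0, n_bands), rep(window[1], n_bands),
             rep(max(step, 1e-3), n_bands))
  upper <- c(rep(Inf, n_bands), rep(window[2], n_bands),
             rep(2 * (window[2] - window[1]), n_bands))

  fit <- minpack.lm::nls.lm(
    par = par0,
    fn = function(p) y - multi_gauss(nu, p),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(
      maxiter = min(max_iter, 1024L), ftol = tol, ptol = tol, gtol = 0))
  p <- fit$par
  k <- n_bands
  comp <- data.frame(center = p[k + seq_len(k)], height = p[seq_len(k)],
                     fwhm = p[2 * k + seq_len(k)])
  comp$area <- comp$height * comp$fwhm * GAUSS_AREA_CONST
  comp <- comp[order(comp$center), , drop = FALSE]
  rownames(comp) <- NULL
  if (k > 1 && any(diff(comp$center) < 2 * step)) {
    warning("degenerate band fit: two centers within the grid resolution",
            call. = FALSE)
  }
  res <- y - multi_gauss(nu, p)
  structure(list(window = window, components = comp,
                 residual_rms = sqrt(mean(res^2)),
                 n_iterations = fit$niter,
                 converged = fit$info %in% 1:4,
                 shift = nu, fitted = multi_gauss(nu, p)),
            class = "band_fit")
}

#' @export
print.band_fit <- function(x, ...) {
  cat(sprintf("<band_fit %g-%g cm-1: %d components, residual rms %.3g, %s>\n",
              x$window[1], x$window[2], nrow(x$components), x$residual_rms,
              if (x$converged) "converged" else "NOT converged"))
  print(x$components)
  invisible(x)
}

#' Per-spectrum band intensity at a target position
#'
#' The maximum intensity within `shift_cm1 +/- half_window` per spectrum;
#' with `half_window = 0` the value at the nearest grid point.
#'
#' @param set A `raman_set` (normalized).
#' @param shift_cm1 Target band position, cm^-1 (must lie on the axis range).
#' @param half_window Half window, cm^-1 (default 5).
#' @return Named numeric vector, one value per spectrum.
#' @export
band_intensity <- function(set, shift_cm1, half_window = 5) {
  stopifnot(inherits(set, "raman_set"))
  if (shift_cm1 < min(set$shift) || shift_cm1 > max(set$shift)) {
    stop_ramansalt("parameter", "band position ", shift_cm1,
                   " cm-1 is off the shift axis")
  }
  idx <- which(set$shift >= shift_cm1 - half_window &
               set$shift <= shift_cm1 + half_window)
  if (!length(idx)) idx <- which.min(abs(set$shift - shift_cm1))
  vals <- apply(set$intensities[, idx, drop = FALSE], 1, max)
  names(vals) <- spectrum_ids(set)
  vals
}

#' Band trends across weeks and concentrations
#'
#' With `mode = "intensity"`, aggregates [band_intensity()] per
#' (week, concentration) group: mean plus interquartile range. With
#' `mode = "center"`, fits Gaussian components to each group's mean
#' spectrum over `center_window` (the Amide I region by default), matches
#' components across groups to the lowest-concentration reference of the
#' same week by nearest center, and reports the matched centers. Group
#' fits at realistic noise are run on mean spectra because per-spectrum
#' deconvolution is unstable.
#'
#' @param set A preprocessed `raman_set` with metadata.
#' @param bands Data frame with columns `label`, `shift`, `half_window`
#'   (intensity mode only).
#' @param mode `"intensity"` or `"center"`.
#' @param center_window Window for center-mode deconvolution, cm^-1
#'   (default `c(1590, 1720)`).
#' @param n_bands Number of components in center mode; default taken from
#'   [count_subpeaks()] on the reference group's mean spectrum.
#' @return A data.frame with columns week, concentration_mM, band_label,
#'   value (mean intensity or fitted center, cm^-1) and iqr (NA in center
#'   mode, where one fit per group exists).
#' @export
band_trends <- function(set, bands = NULL,
                        mode = c("intensity", "center"),
                        center_window = c(1590, 1720), n_bands = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(set, "raman_set"))
  if (is.null(set$meta)) stop_ramansalt("metadata", "band_trends needs metadata")
  weeks <- sort(unique(set$meta$week))
  concs <- sort(unique(set$meta$concentration_mM))
  rows <- list()
  if (mode == "intensity") {
    stopifnot(is.data.frame(bands))
    for (b in seq_len(nrow(bands))) {
      vals <- band_intensity(set, bands$shift[b], bands$half_window[b])
      for (w in weeks) for (cc in concs) {
        m <- set$meta$week == w & set$meta$concentration_mM == cc
        if (!any(m)) {
          warning(sprintf("group week %s / %s mM has no spectra; omitted",
                          w, cc), call. = FALSE)
          next
        }
        v <- vals[set$meta$spectrum_id[m]]
        rows[[length(rows) + 1L]] <- data.frame(
          week = w, concentration_mM = cc,
          band_label = bands$label[b],
          value = mean(v), iqr = stats::IQR(v))
      }
    }
  } else {
    for (w in weeks) {
      ref_fit <- NULL
      for (cc in concs) {
        m <- set$meta$week == w & set$meta$concentration_mM == cc
        if (!any(m)) {
          warning(sprintf("group week %s / %s mM has no spectra; omitted",
                          w, cc), call. = FALSE)
          next
        }
        mean_sp <- raman_spectrum(set$shift,
                                  colMeans(set$intensities[m, , drop = FALSE]),
                                  id = sprintf("w%s_c%s_mean", w, cc))
        if (is.null(ref_fit)) {
          k <- n_bands
          init <- NULL
          if (is.null(k)) {
            cs <- count_subpeaks(mean_sp, center_window)
            k <- max(cs$count, 1L)
            init <- cs$centers
          }
          ref_fit <- fit_gaussian_bands(mean_sp, center_window, k,
                                        init_centers = init)
          labels <- sprintf("band_%d", round(ref_fit$components$center))
          fit <- ref_fit
        } else {
          fit <- fit_gaussian_bands(mean_sp, center_window,
                                    nrow(ref_fit$components),
                                    init_centers = ref_fit$components$center)
        }
        # nearest-center matching to the reference component list
        ord <- vapply(ref_fit$components$center,
                      function(rc) which.min(abs(fit$components$center - rc)),
                      integer(1))
        rows[[length(rows) + 1L]] <- data.frame(
          week = w, concentration_mM = cc, band_label = labels,
          value = fit$components$center[ord], iqr = NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reference band positions and tentative assignments
#'
#' The band set used throughout: cellulose 522, pectin 747, serine 855,
#' carotenoid 1515, chlorophyll b 1563, and the Amide I region components
#' 1619/1646/1657/1669/1686 cm^-1.
#'
#' @return Data frame with `label`, `shift` (cm^-1), `assignment`.
#' @export
reference_bands <- function() {
  data.frame(
    label = c("cellulose_522", "pectin_747", "serine_855",
              "carotenoid_1515", "chlorophyll_1563", "methionine_1619",
              "water_1646", "amide1_1657", "amide1_1669", "amide1_1686"),
    shift = c(522, 747, 855, 1515, 1563, 1619, 1646, 1657, 1669, 1686),
    assignment = c("nu(C-O-C) cellulose", "nu(C-O-H) pectin",
                   "omega(Ce-H) serine", "nu(C=C) carotenoid",
                   "chlorophyll b",
                   "delta(H-N-H) methionine / lysine / tyrosine",
                   "delta(H2O) water / nu(C=C) ethylene",
                   "nu(C=O)+omega(N-H) amide I",
                   "nu(C=O)+omega(N-H) amide I",
                   "nu(C=O)+omega(N-H) amide I"))
}
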