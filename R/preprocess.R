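# Preprocessing chain: boxcar denoising -> piecewise-linear fluorescence
# baseline subtraction anchored at local minima -> L2 normalization ->
# quantile outlier elimination.

#' Boxcar (moving-average) smoothing
#'
#' Each point is replaced by the mean of the window centred on it; at the
#' spectrum edges the window is truncated to the available points rather
#' than padded, so no intensity is fabricated beyond the axis.
#'
#' @param spectrum A `raman_spectrum`.
#' @param window Odd positive integer window width in spectral points
#'   (default 3, the acquisition-time denoising width).
#' @return A smoothed `raman_spectrum` on the same axis.
#' @export
boxcar_smooth <- function(spectrum, window = 3L) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  window <- as.integer(window)
  n <- length(spectrum$intensity)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    stop_ramansalt("parameter", "window must be an odd positive integer")
  }
  if (window > n) {
    stop_ramansalt("parameter", "window (", window,
                   ") exceeds spectrum length (", n, ")")
  }
  if (window == 1L) return(spectrum)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, spectrum$intensity))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  raman_spectrum(spectrum$shift, out, id = spectrum$id)
}

#' Locate baseline anchor points (local intensity minima)
#'
#' An interior index i is an anchor when intensity strictly decreases into
#' it from the left and does not increase leaving it to the right
#' (`x[i] < x[i-1]` and `x[i] <= x[i+1]`); the asymmetric tie rule resolves
#' plateaus deterministically. The first and last points are always
#' anchors so the baseline is defined over the full axis.
#'
#' @param spectrum A `raman_spectrum` with at least 3 points.
#' @return Sorted integer vector of anchor indices (1-based).
#' @export
find_baseline_anchors <- function(spectrum) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  x <- spectrum$intensity
  n <- length(x)
  i <- 2:(n - 1L)
  interior <- i[x[i] < x[i - 1L] & x[i] <= x[i + 1L]]
  sort(unique(c(1L, interior, n)))
}

#' Estimate and subtract the fluorescence baseline
#'
#' The baseline linearly interpolates the intensity values between
#' consecutive anchor minima in shift (cm^-1) coordinates; concatenating
#' those segments gives the estimated fluorescence profile, which is
#' subtracted. The corrected signal is exactly zero at every anchor and
#' may be negative between anchors (noise below baseline is not clipped).
#'
#' @param spectrum A `raman_spectrum`.
#' @return A `baseline_result` list: `baseline`, `corrected` (both numeric
#'   vectors on the input axis), `anchor_indices`, and the input `spectrum`.
#' @export
baseline_correct <- function(spectrum) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  anchors <- find_baseline_anchors(spectrum)
  baseline <- stats::approx(spectrum$shift[anchors],
                            spectrum$intensity[anchors],
                            xout = spectrum$shift, method = "linear",
                            ties = "ordered")$y
  baseline[anchors] <- spectrum$intensity[anchors]  # exact at anchors
  corrected <- spectrum$intensity - baseline
  structure(list(baseline = baseline, corrected = corrected,
                 anchor_indices = anchors, spectrum = spectrum),
            class = "baseline_result")
}

#' L2 (vector) normalization
#'
#' Divides the intensity vector by its Euclidean norm so the result has
#' unit length; idempotent. An all-zero spectrum cannot be normalized.
#'
#' @param spectrum A `raman_spectrum`.
#' @return A unit-norm `raman_spectrum`.
#' @export
l2_normalize <- function(spectrum) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  nrm <- sqrt(sum(spectrum$intensity^2))
  if (!is.finite(nrm) || nrm == 0) {
    stop_ramansalt("normalization", "cannot normalize: zero or non-finite norm")
  }
  raman_spectrum(spectrum$shift, spectrum$intensity / nrm, id = spectrum$id)
}

spectrum_scores <- function(set, score = c("total_intensity", "l2_norm_raw")) {
  score <- match.arg(score)
  switch(score,
         total_intensity = rowSums(set$intensities),
         l2_norm_raw = sqrt(rowSums(set$intensities^2)))
}

#' Quantile-based outlier elimination
#'
#' Computes a scalar score per spectrum and keeps the spectra whose score
#' lies in the closed interval between the `lower_q` and `upper_q` sample
#' quantiles (linear interpolation between order statistics, R type 7).
#' With `per_group = TRUE` the quantiles are computed within each
#' (week, concentration) metadata group.
#'
#' @param set A `raman_set`.
#' @param lower_q,upper_q Quantile levels as fractions, default 0.005 and
#'   0.995 (keep the central 99%).
#' @param score Scored quantity: `"total_intensity"` (sum of intensities,
#'   default) or `"l2_norm_raw"` (Euclidean norm).
#' @param per_group Compute quantiles within (week, concentration_mM)
#'   groups; requires metadata.
#' @return List with `set` (the filtered `raman_set`) and `report`, a
#'   `quantile_filter_report` holding `kept_ids`, `removed_ids`, the
#'   quantile levels, `score_name` and per-group kept counts.
#' @export
quantile_filter <- function(set, lower_q = 0.005, upper_q = 0.995,
                            score = c("total_intensity", "l2_norm_raw"),
                            per_group = FALSE) {
  score <- match.arg(score)
  if (n_spectra(set) == 0L) stop_ramansalt("input", "empty spectrum set")
  if (!(lower_q >= 0 && lower_q < upper_q && upper_q <= 1)) {
    stop_ramansalt("parameter", "need 0 <= lower_q < upper_q <= 1")
  }
  s <- spectrum_scores(set, score)
  ids <- spectrum_ids(set)
  if (per_group) {
    if (is.null(set$meta)) {
      stop_ramansalt("metadata", "per_group filtering requires metadata")
    }
    grp <- interaction(set$meta$week, set$meta$concentration_mM, drop = TRUE)
    keep <- logical(length(s))
    for (g in levels(grp)) {
      m <- grp == g
      q <- stats::quantile(s[m], c(lower_q, upper_q), type = 7, names = FALSE)
      keep[m] <- s[m] >= q[1] & s[m] <= q[2]
    }
  } else {
    q <- stats::quantile(s, c(lower_q, upper_q), type = 7, names = FALSE)
    keep <- s >= q[1] & s <= q[2]
  }
  kept <- ids[keep]
  out <- subset_spectra(set, kept)
  report <- structure(list(kept_ids = kept, removed_ids = ids[!keep],
                           lower_q = lower_q, upper_q = upper_q,
                           score_name = score,
                           quantile_type = "linear interpolation (type 7)",
                           group_counts = group_count_table(out)),
                      class = "quantile_filter_report")
  list(set = out, report = report)
}

# per-(week, concentration) spectrum counts, the layout used for reporting
# how many spectra survive elimination in each group
group_count_table <- function(set) {
  if (is.null(set$meta)) return(NULL)
  agg <- stats::aggregate(list(n = set$meta$spectrum_id),
                          by = list(week = set$meta$week,
                                    concentration_mM = set$meta$concentration_mM),
                          FUN = length)
  agg[order(agg$week, agg$concentration_mM), , drop = FALSE]
}

#' Resample a spectrum onto a target shift grid
#'
#' Linear interpolation; the target grid must lie inside the source axis
#' range (extrapolation is refused). This is the only sanctioned way to
#' merge spectra recorded on different axes.
#'
#' @param spectrum A `raman_spectrum`.
#' @param grid Strictly increasing target shift axis, cm^-1.
#' @return The resampled `raman_spectrum` on `grid`.
#' @export
resample_to_grid <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  grid <- as.numeric(grid)
  if (min(grid) < min(spectrum$shift) || max(grid) > max(spectrum$shift)) {
    stop_ramansalt("extrapolation",
                   "target grid extends beyond the spectrum's axis range")
  }
  y <- stats::approx(spectrum$shift, spectrum$intensity, xout = grid,
                     method = "linear", ties = "ordered")$y
  raman_spectrum(grid, y, id = spectrum$id)
}

#' Default preprocessing configuration
#'
#' @param boxcar_window Odd integer or NULL to skip smoothing (default 3).
#' @param baseline,normalize Logical stage switches.
#' @param lower_q,upper_q Quantile elimination levels (0.005/0.995); set
#'   `quantile_filter = FALSE` to skip elimination.
#' @param quantile_filter Logical, run the elimination stage.
#' @param score Scored quantity for elimination.
#' @param per_group Group-wise quantiles (needs metadata).
#' @return A named list understood by [preprocess_pipeline()].
#' @export
preprocess_config <- function(boxcar_window = 3L, baseline = TRUE,
                              normalize = TRUE, quantile_filter = TRUE,
                              lower_q = 0.005, upper_q = 0.995,
                              score = "total_intensity", per_group = FALSE) {
  list(boxcar_window = boxcar_window, baseline = baseline,
       normalize = normalize, quantile_filter = quantile_filter,
       lower_q = lower_q, upper_q = upper_q, score = score,
       per_group = per_group)
}

#' Run the full preprocessing chain on a spectrum set
#'
#' Stage order: boxcar smoothing (optional), baseline correction, L2
#' normalization, quantile elimination. Every output spectrum therefore has
#' unit Euclidean norm (the filter drops spectra but never rescales them).
#'
#' @param set A `raman_set`.
#' @param config List from [preprocess_config()].
#' @param verbose Log per-group kept counts to stderr.
#' @return List with the processed `set` and the `report` from the
#'   elimination stage (NULL when that stage is disabled).
#' @export
preprocess_pipeline <- function(set, config = preprocess_config(),
                                verbose = FALSE) {
  stopifnot(inherits(set, "raman_set"))
  mat <- set$intensities
  n <- n_spectra(set)
  for (i in seq_len(n)) {
    sp <- raman_spectrum(set$shift, mat[i, ], id = spectrum_ids(set)[i])
    if (!is.null(config$boxcar_window) && config$boxcar_window > 1L) {
      sp <- boxcar_smooth(sp, config$boxcar_window)
    }
    if (isTRUE(config$baseline)) {
      sp$intensity <- baseline_correct(sp)$corrected
    }
    if (isTRUE(config$normalize)) {
      sp <- l2_normalize(sp)
    }
    mat[i, ] <- sp$intensity
  }
  out <- raman_set(set$shift, mat)
  if (!is.null(set$meta)) out$meta <- set$meta
  report <- NULL
  if (isTRUE(config$quantile_filter)) {
    fl <- quantile_filter(out, lower_q = config$lower_q,
                          upper_q = config$upper_q,
                          score = config$score,
                          per_group = isTRUE(config$per_group))
    out <- fl$set
    report <- fl$report
    if (verbose && !is.null(report$group_counts)) {
      message("spectra kept per (week, concentration) group:")
      message(paste(utils::capture.output(print(report$group_counts)),
                    collapse = "\n"))
    }
  }
  list(set = out, report = report)
}
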