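#' Construct a single Raman spectrum
#'
#' A spectrum is a strictly increasing Raman shift axis (cm^-1) paired with an
#' intensity vector in arbitrary units. Negative intensities are permitted
#' (baseline-corrected signal dips below zero in noise), `NA`/`NaN` are not.
#'
#' @param shift Numeric vector of Raman shifts, cm^-1, strictly increasing,
#'   length >= 3.
#' @param intensity Numeric vector, same length as `shift`.
#' @param id Spectrum identifier (single string).
#' @return An object of class `raman_spectrum`: a list with elements
#'   `shift`, `intensity`, `id`.
#' @examples
#' s <- raman_spectrum(400:410, rnorm(11) + 10, id = "a")
#' @export
raman_spectrum <- function(shift, intensity, id = "spectrum") {
  shift <- as.numeric(shift)
  intensity <- as.numeric(intensity)
  if (length(shift) != length(intensity)) {
    stop_ramansalt("format", "shift and intensity lengths differ (",
                   length(shift), " vs ", length(intensity), ")")
  }
  if (length(shift) < 3L) {
    stop_ramansalt("format", "a spectrum needs at least 3 points")
  }
  if (anyNA(shift) || any(!is.finite(shift))) {
    stop_ramansalt("axis", "shift axis contains NA or non-finite values")
  }
  if (any(diff(shift) <= 0)) {
    stop_ramansalt("axis", "shift axis must be strictly increasing")
  }
  if (anyNA(intensity) || any(is.nan(intensity))) {
    stop_ramansalt("validation", "intensity contains NA/NaN")
  }
  structure(list(shift = shift, intensity = intensity,
                 id = as.character(id)[1]),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum '%s': %d points, %.1f-%.1f cm-1>\n",
              x$id, length(x$shift), min(x$shift), max(x$shift)))
  invisible(x)
}

#' Construct an aligned collection of Raman spectra
#'
#' All member spectra share one shift axis exactly (bitwise-equal values);
#' merging spectra on different grids must go through [resample_to_grid()]
#' so that interpolation is always explicit.
#'
#' @param shift Shared shift axis, cm^-1, strictly increasing.
#' @param intensities Numeric matrix, one row per spectrum, `length(shift)`
#'   columns. Row names are used as spectrum ids if present.
#' @param meta Optional data.frame of per-spectrum metadata with at least a
#'   `spectrum_id` column matching the intensity row names one-to-one.
#' @return An object of class `raman_set`: list with `shift`, `intensities`
#'   (rownamed matrix) and `meta` (data.frame or NULL).
#' @export
raman_set <- function(shift, intensities, meta = NULL) {
  shift <- as.numeric(shift)
  if (any(diff(shift) <= 0)) {
    stop_ramansalt("axis", "shared shift axis must be strictly increasing")
  }
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (ncol(intensities) != length(shift)) {
    stop_ramansalt("format", "intensity matrix has ", ncol(intensities),
                   " columns but the axis has ", length(shift), " points")
  }
  if (anyNA(intensities)) {
    stop_ramansalt("validation", "intensity matrix contains NA/NaN")
  }
  if (is.null(rownames(intensities)) && nrow(intensities) > 0) {
    rownames(intensities) <- sprintf("s%03d", seq_len(nrow(intensities)))
  }
  obj <- structure(list(shift = shift, intensities = intensities,
                        meta = NULL),
                   class = "raman_set")
  if (!is.null(meta)) obj <- set_meta(obj, meta)
  obj
}

set_meta <- function(set, meta) {
  meta <- as.data.frame(meta)
  if (!"spectrum_id" %in% names(meta)) {
    stop_ramansalt("metadata", "metadata must have a 'spectrum_id' column")
  }
  meta$spectrum_id <- as.character(meta$spectrum_id)
  if (anyDuplicated(meta$spectrum_id)) {
    dup <- unique(meta$spectrum_id[duplicated(meta$spectrum_id)])
    stop_ramansalt("metadata", "duplicate spectrum_id rows: ",
                   paste(utils::head(dup, 5), collapse = ", "))
  }
  ids <- spectrum_ids(set)
  missing <- setdiff(ids, meta$spectrum_id)
  if (length(missing)) {
    stop_ramansalt("metadata", "no metadata row for spectrum id(s): ",
                   paste(utils::head(missing, 10), collapse = ", "))
  }
  if ("concentration_mM" %in% names(meta) &&
      any(meta$concentration_mM < 0, na.rm = TRUE)) {
    stop_ramansalt("metadata", "concentration_mM must be non-negative")
  }
  set$meta <- meta[match(ids, meta$spectrum_id), , drop = FALSE]
  rownames(set$meta) <- NULL
  set
}

#' @export
print.raman_set <- function(x, ...) {
  cat(sprintf("<raman_set: %d spectra x %d points, %.1f-%.1f cm-1%s>\n",
              nrow(x$intensities), length(x$shift),
              min(x$shift), max(x$shift),
              if (is.null(x$meta)) "" else ", with metadata"))
  invisible(x)
}

#' Number of spectra in a set
#' @param set A `raman_set`.
#' @return Integer count.
#' @export
n_spectra <- function(set) nrow(set$intensities)

#' Spectrum ids of a set
#' @param set A `raman_set`.
#' @return Character vector of ids in storage order.
#' @export
spectrum_ids <- function(set) rownames(set$intensities)

#' Extract one spectrum from a set
#' @param set A `raman_set`.
#' @param id Spectrum id or integer index.
#' @return A `raman_spectrum`.
#' @export
get_spectrum <- function(set, id) {
  if (is.numeric(id)) id <- spectrum_ids(set)[id]
  if (!id %in% spectrum_ids(set)) {
    stop_ramansalt("input", "no spectrum with id '", id, "'")
  }
  raman_spectrum(set$shift, set$intensities[id, ], id = id)
}

#' Subset a set by spectrum ids
#' @param set A `raman_set`.
#' @param ids Character ids (or logical/integer index) to keep.
#' @return A `raman_set` with matching metadata rows.
#' @export
subset_spectra <- function(set, ids) {
  if (is.logical(ids) || is.numeric(ids)) ids <- spectrum_ids(set)[ids]
  keep <- match(ids, spectrum_ids(set))
  if (anyNA(keep)) stop_ramansalt("input", "unknown spectrum id(s)")
  out <- raman_set(set$shift, set$intensities[keep, , drop = FALSE])
  if (!is.null(set$meta)) {
    out$meta <- set$meta[keep, , drop = FALSE]
    rownames(out$meta) <- NULL
  }
  out
}

# classed conditions so callers can distinguish failure modes
stop_ramansalt <- function(class, ...) {
  stop(structure(class = c(paste0("ramansalt_", class, "_error"),
                           "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
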