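# Plain-text spectral IO. Two dialects:
#   wide: column 1 "shift_cm-1", one column per spectrum (header = id)
#   long: columns spectrum_id, shift_cm-1, intensity
# Delimiter (TAB or comma) is sniffed by fread on read; writes are TSV/CSV by
# file extension (.csv -> comma, anything else -> TAB).

SHIFT_COL <- "shift_cm-1"

#' Read a spectral table into a `raman_set`
#'
#' @param path Path to a delimited text file (delimiter sniffed).
#' @param dialect `"wide"` (first column `shift_cm-1`, one column per
#'   spectrum) or `"long"` (columns `spectrum_id`, `shift_cm-1`,
#'   `intensity`). In the long dialect every spectrum must be on the
#'   identical shift grid; mismatches raise an alignment error.
#' @return A `raman_set` (no metadata attached; see [attach_metadata()]).
#' @seealso [write_spectrum_table()]
#' @export
read_spectrum_table <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_ramansalt("io", "file not found: ", path)
  # ragged rows surface as fread warnings; collect them without
  # interrupting fread (aborting mid-read leaves its session dirty), then
  # fail with a format error
  warn_msgs <- character(0)
  dt <- tryCatch(
    withCallingHandlers(
      data.table::fread(path, header = TRUE, check.names = FALSE,
                        fill = FALSE, data.table = FALSE),
      warning = function(w) {
        warn_msgs <<- c(warn_msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
    error = function(e) stop_ramansalt("format", "cannot parse '", path,
                                       "': ", conditionMessage(e)))
  if (length(warn_msgs)) {
    stop_ramansalt("format", "malformed table '", path, "': ",
                   paste(warn_msgs, collapse = "; "))
  }
  if (dialect == "wide") {
    if (names(dt)[1] != SHIFT_COL) {
      stop_ramansalt("format", "wide dialect requires first column '",
                     SHIFT_COL, "', got '", names(dt)[1], "'")
    }
    shift <- dt[[1]]
    if (any(diff(shift) <= 0)) {
      stop_ramansalt("axis", "shift axis in '", path,
                     "' is not strictly increasing")
    }
    ids <- names(dt)[-1]
    mat <- t(as.matrix(dt[, -1, drop = FALSE]))
    rownames(mat) <- ids
    raman_set(shift, mat)
  } else {
    need <- c("spectrum_id", SHIFT_COL, "intensity")
    if (!all(need %in% names(dt))) {
      stop_ramansalt("format", "long dialect requires columns ",
                     paste(need, collapse = ", "))
    }
    ids <- unique(dt$spectrum_id)
    ref <- dt[[SHIFT_COL]][dt$spectrum_id == ids[1]]
    if (any(diff(ref) <= 0)) {
      stop_ramansalt("axis", "shift axis is not strictly increasing")
    }
    mat <- matrix(NA_real_, nrow = length(ids), ncol = length(ref),
                  dimnames = list(as.character(ids), NULL))
    for (id in ids) {
      rows <- dt$spectrum_id == id
      ax <- dt[[SHIFT_COL]][rows]
      if (length(ax) != length(ref) || !identical(as.numeric(ax),
                                                  as.numeric(ref))) {
        stop_ramansalt("alignment", "spectrum '", id,
                       "' is on a different shift grid than '", ids[1], "'")
      }
      mat[as.character(id), ] <- dt$intensity[rows]
    }
    raman_set(ref, mat)
  }
}

#' Write a `raman_set` to a delimited text file
#'
#' Values are written at full float round-trip precision so that
#' `read_spectrum_table(write_spectrum_table(s))` reproduces `s` exactly.
#' A set with zero spectra writes a header-only wide file.
#'
#' @param set A valid `raman_set` (NA/NaN intensities are refused).
#' @param path Output path; `.csv` extension selects comma separation,
#'   anything else TAB.
#' @inheritParams read_spectrum_table
#' @export
write_spectrum_table <- function(set, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(set, "raman_set"))
  if (anyNA(set$intensities)) {
    stop_ramansalt("validation", "set contains NA/NaN intensities")
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (dialect == "wide") {
    df <- data.frame(shift = set$shift, check.names = FALSE)
    names(df) <- SHIFT_COL
    if (n_spectra(set) > 0) {
      m <- as.data.frame(t(set$intensities), check.names = FALSE)
      names(m) <- spectrum_ids(set)
      df <- cbind(df, m)
    }
    ok <- try(data.table::fwrite(df, path, sep = sep), silent = TRUE)
  } else {
    ids <- spectrum_ids(set)
    df <- data.frame(
      spectrum_id = rep(ids, each = length(set$shift)),
      shift = rep(set$shift, times = length(ids)),
      intensity = as.vector(t(set$intensities)),
      check.names = FALSE)
    names(df)[2] <- SHIFT_COL
    ok <- try(data.table::fwrite(df, path, sep = sep), silent = TRUE)
  }
  if (inherits(ok, "try-error")) {
    stop_ramansalt("io", "cannot write '", path, "'")
  }
  invisible(path)
}

#' Attach a sidecar metadata table to a spectrum set
#'
#' The metadata file must contain `spectrum_id`, `week` and
#' `concentration_mM` columns (`replicate`, `x_um`, `y_um` optional); every
#' spectrum must match exactly one row, and duplicate or missing ids are
#' errors naming the offending ids.
#'
#' @param set A `raman_set`.
#' @param meta_path Path to a delimited metadata table, or a data.frame.
#' @return The set with `$meta` populated, rows ordered as the spectra.
#' @export
attach_metadata <- function(set, meta_path) {
  meta <- if (is.data.frame(meta_path)) meta_path else {
    if (!file.exists(meta_path)) {
      stop_ramansalt("io", "metadata file not found: ", meta_path)
    }
    data.table::fread(meta_path, header = TRUE, check.names = FALSE,
                      data.table = FALSE)
  }
  need <- c("spectrum_id", "week", "concentration_mM")
  if (!all(need %in% names(meta))) {
    stop_ramansalt("metadata", "metadata requires columns ",
                   paste(need, collapse = ", "))
  }
  set_meta(set, meta)
}
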