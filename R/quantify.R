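# Quantitative bookkeeping: EIC peak areas, recovery percentages relative to
# a reference extraction, and per-dose detection/area tables across patients.

#' Trapezoidal area of an extracted-ion chromatogram
#'
#' @param rt strictly increasing retention-time grid (min).
#' @param intensity intensities on the grid (counts, >= 0).
#' @param window length-2 numeric integration window (min); defaults to the
#'   full grid. An empty overlap yields area 0 with a warning.
#' @return Area in counts*min.
#' @export
integrate_eic <- function(rt, intensity, window = range(rt)) {
  stopifnot(length(rt) == length(intensity), length(rt) >= 1,
            all(diff(rt) > 0), all(intensity >= 0), length(window) == 2)
  window <- sort(window)
  lo <- max(window[1], min(rt)); hi <- min(window[2], max(rt))
  if (lo >= hi) {
    warning("integration window does not overlap the retention-time grid")
    return(0)
  }
  inside <- rt > lo & rt < hi
  grid <- c(lo, rt[inside], hi)
  vals <- stats::approx(rt, intensity, xout = grid)$y
  sum(diff(grid) * (utils::head(vals, -1) + utils::tail(vals, -1)) / 2)
}

#' Recovery of a purification method relative to a reference extraction
#'
#' Recovery is the mean EIC area after the method under test as a percentage
#' of the mean reference area (e.g. areas after a two-step cleanup relative
#' to the plain liquid-liquid extract); dispersion is the sample standard
#' deviation of the method areas on the same reference scale, matching the
#' "91 +/- 2 %" reporting convention.
#'
#' @param area_method numeric vector of replicate areas for the method.
#' @param area_reference numeric vector of replicate reference areas; the
#'   reference mean must be positive.
#' @param method,ion optional labels carried into the record.
#' @return Data frame with one row: \code{method}, \code{ion},
#'   \code{recovery} (percent) and \code{dispersion} (percent; \code{NA}
#'   with a single replicate).
#' @export
recovery_percent <- function(area_method, area_reference, method = NA_character_,
                             ion = NA_real_) {
  ref <- mean(area_reference)
  if (!is.finite(ref) || ref <= 0) stop("reference mean area must be positive")
  data.frame(method = method, ion = ion,
             recovery = 100 * mean(area_method) / ref,
             dispersion = 100 * stats::sd(area_method) / ref,
             stringsAsFactors = FALSE)
}

.DOSE_LEVELS <- c("BID", "AID", "BIID", "AIID", "BIIID", "AIIID", "BIVD", "AIVD")

#' Dose-course area matrix
#'
#' Pivots long-format EIC area records (one row per sample, dose and ion)
#' into a matrix of areas keyed by ion and dose per sample, rendering
#' undetected cells as \code{"-"} and appending a before/after ratio column
#' for each dose number.
#'
#' @param records data frame with columns \code{sample}, \code{dose} (one of
#'   BID, AID, BIID, AIID, BIIID, AIIID, BIVD, AIVD: before/after the first
#'   to fourth dose), \code{mz} and \code{area} (\code{NA} = not measured);
#'   duplicate (sample, dose, mz) combinations are an error.
#' @param threshold detection threshold on area; any area strictly greater
#'   counts as detected. Default 0 (no limit of detection is invented).
#' @return List with \code{areas} (numeric matrix, rows = ions, columns =
#'   sample:dose), \code{detected} (logical matrix), \code{rendered}
#'   (character matrix with \code{"-"} for undetected) and \code{ratios}
#'   (after/before ratio matrix per sample and dose number, \code{NA} where
#'   either side is undetected).
#' @export
dose_course_table <- function(records, threshold = 0) {
  req <- c("sample", "dose", "mz", "area")
  stopifnot(all(req %in% names(records)))
  if (!all(records$dose %in% .DOSE_LEVELS))
    stop("unknown dose label(s): ",
         paste(setdiff(unique(records$dose), .DOSE_LEVELS), collapse = ", "))
  key <- paste(records$sample, records$dose, records$mz, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate (sample, dose, mz) records: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  ions <- sort(unique(records$mz))
  cols <- unique(records$sample)
  cols <- as.vector(outer(.DOSE_LEVELS, cols,
                          function(d, s) paste(s, d, sep = ":")))
  cols <- cols[cols %in% paste(records$sample, records$dose, sep = ":")]
  areas <- matrix(NA_real_, nrow = length(ions), ncol = length(cols),
                  dimnames = list(as.character(ions), cols))
  for (i in seq_len(nrow(records))) {
    cn <- paste(records$sample[i], records$dose[i], sep = ":")
    areas[as.character(records$mz[i]), cn] <- records$area[i]
  }
  detected <- !is.na(areas) & areas > threshold
  rendered <- ifelse(detected, formatC(areas, format = "fg", big.mark = ""), "-")
  pairs <- matrix(.DOSE_LEVELS, nrow = 2)  # before/after per dose number
  samples <- unique(records$sample)
  ratio_cols <- as.vector(outer(paste0("dose", 1:4), samples,
                                function(d, s) paste(s, d, sep = ":")))
  ratios <- matrix(NA_real_, nrow = length(ions), ncol = length(ratio_cols),
                   dimnames = list(as.character(ions), ratio_cols))
  for (s in samples) for (d in 1:4) {
    before <- paste(s, pairs[1, d], sep = ":")
    after <- paste(s, pairs[2, d], sep = ":")
    if (before %in% colnames(areas) && after %in% colnames(areas)) {
      ok <- detected[, before] & detected[, after]
      ratios[ok, paste(s, paste0("dose", d), sep = ":")] <-
        areas[ok, after] / areas[ok, before]
    }
  }
  list(areas = areas, detected = detected, rendered = rendered, ratios = ratios)
}

#' Parse a rendered dose-course matrix back to records
#'
#' Inverse of the \code{rendered} element of \code{\link{dose_course_table}}:
#' \code{"-"} cells become undetected (\code{NA} area) records.
#'
#' @param rendered character matrix with rownames = ions and colnames =
#'   \code{"sample:dose"}.
#' @return Long-format data frame with columns \code{sample}, \code{dose},
#'   \code{mz}, \code{area}.
#' @export
parse_dose_course <- function(rendered) {
  out <- do.call(rbind, lapply(colnames(rendered), function(cn) {
    parts <- strsplit(cn, ":", fixed = TRUE)[[1]]
    data.frame(sample = parts[1], dose = parts[2],
               mz = as.numeric(rownames(rendered)),
               area = suppressWarnings(
                 ifelse(rendered[, cn] == "-", NA_real_,
                        as.numeric(rendered[, cn]))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
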