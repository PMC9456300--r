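# File I/O and bundled reference data: CSV peak lists in, TSV tables out,
# plus accessors for the packaged serum reference tables.

#' Read a centroided peak list from CSV
#'
#' Expects a header \code{mz,z,rt,intensity}, one ion per row. A blank
#' charge is treated as 1 and flagged in the \code{unknown_charge} column
#' (charge can then be re-determined from an isotope envelope with
#' \code{\link{charge_from_spacing}} when envelope data are available).
#'
#' @param path CSV file path.
#' @return Data frame with columns \code{mz}, \code{z}, \code{rt},
#'   \code{intensity}, \code{unknown_charge} and \code{line} (source line
#'   number for diagnostics).
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) stop("peak list not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("mz", "z", "rt", "intensity")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0)
    stop("peak list ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(raw)
  line <- seq_len(n) + 1L  # header is line 1
  num <- function(col, allow_blank = FALSE) {
    v <- trimws(raw[[col]])
    blank <- v == "" | is.na(v)
    x <- suppressWarnings(as.numeric(v))
    bad <- !blank & is.na(x)
    if (any(bad))
      stop("non-numeric ", col, " in ", path, ":", line[which(bad)[1]])
    list(x = x, blank = blank)
  }
  mz <- num("mz"); z <- num("z", allow_blank = TRUE)
  rt <- num("rt"); inten <- num("intensity")
  for (chk in list(list(v = mz, col = "mz", pos = TRUE),
                   list(v = rt, col = "rt", pos = FALSE),
                   list(v = inten, col = "intensity", pos = FALSE))) {
    if (any(chk$v$blank))
      stop("blank ", chk$col, " in ", path, ":", line[which(chk$v$blank)[1]])
    bad <- if (chk$pos) chk$v$x <= 0 else chk$v$x < 0
    if (any(bad))
      stop("negative or zero ", chk$col, " in ", path, ":",
           line[which(bad)[1]])
  }
  zx <- abs(z$x)
  zx[z$blank] <- 1L
  if (any(!z$blank & !zx %in% 1:4))
    stop("charge outside 1..4 in ", path, ":", line[which(!z$blank & !zx %in% 1:4)[1]])
  data.frame(mz = mz$x, z = as.integer(zx), rt = rt$x, intensity = inten$x,
             unknown_charge = z$blank, line = line)
}

#' Write a table as TSV with a configuration header block
#'
#' @param x data frame (e.g. an \code{assignment_table}).
#' @param path output path; overwritten if present.
#' @param config optional \code{identify_config} echoed as \code{#}-prefixed
#'   header lines.
#' @export
write_output_table <- function(x, path, config = attr(x, "config")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    for (nm in names(config))
      writeLines(sprintf("# %s: %s", nm,
                         paste(format(config[[nm]]), collapse = ",")), con)
  }
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by \code{\link{write_output_table}}
#'
#' @param path file path.
#' @return Data frame; header lines are skipped and returned in the
#'   \code{header} attribute.
#' @export
read_output_table <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  out <- utils::read.delim(text = paste(lines[!hdr], collapse = "\n"),
                           stringsAsFactors = FALSE)
  attr(out, "header") <- lines[hdr]
  out
}

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "nusimet")
  if (path == "") {
    # during in-source development (pkgload) inst/ is on the search path root
    path <- file.path("inst", "extdata", name)
  }
  if (!file.exists(path)) stop("bundled data file not found: ", name)
  path
}

#' Bundled serum reference ion list
#'
#' The published full-scan ions observed for nusinersen metabolites in a
#' patient serum extract: m/z, charge state and retention time for 30 ions
#' over 17 species (13 -1/-2 ion pairs and 4 single-charge-state species).
#' Intensities are not published; all are set to 1.
#'
#' @return Peak-list data frame (\code{mz}, \code{z}, \code{rt},
#'   \code{intensity}) plus \code{row_id} linking ions of one species to
#'   \code{\link{reference_metabolites}}.
#' @export
reference_ions <- function() {
  utils::read.csv(.extdata("serum_reference_ions.csv"),
                  stringsAsFactors = FALSE)
}

#' Bundled serum reference metabolite annotations
#'
#' Per-species published annotations: retention time, deconvoluted and
#' predicted masses, the reported sequence string(s) and shortmer label(s),
#' identification flag and transcription notes (several printed values are
#' internally inconsistent and are preserved verbatim with a note rather
#' than corrected).
#'
#' @return Data frame keyed by \code{row_id}.
#' @export
reference_metabolites <- function() {
  utils::read.csv(.extdata("serum_reference_metabolites.csv"),
                  stringsAsFactors = FALSE)
}

#' Bundled extraction-recovery reference table
#'
#' Published recovery percentages (mean +/- sd) of five selected metabolite
#' ions for two-step cleanup methods relative to the liquid-liquid extract:
#' solid-phase extraction, microextraction by packed sorbent with two
#' adsorbents, and magnetic nanoparticles.
#'
#' @return Long-format data frame: \code{ion}, \code{label}, \code{method},
#'   \code{recovery}, \code{sd}.
#' @export
reference_recovery <- function() {
  utils::read.csv(.extdata("extraction_recovery.csv"),
                  stringsAsFactors = FALSE)
}

#' Bundled dose-course EIC area table
#'
#' Published EIC peak areas per metabolite ion for two patients across the
#' loading doses (before/after first to fourth dose); undetected cells are
#' \code{NA}. One printed cell (ion 1307.52, P1 after third dose, area
#' 5,416) is anomalous against its neighbours and is preserved verbatim.
#'
#' @return Long-format data frame: \code{mz}, \code{metabolite},
#'   \code{sample}, \code{dose}, \code{area}.
#' @export
reference_dose_course <- function() {
  utils::read.csv(.extdata("dose_course_areas.csv"),
                  stringsAsFactors = FALSE)
}
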