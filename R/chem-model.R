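# Elemental chemistry of 2'-O-methoxyethyl phosphorothioate oligonucleotides:
# isotope data, molecular formulas, residue registry, sequence parsing and
# monoisotopic / average / nominal mass computation.

#' Isotope table for the elements of modified oligonucleotides
#'
#' Isotopic masses and abundances for H, C, N, O, P and S, the only elements
#' occurring in 2'-O-methoxyethyl (MOE) phosphorothioate oligonucleotides and
#' their exonuclease / base-loss metabolites. Values are from the IUPAC/CIAAW
#' standard atomic-data compilation (2013 isotopic compositions, masses from
#' AME2012), stored per element as a data frame with columns \code{mass}
#' (Da, strictly increasing) and \code{abundance} (fractions summing to 1).
#'
#' @format A named list of data frames, one per element symbol.
#' @export
isotope_table <- list(
  H = data.frame(mass = c(1.0078250319, 2.0141017780),
                 abundance = c(0.999885, 0.000115)),
  C = data.frame(mass = c(12.0000000, 13.0033548378),
                 abundance = c(0.9893, 0.0107)),
  N = data.frame(mass = c(14.0030740052, 15.0001088984),
                 abundance = c(0.99636, 0.00364)),
  O = data.frame(mass = c(15.9949146221, 16.9991315000, 17.9991604000),
                 abundance = c(0.99757, 0.00038, 0.00205)),
  P = data.frame(mass = 30.97376151, abundance = 1.0),
  S = data.frame(mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
                 abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

#' Mass of a proton in Da
#'
#' Used for proton restoration when deconvoluting negative-mode ions
#' (each charge corresponds to the loss of one proton).
#' @export
PROTON_MASS <- 1.007276

# MOE sugar substitution relative to ribose: -O-CH2CH2-O-CH3 replaces 2'-OH,
# a net +C3H6O. Held in one constant so the sugar chemistry is configurable.
MOE_DELTA <- c(C = 3, H = 6, O = 1)

.ELEMENTS <- c("C", "H", "N", "O", "P", "S")

#' Construct a molecular formula
#'
#' A formula is a named integer vector over the elements H, C, N, O, P, S.
#' Addition and subtraction are element-wise; intermediate results may carry
#' negative counts but any formula describing a real species must not.
#'
#' @param ... named integer atom counts, e.g. \code{formula(C = 5, H = 5, N = 5)}.
#' @return Named integer vector of atom counts over all six elements.
#' @examples
#' adenine <- formula(C = 5, H = 5, N = 5)
#' @export
formula <- function(...) {
  x <- c(...)
  if (length(x) == 0) return(stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS))
  if (is.null(names(x)) || any(names(x) == ""))
    stop("all atom counts must be named by element symbol")
  bad <- setdiff(names(x), .ELEMENTS)
  if (length(bad) > 0)
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  out <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  out[names(x)] <- out[names(x)] + as.integer(round(x))
  out
}

#' @rdname formula
#' @param f1,f2 formulas as returned by \code{formula()}.
#' @export
formula_add <- function(f1, f2) {
  f1 <- formula_canon(f1); f2 <- formula_canon(f2)
  f1 + f2
}

#' @rdname formula
#' @export
formula_diff <- function(f1, f2) {
  f1 <- formula_canon(f1); f2 <- formula_canon(f2)
  f1 - f2
}

# coerce any named count vector onto the fixed element order
formula_canon <- function(f) {
  out <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  if (length(f) > 0) {
    if (is.null(names(f)) || any(names(f) == ""))
      stop("formula must be a named count vector")
    bad <- setdiff(names(f), .ELEMENTS)
    if (length(bad) > 0) stop("unknown element(s): ", paste(bad, collapse = ", "))
    out[names(f)] <- out[names(f)] + as.integer(round(f))
  }
  out
}

#' Render a formula as a Hill-order string
#'
#' Carbon first, hydrogen second, remaining elements alphabetically; elements
#' with a zero count are omitted, a count of one is printed without a digit.
#'
#' @param f formula.
#' @return A string such as \code{"C26H38N10O15P2S2"}; \code{""} for the
#'   empty formula.
#' @export
formula_string <- function(f) {
  f <- formula_canon(f)
  ord <- c("C", "H", sort(setdiff(.ELEMENTS, c("C", "H"))))
  parts <- vapply(ord, function(el) {
    n <- f[[el]]
    if (n == 0) "" else if (n == 1) el else paste0(el, n)
  }, character(1))
  paste0(parts, collapse = "")
}

#' Parse a Hill-order formula string
#'
#' @param s string such as \code{"C13H19N5O6"}.
#' @return formula vector.
#' @export
formula_parse <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  if (nchar(s) == 0) return(formula())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (sum(nchar(toks)) != nchar(s)) stop("cannot parse formula string: ", s)
  out <- formula()
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nchar(n) == 0) 1L else as.integer(n)
    if (!el %in% .ELEMENTS) stop("unknown element(s): ", el)
    out[[el]] <- out[[el]] + n
  }
  out
}

#' Residue registry for nusinersen-type oligonucleotides
#'
#' The four residues occurring in nusinersen: 5-methyluridine (\code{mU}),
#' 5-methylcytidine (\code{mC}), adenosine (\code{A}) and guanosine
#' (\code{G}), each carrying the 2'-O-methoxyethyl ribose. For every code the
#' registry stores the free nucleobase formula and the nucleoside formula
#' (base + MOE-ribose - H2O for the glycosidic bond).
#'
#' @format Named list; per residue a list with elements \code{base} and
#'   \code{nucleoside}, both formulas.
#' @export
residue_registry <- local({
  moe_ribose <- formula(C = 8, H = 16, O = 6)   # ribofuranose C5H10O5 + C3H6O
  water <- formula(H = 2, O = 1)
  mk <- function(base) {
    list(base = base,
         nucleoside = formula_add(base, moe_ribose) - water)
  }
  list(
    mU = mk(formula(C = 5, H = 6, N = 2, O = 2)),  # 5-methyluracil (thymine)
    mC = mk(formula(C = 5, H = 7, N = 3, O = 1)),  # 5-methylcytosine
    A  = mk(formula(C = 5, H = 5, N = 5)),         # adenine
    G  = mk(formula(C = 5, H = 5, N = 5, O = 1))   # guanine
  )
})

#' Construct a modified oligonucleotide
#'
#' @param residues character vector of residue codes (\code{mU}, \code{mC},
#'   \code{A}, \code{G}), stored left to right in the printed order.
#' @param linkages character vector of length \code{length(residues) - 1};
#'   each \code{"phosphorothioate"} or \code{"phosphodiester"}.
#' @param terminals character vector of length 2 (left end, right end), each
#'   \code{"hydroxyl"} or \code{"thiophosphate"}.
#' @param end_labels optional character vector of length 2 preserving any
#'   end annotations of the source string (e.g. \code{c("3'", "5'")}); kept
#'   as metadata only, no directional chemistry is attached to it.
#' @return An object of class \code{modified_oligo}.
#' @export
modified_oligo <- function(residues,
                           linkages = rep("phosphorothioate",
                                          max(length(residues) - 1L, 0L)),
                           terminals = c("hydroxyl", "hydroxyl"),
                           end_labels = NULL) {
  residues <- as.character(residues)
  if (length(residues) < 1) stop("an oligonucleotide needs at least one residue")
  bad <- setdiff(residues, names(residue_registry))
  if (length(bad) > 0)
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  if (length(linkages) != length(residues) - 1L)
    stop("need exactly ", length(residues) - 1L, " linkages, got ", length(linkages))
  stopifnot(all(linkages %in% c("phosphorothioate", "phosphodiester")),
            length(terminals) == 2,
            all(terminals %in% c("hydroxyl", "thiophosphate")))
  structure(list(residues = residues, linkages = as.character(linkages),
                 terminals = as.character(terminals), end_labels = end_labels),
            class = "modified_oligo")
}

#' @export
print.modified_oligo <- function(x, ...) {
  cat("<modified_oligo> ", length(x$residues), "-mer: ",
      oligo_to_string(x), "\n", sep = "")
  invisible(x)
}

#' @export
length.modified_oligo <- function(x) length(x$residues)

#' Parse a printed oligonucleotide sequence
#'
#' Accepts hyphen-separated residue tokens with optional end labels at both
#' ends (e.g. \code{"3'-mU-mC-A-...-G-5'"}). Residues are kept in the printed
#' left-to-right order; the end labels are preserved verbatim as metadata.
#' All linkages default to phosphorothioate and both termini to hydroxyl.
#'
#' @param text sequence string.
#' @return A \code{modified_oligo}.
#' @export
parse_sequence <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  toks <- strsplit(trimws(text), "-", fixed = TRUE)[[1]]
  toks <- trimws(toks)
  if (length(toks) == 0 || all(nchar(toks) == 0))
    stop("empty sequence string")
  is_end <- grepl("^[35][′']?$", toks)
  end_labels <- NULL
  if (any(is_end)) {
    if (!(is_end[1] && is_end[length(toks)] && sum(is_end) == 2))
      stop("end labels must appear at both ends of the sequence, or not at all")
    end_labels <- toks[c(1, length(toks))]
    toks <- toks[-c(1, length(toks))]
  }
  if (length(toks) == 0) stop("sequence contains no residues")
  known <- toks %in% names(residue_registry)
  if (!all(known)) {
    i <- which(!known)[1]
    stop("unknown residue token '", toks[i], "' at position ", i)
  }
  modified_oligo(toks, end_labels = end_labels)
}

#' Serialize an oligonucleotide back to its sequence string
#'
#' Inverse of \code{\link{parse_sequence}}: re-emits the hyphen-separated
#' residue tokens (and the preserved end labels, if any).
#'
#' @param oligo a \code{modified_oligo}.
#' @return Sequence string.
#' @export
oligo_to_string <- function(oligo) {
  stopifnot(inherits(oligo, "modified_oligo"))
  toks <- oligo$residues
  if (!is.null(oligo$end_labels))
    toks <- c(oligo$end_labels[1], toks, oligo$end_labels[2])
  paste(toks, collapse = "-")
}

#' The nusinersen (Spinraza) 18-mer
#'
#' Full-length nusinersen as printed: 18 MOE residues, all 17 internucleotide
#' linkages phosphorothioate, free hydroxyl termini (the neutral free acid is
#' modeled; the drug substance is a sodium salt). The left end is labeled 3'
#' in the source notation; the label is metadata only and no composition or
#' mass result depends on orientation.
#'
#' @export
NUSINERSEN <- parse_sequence(
  "3'-mU-mC-A-mC-mU-mU-mU-mC-A-mU-A-A-mU-G-mC-mU-G-G-5'"
)

# net composition deltas for internucleotide bridges and terminal groups
.LINKAGE_DELTA <- list(
  phosphorothioate = c(H = -1, O = 1, P = 1, S = 1),  # H3PO3S - 2 H2O
  phosphodiester   = c(H = -1, O = 2, P = 1)          # H3PO4  - 2 H2O
)
.TERMINAL_DELTA <- list(
  hydroxyl      = c(H = 0),
  thiophosphate = c(H = 1, O = 2, P = 1, S = 1)       # H3PO3S - H2O
)

#' Elemental formula of a modified oligonucleotide
#'
#' Sums the nucleoside formulas over all residues, then applies the net
#' contribution of every internucleotide bridge (phosphorothioate: +P +S +O
#' -H; phosphodiester: +P +2O -H) and of each terminal group (thiophosphate:
#' +H +P +2O +S; hydroxyl: nothing). Optional abasic positions replace the
#' residue's nucleoside by the abasic MOE-ribose (nucleoside - base + H2O).
#'
#' @param oligo a \code{modified_oligo}.
#' @param abasic integer positions (1-based, within the oligo) whose
#'   nucleobase has been hydrolytically lost.
#' @return formula vector; all counts are non-negative.
#' @export
oligo_formula <- function(oligo, abasic = integer(0)) {
  stopifnot(inherits(oligo, "modified_oligo"))
  n <- length(oligo$residues)
  abasic <- as.integer(abasic)
  if (length(abasic) > 0 &&
      (any(abasic < 1) || any(abasic > n) || anyDuplicated(abasic)))
    stop("abasic positions must be distinct indices into the oligo")
  water <- formula(H = 2, O = 1)
  f <- formula()
  for (i in seq_len(n)) {
    r <- residue_registry[[oligo$residues[i]]]
    nuc <- r$nucleoside
    if (i %in% abasic) nuc <- formula_add(nuc - r$base, water)
    f <- f + nuc
  }
  for (lk in oligo$linkages) f <- f + formula_canon(.LINKAGE_DELTA[[lk]])
  for (tg in oligo$terminals) f <- f + formula_canon(.TERMINAL_DELTA[[tg]])
  if (any(f < 0)) stop("negative atom count in final formula")
  f
}

#' Mass of a molecular formula
#'
#' @param f formula.
#' @param kind one of \code{"monoisotopic"} (sum over atoms of the most
#'   abundant isotope's mass), \code{"average"} (abundance-weighted mean
#'   isotope mass) or \code{"nominal"} (integer mass number of the most
#'   abundant isotope).
#' @return Mass in Da; \code{0} for the empty formula.
#' @export
formula_mass <- function(f, kind = c("monoisotopic", "average", "nominal")) {
  kind <- match.arg(kind)
  f <- formula_canon(f)
  if (any(f < 0)) stop("formula has negative atom counts")
  total <- 0
  for (el in names(f)) {
    n <- f[[el]]
    if (n == 0) next
    if (!el %in% names(isotope_table)) stop("element absent from isotope table: ", el)
    iso <- isotope_table[[el]]
    top <- which.max(iso$abundance)
    m <- switch(kind,
      monoisotopic = iso$mass[top],
      average = sum(iso$mass * iso$abundance),
      nominal = round(iso$mass[top]))
    total <- total + n * m
  }
  total
}

#' Round half away from zero
#'
#' Reporting convention for masses in tables: two decimals, ties rounded away
#' from zero (base \code{round()} rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so decimal halves stored just below .5
  # in binary (e.g. 1.005) still round away from zero
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
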