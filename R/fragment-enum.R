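# Enumeration of the exonuclease / base-loss candidate space: contiguous
# truncation products of a parent oligo, terminal-chemistry variants and
# depurination / depyrimidination (abasic) variants, with canonical labels.

#' Canonical truncation label
#'
#' A truncation is described by \code{a} residues removed from the left
#' (printed-3') end and \code{b} from the right (printed-5') end. Rendering
#' follows the field's shortmer notation: single-end truncations render as
#' \code{"3'N-b"} / \code{"5'N-a"}, both-end products as
#' \code{"5'N-a+3'N-b"}, the intact molecule as \code{"intact"}. The label
#' direction is a fixed convention of this package (the left printed end is
#' taken as the 3' end); explicit spans are always reported alongside, so no
#' information depends on the convention.
#'
#' @param a residues removed from the left end (>= 0).
#' @param b residues removed from the right end (>= 0).
#' @return Label string.
#' @export
truncation_label <- function(a, b) {
  stopifnot(a >= 0, b >= 0)
  if (a == 0 && b == 0) return("intact")
  if (a == 0) return(paste0("3'N-", b))
  if (b == 0) return(paste0("5'N-", a))
  paste0("5'N-", a, "+3'N-", b)
}

# sequence string in the published dialect: residues joined by "*" for
# phosphorothioate bridges, abasic positions rendered "MoeR", a leading /
# trailing "*" marking a terminal thiophosphate.
fragment_seq_string <- function(residues, terminals, abasic_rel = integer(0)) {
  toks <- residues
  toks[abasic_rel] <- "MoeR"
  s <- paste(toks, collapse = "*")
  if (terminals[1] == "thiophosphate") s <- paste0("*", s)
  if (terminals[2] == "thiophosphate") s <- paste0(s, "*")
  s
}

.candidate_row <- function(parent, start, end, terminals, abasic_abs) {
  n <- length(parent$residues)
  res <- parent$residues[start:end]
  sub <- modified_oligo(res, terminals = terminals)
  abasic_rel <- as.integer(abasic_abs - start + 1L)
  f <- oligo_formula(sub, abasic = abasic_rel)
  data.frame(
    start = start, end = end, length = end - start + 1L,
    a = start - 1L, b = n - end,
    label = truncation_label(start - 1L, n - end),
    term_left = terminals[1], term_right = terminals[2],
    losses = paste(abasic_abs, collapse = ";"),
    n_losses = length(abasic_abs),
    sequence = fragment_seq_string(res, terminals, abasic_rel),
    formula = formula_string(f),
    monoisotopic = formula_mass(f, "monoisotopic"),
    average = formula_mass(f, "average"),
    nominal = formula_mass(f, "nominal"),
    stringsAsFactors = FALSE
  )
}

#' Enumerate contiguous truncation products
#'
#' Generates exactly one candidate per contiguous span of the parent with
#' length in \code{[min_len, max_len]}; all candidates carry hydroxyl
#' termini and no base losses. Spans are 1-based inclusive \code{[start,
#' end]} into the printed residue order.
#'
#' @param parent a \code{modified_oligo}.
#' @param min_len,max_len span length bounds, \code{1 <= min_len <= max_len
#'   <= length(parent)}.
#' @param include_full keep the full-length span?
#' @return Candidate data frame with columns \code{start, end, length, a, b,
#'   label, term_left, term_right, losses, n_losses, sequence, formula,
#'   monoisotopic, average, nominal}.
#' @export
enumerate_truncations <- function(parent, min_len = 1L,
                                  max_len = length(parent$residues),
                                  include_full = FALSE) {
  stopifnot(inherits(parent, "modified_oligo"))
  n <- length(parent$residues)
  if (!(min_len >= 1 && min_len <= max_len && max_len <= n))
    stop("need 1 <= min_len <= max_len <= ", n)
  rows <- list()
  for (L in min_len:max_len) {
    for (start in seq_len(n - L + 1L)) {
      end <- start + L - 1L
      if (!include_full && L == n) next
      rows[[length(rows) + 1L]] <-
        .candidate_row(parent, start, end, c("hydroxyl", "hydroxyl"), integer(0))
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- .candidate_row(parent, 1L, 1L, c("hydroxyl","hydroxyl"),
                                          integer(0))[0, ]
  attr(out, "parent") <- parent
  out
}

#' Expand candidates over a terminal-group policy
#'
#' Each candidate is replicated once per allowed (left, right) terminal
#' combination, with formulas and masses recomputed. The published sequence
#' strings of observed metabolites show thiophosphate groups at either end,
#' neither, or both, so the default policy admits all four combinations.
#'
#' @param candidates candidate data frame (see
#'   \code{\link{enumerate_truncations}}).
#' @param policy data frame with character columns \code{left} and
#'   \code{right}, one row per allowed combination; or the string
#'   \code{"all"} for the full cartesian set.
#' @return Expanded candidate data frame; no duplicate
#'   (span, losses, terminals) rows.
#' @export
apply_terminal_policy <- function(candidates, policy = "all") {
  parent <- attr(candidates, "parent")
  if (identical(policy, "all"))
    policy <- expand.grid(left = c("hydroxyl", "thiophosphate"),
                          right = c("hydroxyl", "thiophosphate"),
                          stringsAsFactors = FALSE)
  if (nrow(policy) == 0) stop("terminal policy must be non-empty")
  stopifnot(all(unlist(policy) %in% c("hydroxyl", "thiophosphate")))
  if (anyDuplicated(policy)) stop("duplicate terminal combinations in policy")
  rows <- vector("list", nrow(candidates) * nrow(policy))
  k <- 0L
  for (i in seq_len(nrow(candidates))) {
    losses <- .parse_losses(candidates$losses[i])
    for (p in seq_len(nrow(policy))) {
      k <- k + 1L
      rows[[k]] <- .candidate_row(parent, candidates$start[i], candidates$end[i],
                                  c(policy$left[p], policy$right[p]), losses)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "parent") <- parent
  out
}

.parse_losses <- function(s) {
  if (is.na(s) || s == "") integer(0) else as.integer(strsplit(s, ";")[[1]])
}

#' Expand candidates with nucleobase losses
#'
#' For every candidate, emits all variants with up to \code{max_losses}
#' depurination / depyrimidination events: each lost base leaves an abasic
#' MOE-ribose (formula of the residue minus its nucleobase plus water).
#' Candidates identical in elemental formula are retained (they differ in
#' which position lost its base); use \code{\link{formula_groups}} to view
#' isobaric groups.
#'
#' @param candidates candidate data frame.
#' @param max_losses maximum number of lost bases per candidate (>= 0).
#' @return Expanded candidate data frame including the loss-free originals.
#' @export
enumerate_base_losses <- function(candidates, max_losses = 1L) {
  stopifnot(max_losses >= 0)
  parent <- attr(candidates, "parent")
  if (max_losses == 0) return(candidates)
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    span <- candidates$start[i]:candidates$end[i]
    terminals <- c(candidates$term_left[i], candidates$term_right[i])
    base_losses <- .parse_losses(candidates$losses[i])
    for (k in 0:min(max_losses, length(span))) {
      combos <- if (k == 0) list(integer(0)) else {
        cm <- utils::combn(span, k)
        lapply(seq_len(ncol(cm)), function(j) cm[, j])
      }
      for (extra in combos) {
        abasic <- sort(unique(c(base_losses, as.integer(extra))))
        if (length(abasic) != length(base_losses) + k) next  # overlap: skip
        rows[[length(rows) + 1L]] <-
          .candidate_row(parent, candidates$start[i], candidates$end[i],
                         terminals, abasic)
      }
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[!duplicated(out[, c("start", "end", "term_left", "term_right", "losses")]), ]
  rownames(out) <- NULL
  attr(out, "parent") <- parent
  out
}

#' Group candidates by elemental formula
#'
#' Isobaric candidates (identical formula, hence identical mass) cannot be
#' told apart by mass alone; this view partitions a candidate table into
#' formula groups for ambiguity reporting.
#'
#' @param candidates candidate data frame.
#' @return Data frame with one row per distinct formula: \code{formula},
#'   \code{monoisotopic}, \code{n_candidates}, and \code{members}
#'   (semicolon-separated candidate sequence strings).
#' @export
formula_groups <- function(candidates) {
  if (nrow(candidates) == 0)
    return(data.frame(formula = character(0), monoisotopic = numeric(0),
                      n_candidates = integer(0), members = character(0),
                      stringsAsFactors = FALSE))
  sp <- split(candidates, candidates$formula)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(formula = g$formula[1], monoisotopic = g$monoisotopic[1],
               n_candidates = nrow(g),
               members = paste(g$sequence, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$monoisotopic), ]
}

#' Count contiguous windows with a given residue composition
#'
#' Counts the windows of length \code{length(composition)} in the parent
#' whose residue multiset equals the given composition, irrespective of
#' order within the window (a window read in either direction counts once).
#' Used to quantify how ambiguous a short metabolite sequence is within the
#' full-length drug: e.g. the mU-mC dinucleotide occurs in four places in
#' nusinersen while G-G occurs only once.
#'
#' @param parent a \code{modified_oligo}.
#' @param composition character vector (multiset) of residue codes, length
#'   >= 2.
#' @return Integer count (0 if the composition is longer than the parent).
#' @export
count_adjacent_runs <- function(parent, composition) {
  stopifnot(inherits(parent, "modified_oligo"), length(composition) >= 2)
  n <- length(parent$residues)
  w <- length(composition)
  if (w > n) return(0L)
  key <- paste(sort(composition), collapse = "|")
  hits <- 0L
  for (start in seq_len(n - w + 1L)) {
    win <- parent$residues[start:(start + w - 1L)]
    if (paste(sort(win), collapse = "|") == key) hits <- hits + 1L
  }
  hits
}

#' Default metabolite candidate space for nusinersen
#'
#' The observed serum metabolites of nusinersen are 2- to 4-mer shortmers,
#' with either terminal chemistry and at most one base loss; this helper
#' builds that space (a few hundred candidates) in one call.
#'
#' @param parent parent oligo, default \code{\link{NUSINERSEN}}.
#' @param min_len,max_len span length range, default 2-4.
#' @param policy terminal policy, default all four combinations.
#' @param max_losses maximum base losses, default 1.
#' @return Candidate data frame.
#' @export
default_candidate_space <- function(parent = NUSINERSEN, min_len = 2L,
                                    max_len = 4L, policy = "all",
                                    max_losses = 1L) {
  x <- enumerate_truncations(parent, min_len, max_len)
  x <- apply_terminal_policy(x, policy)
  enumerate_base_losses(x, max_losses)
}

#' Write a candidate table as TSV
#'
#' @param candidates candidate data frame.
#' @param path output path.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
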