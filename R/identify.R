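# Pipeline driver: match deconvolved species against the enumerated
# candidate space, report isobaric ambiguity, confirm by co-elution, and
# summarize the resulting assignment table.

#' Configuration for an identification run
#'
#' @param mass_tol ion-pairing mass tolerance (Da): maximum spread of the
#'   per-ion neutral-mass estimates within one species.
#' @param rt_tol co-elution tolerance (min).
#' @param match_tol candidate-matching tolerance (Da). The default is
#'   deliberately loose (2.5 Da) to cover the scatter between measured and
#'   predicted shortmer masses seen in serum data; tighten towards ppm scale
#'   for well-calibrated instruments.
#' @param kind mass kind used for matching, \code{"monoisotopic"} (default)
#'   or \code{"average"}; deltas for both are always reported.
#' @param min_len,max_len,policy,max_losses candidate-space parameters, see
#'   \code{\link{default_candidate_space}}.
#' @param seed integer seed recorded with the run (identification itself is
#'   deterministic; the seed matters when the config drives synthesis).
#' @return A list of class \code{identify_config}.
#' @export
identify_config <- function(mass_tol = 0.2, rt_tol = 0.1, match_tol = 2.5,
                            kind = c("monoisotopic", "average"),
                            min_len = 2L, max_len = 4L, policy = "all",
                            max_losses = 1L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(mass_tol > 0, rt_tol > 0, match_tol > 0,
            min_len >= 1, min_len <= max_len, max_losses >= 0)
  structure(list(mass_tol = mass_tol, rt_tol = rt_tol, match_tol = match_tol,
                 kind = kind, min_len = as.integer(min_len),
                 max_len = as.integer(max_len), policy = policy,
                 max_losses = as.integer(max_losses), seed = as.integer(seed)),
            class = "identify_config")
}

#' Match one deconvolved species against a candidate table
#'
#' Candidates whose mass (of the configured kind) lies within \code{tol} of
#' the species mass are retained, sorted by absolute mass error then by span
#' start. The status is \code{"identified"} for a single isobaric formula
#' group, \code{"ambiguous"} for two or more groups (all alternatives are
#' listed, never resolved), and \code{"unidentified"} for no match.
#'
#' @param mass species neutral mass (Da).
#' @param candidates candidate data frame.
#' @param tol match tolerance (Da).
#' @param kind \code{"monoisotopic"} or \code{"average"}.
#' @return List with \code{matches} (candidate rows plus \code{dm},
#'   \code{dm_avg}) and \code{status}.
#' @export
match_candidates <- function(mass, candidates, tol = 2.5,
                             kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  stopifnot(tol > 0)
  dm <- candidates[[kind]] - mass
  hit <- which(abs(dm) <= tol)
  m <- candidates[hit, , drop = FALSE]
  m$dm <- m[[kind]] - mass
  m$dm_avg <- m$average - mass
  m <- m[order(abs(m$dm), m$start), , drop = FALSE]
  rownames(m) <- NULL
  status <- if (nrow(m) == 0) "unidentified"
            else if (length(unique(m$formula)) >= 2) "ambiguous"
            else "identified"
  list(matches = m, status = status)
}

#' Co-elution confirmation for a species
#'
#' A species is confirmed when at least two supporting ions elute together
#' (all pairwise retention-time differences within \code{rt_tol}).
#'
#' @param rts retention times of the supporting ions (min).
#' @param rt_tol tolerance (min).
#' @return \code{TRUE} if confirmed, \code{FALSE} otherwise (including the
#'   single-ion case).
#' @export
coelution_confirm <- function(rts, rt_tol = 0.1) {
  if (length(rts) < 2) return(FALSE)
  max(rts) - min(rts) <= rt_tol
}

#' Run the full identification pipeline on a peak list
#'
#' Deterministic composition of ion pairing, candidate matching and
#' co-elution confirmation over the configured candidate space. Species
#' supported by a single ion keep their candidate list but are flagged
#' \code{"unconfirmed"}.
#'
#' @param peaklist data frame of ions (\code{mz}, \code{z}, \code{rt},
#'   \code{intensity}), e.g. from \code{\link{read_peaklist}}.
#' @param config an \code{\link{identify_config}}.
#' @param candidates optional pre-built candidate table (skips rebuilding
#'   the space from the config).
#' @return Object of class \code{assignment_table}: a data frame ordered by
#'   consensus retention time with columns \code{species}, \code{rt},
#'   \code{mass}, \code{n_ions}, \code{ions}, \code{charges},
#'   \code{confirmed}, \code{status}, \code{n_candidates},
#'   \code{n_formula_groups}, \code{best_sequence}, \code{best_label},
#'   \code{best_dm}, \code{candidates}; attributes \code{config} (the run
#'   configuration snapshot) and \code{matches} (per-species candidate
#'   tables, in row order).
#' @export
run_identification <- function(peaklist, config = identify_config(),
                               candidates = NULL) {
  stopifnot(inherits(config, "identify_config"))
  if (is.null(candidates))
    candidates <- default_candidate_space(NUSINERSEN, config$min_len,
                                          config$max_len, config$policy,
                                          config$max_losses)
  dec <- pair_ions(peaklist, config$mass_tol, config$rt_tol)
  sp <- dec$species
  rows <- vector("list", nrow(sp))
  match_list <- vector("list", nrow(sp))
  for (i in seq_len(nrow(sp))) {
    mm <- match_candidates(sp$mass[i], candidates, config$match_tol, config$kind)
    mem <- dec$ions[dec$ions$species == sp$species[i], , drop = FALSE]
    confirmed <- coelution_confirm(mem$rt, config$rt_tol)
    status <- if (!confirmed && sp$n_ions[i] < 2) "unconfirmed" else mm$status
    m <- mm$matches
    rows[[i]] <- data.frame(
      species = sp$species[i], rt = sp$rt[i], mass = sp$mass[i],
      n_ions = sp$n_ions[i],
      ions = paste(sprintf("%.4f", sort(mem$mz)), collapse = ";"),
      charges = paste(sort(mem$z), collapse = ";"),
      confirmed = confirmed, status = status,
      n_candidates = nrow(m),
      n_formula_groups = length(unique(m$formula)),
      best_sequence = if (nrow(m) > 0) m$sequence[1] else NA_character_,
      best_label = if (nrow(m) > 0) m$label[1] else NA_character_,
      best_dm = if (nrow(m) > 0) m$dm[1] else NA_real_,
      candidates = paste(sprintf("%s|%s|%+.3f", m$sequence, m$label, m$dm),
                         collapse = ";"),
      stringsAsFactors = FALSE)
    match_list[[i]] <- m
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(species = integer(0), rt = numeric(0), mass = numeric(0),
               n_ions = integer(0), ions = character(0), charges = character(0),
               confirmed = logical(0), status = character(0),
               n_candidates = integer(0), n_formula_groups = integer(0),
               best_sequence = character(0), best_label = character(0),
               best_dm = numeric(0), candidates = character(0),
               stringsAsFactors = FALSE)
  ord <- order(out$rt, out$mass)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "matches") <- match_list[ord]
  attr(out, "config") <- config
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' Summarize an assignment table
#'
#' Reports species counts by status, the metabolite mass range over species
#' with at least one candidate (both the deconvoluted consensus-mass and the
#' best-candidate-mass variants; a \code{predicted_mass} column, when
#' present, yields a third variant), and counts of best candidates by span
#' length and by class (single-end truncation, both-end truncation, base
#' loss).
#'
#' @param tab an \code{assignment_table} (or any data frame with compatible
#'   columns).
#' @return List with elements \code{n_species}, \code{status_counts},
#'   \code{mass_range} (data frame: variant, min, max), \code{length_counts}
#'   and \code{class_counts}.
#' @export
summarize_assignments <- function(tab) {
  idf <- tab[!is.na(tab$status) & tab$status %in% c("identified", "ambiguous"), ,
             drop = FALSE]
  status_counts <- table(factor(tab$status,
    levels = c("identified", "ambiguous", "unidentified", "unconfirmed")))
  rng <- function(x) if (length(x) == 0 || all(is.na(x))) c(NA_real_, NA_real_)
                     else range(x, na.rm = TRUE)
  variants <- list(deconvoluted = idf$mass)
  if ("best_dm" %in% names(idf))
    variants$best_candidate <- idf$mass + idf$best_dm
  if ("predicted_mass" %in% names(tab))
    variants$predicted <- tab$predicted_mass[!is.na(tab$predicted_mass) &
      tab$status %in% c("identified", "ambiguous")]
  mass_range <- do.call(rbind, lapply(names(variants), function(v) {
    r <- rng(variants[[v]])
    data.frame(variant = v, min = r[1], max = r[2], stringsAsFactors = FALSE)
  }))
  matches <- attr(tab, "matches")
  len_cls <- NULL
  if (!is.null(matches)) {
    best <- do.call(rbind, lapply(matches, function(m)
      if (!is.null(m) && nrow(m) > 0) m[1, c("length", "a", "b", "n_losses")]
      else NULL))
    if (!is.null(best)) {
      cls <- ifelse(best$n_losses > 0, "base_loss",
             ifelse(best$a > 0 & best$b > 0, "both_end", "single_end"))
      len_cls <- list(length_counts = table(best$length),
                     class_counts = table(cls))
    }
  }
  list(n_species = nrow(tab),
       status_counts = status_counts,
       mass_range = mass_range,
       length_counts = if (is.null(len_cls)) table(integer(0)) else len_cls$length_counts,
       class_counts = if (is.null(len_cls)) table(character(0)) else len_cls$class_counts)
}
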