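# Seeded synthetic serum-extract peak lists and EIC traces with known ground
# truth, emulating the statistical structure the identification pipeline
# assumes: 2-4-mer metabolites each emitting a -1/-2 isotope-resolved ion
# pair at a shared retention time, matrix peaks confined to the dead-time
# region, and additive m/z noise.

#' Synthetic-sample configuration
#'
#' Defaults emulate the serum-extract conditions the pipeline targets:
#' metabolites eluting between 8.5 and 11 min as in the observed serum
#' shortmers, chromatographic peak width 0.05 min (sigma), additive Gaussian
#' m/z error of 0.01 Da (mimicking the ~0.1-0.3 Da observed-vs-predicted
#' scatter at the deconvoluted-mass level), log-uniform abundances over two
#' decades, and charge-free matrix peaks restricted to the first four
#' minutes, where unremoved matrix components elute.
#'
#' @param n_metabolites number of planted metabolites.
#' @param rt_window elution window (min) for planted species.
#' @param rt_min_spacing minimum spacing between planted retention times
#'   (min); keeps distinct species chromatographically resolvable, as the
#'   separation method achieves for species 0.23 min apart.
#' @param peak_sigma chromatographic Gaussian width (min).
#' @param mz_sd additive m/z error standard deviation (Da).
#' @param intensity_decades abundance range in log10 decades.
#' @param intensity_base smallest abundance (counts).
#' @param intensity_cv multiplicative log-normal intensity noise (CV).
#' @param matrix_rt_max matrix peaks elute before this time (min).
#' @param n_matrix number of matrix peaks.
#' @param charges charge states emitted per metabolite.
#' @param prune isotope-envelope truncation threshold.
#' @param seed mandatory integer seed; every random draw flows through it.
#' @return List of class \code{synth_config}.
#' @export
synth_config <- function(n_metabolites = 20L, rt_window = c(8.5, 11.0),
                         rt_min_spacing = 0.12, peak_sigma = 0.05,
                         mz_sd = 0.01, intensity_decades = 2,
                         intensity_base = 1e4, intensity_cv = 0.1,
                         matrix_rt_max = 4.0, n_matrix = 30L,
                         charges = c(1L, 2L), prune = 0.01, seed) {
  if (missing(seed)) stop("a seed is mandatory for synthetic data")
  stopifnot(n_metabolites >= 1, length(rt_window) == 2,
            rt_window[1] < rt_window[2], rt_min_spacing >= 0, peak_sigma > 0,
            mz_sd >= 0, intensity_decades > 0, matrix_rt_max > 0,
            n_matrix >= 0, all(charges %in% 1:4), prune >= 0, prune < 1)
  structure(list(n_metabolites = as.integer(n_metabolites),
                 rt_window = rt_window, rt_min_spacing = rt_min_spacing,
                 peak_sigma = peak_sigma, mz_sd = mz_sd,
                 intensity_decades = intensity_decades,
                 intensity_base = intensity_base, intensity_cv = intensity_cv,
                 matrix_rt_max = matrix_rt_max, n_matrix = as.integer(n_matrix),
                 charges = as.integer(charges), prune = prune,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Sample ground-truth metabolites from the candidate space
#'
#' Draws \code{n_metabolites} distinct fragments uniformly without
#' replacement from the candidate space of the parent, assigns each a
#' retention time in the elution window (respecting the minimum spacing)
#' and a log-uniform abundance. Fully determined by the config seed.
#'
#' @param parent parent oligo, default \code{\link{NUSINERSEN}}.
#' @param config a \code{\link{synth_config}}.
#' @param candidates optional pre-built candidate space.
#' @return Data frame of planted metabolites: the candidate columns plus
#'   \code{truth_id}, \code{rt} and \code{abundance}.
#' @export
generate_truth <- function(parent = NUSINERSEN, config, candidates = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(candidates)) candidates <- default_candidate_space(parent)
  n <- config$n_metabolites
  if (n > nrow(candidates))
    stop("n_metabolites (", n, ") exceeds candidate space size (",
         nrow(candidates), ")")
  set.seed(config$seed)
  pick <- sample.int(nrow(candidates), n)
  truth <- candidates[pick, , drop = FALSE]
  rownames(truth) <- NULL
  truth$truth_id <- seq_len(n)
  truth$rt <- .spaced_uniform(n, config$rt_window, config$rt_min_spacing)
  truth$abundance <- config$intensity_base *
    10^stats::runif(n, 0, config$intensity_decades)
  attr(truth, "parent") <- parent
  truth
}

# n points uniform over the configurations of [window] with minimum pairwise
# spacing: draw n uniforms on the shrunken interval, sort, re-inflate
.spaced_uniform <- function(n, window, spacing) {
  slack <- diff(window) - spacing * (n - 1)
  if (slack <= 0)
    stop("rt window too narrow for ", n, " species at spacing ", spacing)
  u <- sort(stats::runif(n, 0, slack))
  pts <- window[1] + u + spacing * (seq_len(n) - 1)
  pts[sample.int(n)]  # decouple elution order from truth order
}

#' Generate a synthetic peak list, EIC traces and truth manifest
#'
#' For each planted metabolite and emitted charge state the isotope envelope
#' of its formula is computed, scaled by its abundance, perturbed with
#' additive Gaussian m/z noise and multiplicative log-normal intensity
#' noise, and stamped with the metabolite's retention time (shared across
#' its ions). Matrix peaks carry no charge-pair structure -- they must be
#' rejected by ion pairing, not by an intensity gate -- and are confined to
#' the dead-time region. EIC traces are Gaussian peaks on a uniform grid.
#'
#' @param truth data frame from \code{\link{generate_truth}}.
#' @param config the same \code{\link{synth_config}}.
#' @param rt_grid_step EIC grid step (min).
#' @return List of class \code{synth_sample}: \code{peaklist} (columns
#'   \code{mz}, \code{z}, \code{rt}, \code{intensity}), \code{manifest}
#'   (one row per emitted peak with \code{source} = truth id or
#'   \code{"matrix"}), \code{eic} (list of data frames \code{rt},
#'   \code{intensity}, one per truth metabolite and charge), and the config.
#' @export
generate_sample <- function(truth, config, rt_grid_step = 0.01) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  peaks <- list()
  eics <- list()
  grid <- seq(0, config$rt_window[2] + 1, by = rt_grid_step)
  for (i in seq_len(nrow(truth))) {
    f <- formula_parse(truth$formula[i])
    for (z in config$charges) {
      env <- isotope_pattern(f, z, prune = config$prune)
      mz <- env$mz + stats::rnorm(nrow(env), 0, config$mz_sd)
      inten <- truth$abundance[i] * env$abundance *
        stats::rlnorm(nrow(env), 0, config$intensity_cv)
      peaks[[length(peaks) + 1L]] <- data.frame(
        mz = mz, z = z, rt = truth$rt[i], intensity = inten,
        source = truth$truth_id[i], monoisotopic_peak = seq_len(nrow(env)) == 1L)
      apex <- sum(inten)
      eics[[paste0("truth", truth$truth_id[i], "_z", z)]] <- data.frame(
        rt = grid,
        intensity = apex * exp(-(grid - truth$rt[i])^2 / (2 * config$peak_sigma^2)))
    }
  }
  if (config$n_matrix > 0) {
    mt <- data.frame(
      mz = stats::runif(config$n_matrix, 450, 1700),
      z = 1L,
      rt = stats::runif(config$n_matrix, 0, config$matrix_rt_max),
      intensity = config$intensity_base *
        10^stats::runif(config$n_matrix, 0, config$intensity_decades),
      source = NA_integer_, monoisotopic_peak = FALSE)
    peaks[[length(peaks) + 1L]] <- mt
  }
  manifest <- do.call(rbind, peaks)
  manifest$source <- ifelse(is.na(manifest$source), "matrix",
                            as.character(manifest$source))
  rownames(manifest) <- NULL
  peaklist <- manifest[, c("mz", "z", "rt", "intensity")]
  structure(list(peaklist = peaklist, manifest = manifest, eic = eics,
                 config = config, truth = truth),
            class = "synth_sample")
}

#' Score identification recall against planted truth
#'
#' A planted metabolite counts as recovered when some species in the
#' assignment table lists its exact fragment (span, terminal groups and
#' base-loss set) among the matched candidates. Cross-metabolite mergers are
#' species whose supporting ions trace back to more than one planted
#' metabolite in the manifest.
#'
#' @param tab \code{assignment_table} from \code{\link{run_identification}}.
#' @param sample a \code{synth_sample}.
#' @param config the \code{\link{identify_config}} used for the run.
#' @return List with \code{recall}, \code{n_recovered}, \code{n_planted} and
#'   \code{n_mergers}.
#' @export
score_identification <- function(tab, sample, config = identify_config()) {
  truth <- sample$truth
  matches <- attr(tab, "matches")
  key <- function(d) paste(d$start, d$end, d$term_left, d$term_right, d$losses,
                           sep = "/")
  truth_keys <- key(truth)
  recovered <- logical(nrow(truth))
  for (m in matches) {
    if (is.null(m) || nrow(m) == 0) next
    recovered <- recovered | truth_keys %in% key(m)
  }
  # mergers: re-run pairing to map ions back to manifest sources
  dec <- pair_ions(sample$peaklist, config$mass_tol, config$rt_tol)
  src <- sample$manifest$source
  merged <- vapply(split(seq_len(nrow(dec$ions)), dec$ions$species),
                   function(idx) {
                     s <- unique(src[idx])
                     length(setdiff(s, "matrix")) > 1
                   }, logical(1))
  list(recall = mean(recovered), n_recovered = sum(recovered),
       n_planted = nrow(truth), n_mergers = sum(merged))
}
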