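# Spectral operations: isotope-pattern prediction by elemental convolution,
# charge-state determination from isotope spacing, neutral-mass deconvolution
# of negative-mode ions, and -1/-2 ion-pair detection with consensus mass.

#' Predict the isotope envelope of a formula
#'
#' Exact elemental convolution: each element's single-atom isotope
#' distribution is raised to its atom count (convolution by repeated
#' squaring) and the per-element results are convolved across elements.
#' Isotopologues are aggregated on a nominal-mass grid (fine structure
#' within one nominal shift is merged into a single peak at the
#' abundance-weighted mean mass), matching Q-TOF-scale resolution. Neutral
#' isotopologue masses are converted to negative-mode m/z by removing
#' \code{z} protons.
#'
#' @param f formula.
#' @param z charge magnitude (negative mode implied); \code{z = 0} is an
#'   error.
#' @param prune peaks with abundance below \code{prune} (as a fraction of
#'   the most intense peak) are removed and the envelope renormalized to
#'   sum 1. \code{0 <= prune < 1}.
#' @return Data frame with columns \code{mz} (strictly increasing) and
#'   \code{abundance} (fractions summing to 1), with attribute \code{z}.
#' @export
isotope_pattern <- function(f, z = 1L, prune = 1e-4) {
  if (z == 0) stop("charge must be non-zero")
  stopifnot(prune >= 0, prune < 1)
  f <- formula_canon(f)
  if (any(f < 0)) stop("formula has negative atom counts")
  dist <- data.frame(off = 0L, p = 1, m = 0)
  for (el in names(f)) {
    n <- f[[el]]
    if (n == 0) next
    iso <- isotope_table[[el]]
    atom <- data.frame(off = as.integer(round(iso$mass - iso$mass[1])),
                       p = iso$abundance, m = iso$mass)
    dist <- .convolve_nominal(dist, .dist_power(atom, n))
  }
  dist <- dist[order(dist$off), ]
  keep <- dist$p >= prune * max(dist$p)
  dist <- dist[keep, , drop = FALSE]
  dist$p <- dist$p / sum(dist$p)
  out <- data.frame(mz = (dist$m - abs(z) * PROTON_MASS) / abs(z),
                    abundance = dist$p)
  attr(out, "z") <- abs(z)
  attr(out, "offset") <- dist$off
  out
}

# convolve two nominal-grid distributions; m is the abundance-weighted mean
# mass within each nominal bin. The bin count is bounded by the nominal
# offset range, so no abundance floor is applied and the convolution is
# exact up to floating point.
.convolve_nominal <- function(a, b) {
  off <- outer(a$off, b$off, "+")
  p <- outer(a$p, b$p)
  m <- outer(a$m, b$m, "+")
  key <- as.vector(off)
  pv <- as.vector(p)
  mv <- as.vector(m)
  agg_p <- tapply(pv, key, sum)
  agg_m <- tapply(pv * mv, key, sum) / agg_p
  out <- data.frame(off = as.integer(names(agg_p)), p = as.numeric(agg_p),
                    m = as.numeric(agg_m))
  out[out$p > 0, , drop = FALSE]
}

.dist_power <- function(atom, n) {
  result <- NULL
  sq <- atom
  while (n > 0) {
    if (n %% 2 == 1)
      result <- if (is.null(result)) sq else .convolve_nominal(result, sq)
    n <- n %/% 2
    if (n > 0) sq <- .convolve_nominal(sq, sq)
  }
  if (is.null(result)) data.frame(off = 0L, p = 1, m = 0) else result
}

#' Determine charge state from isotope spacing
#'
#' The spacing between successive isotopologue peaks of a \code{z}-charged
#' ion is close to \code{1/z}; the charge is recovered as
#' \code{round(1 / median(spacing))}, accepted only when every successive
#' spacing lies within \code{0.02} of \code{1/z} and \code{z} is in 1..4.
#'
#' @param mz numeric vector of envelope m/z values (>= 2, increasing).
#' @param tol maximum deviation of each spacing from \code{1/z}.
#' @return Integer charge magnitude, or \code{NA_integer_} when the spacing
#'   pattern is inconsistent or implies a charge outside 1..4
#'   (indeterminate; not an error).
#' @export
charge_from_spacing <- function(mz, tol = 0.02) {
  stopifnot(length(mz) >= 2)
  sp <- diff(sort(mz))
  z <- as.integer(round(1 / stats::median(sp)))
  if (is.na(z) || z < 1L || z > 4L) return(NA_integer_)
  if (any(abs(sp - 1 / z) > tol)) return(NA_integer_)
  z
}

#' Neutral mass of a negative-mode ion
#'
#' Proton restoration: a \code{z}-charged negative ion has lost \code{z}
#' protons, so \code{M = z * mz + z * 1.007276}.
#'
#' @param mz observed m/z (Da).
#' @param z charge magnitude.
#' @return Neutral monoisotopic-peak mass in Da. Vectorized.
#' @export
neutral_mass <- function(mz, z) {
  z <- abs(z)
  z * mz + z * PROTON_MASS
}

#' m/z of a neutral mass at a given negative charge
#'
#' Exact inverse of \code{\link{neutral_mass}}.
#'
#' @param M neutral mass (Da); must exceed \code{z * 1.007276}.
#' @param z charge magnitude.
#' @return m/z in Da. Vectorized.
#' @export
mz_from_mass <- function(M, z) {
  z <- abs(z)
  out <- (M - z * PROTON_MASS) / z
  if (any(out <= 0)) stop("nonpositive m/z: neutral mass must exceed z * proton mass")
  out
}

#' Pair negative-mode ions into deconvolved species
#'
#' Ions are processed greedily in order of descending intensity (ties broken
#' by lower m/z). An ion joins an existing species only if its neutral-mass
#' estimate is within \code{mass_tol} of every member's estimate and its
#' retention time within \code{rt_tol} of every member's; otherwise it seeds
#' a new species. Species supported by a single ion are flagged unconfirmed.
#' A -1/-2 pair at a shared retention time is the signature the method uses
#' to confirm that two signals come from one compound.
#'
#' @param ions data frame with columns \code{mz}, \code{z}, \code{rt},
#'   \code{intensity} (one ion per row).
#' @param mass_tol maximum difference between per-ion neutral-mass estimates
#'   within one species (Da).
#' @param rt_tol maximum retention-time difference within one species (min).
#' @return Object of class \code{deconvolved}: a list with \code{species}
#'   (data frame: \code{species}, \code{mass} = unweighted mean of the
#'   per-ion estimates, \code{rt} = intensity-weighted mean, \code{n_ions},
#'   \code{confirmed}) and \code{ions} (the input plus \code{species} id and
#'   per-ion \code{mass_est}).
#' @export
pair_ions <- function(ions, mass_tol = 0.2, rt_tol = 0.1) {
  stopifnot(mass_tol > 0, rt_tol > 0)
  req <- c("mz", "z", "rt", "intensity")
  if (!all(req %in% names(ions)))
    stop("ions must have columns: ", paste(req, collapse = ", "))
  n <- nrow(ions)
  if (n == 0) {
    sp <- data.frame(species = integer(0), mass = numeric(0), rt = numeric(0),
                     n_ions = integer(0), confirmed = logical(0))
    return(structure(list(species = sp,
                          ions = cbind(ions, species = integer(0),
                                       mass_est = numeric(0))),
                     class = "deconvolved"))
  }
  ions$mass_est <- neutral_mass(ions$mz, ions$z)
  ord <- order(-ions$intensity, ions$mz)
  assign_id <- integer(n)
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (s in seq_along(members)) {
      mem <- members[[s]]
      if (all(abs(ions$mass_est[i] - ions$mass_est[mem]) <= mass_tol) &&
          all(abs(ions$rt[i] - ions$rt[mem]) <= rt_tol)) {
        members[[s]] <- c(mem, i)
        assign_id[i] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      members[[length(members) + 1L]] <- i
      assign_id[i] <- length(members)
    }
  }
  sp <- do.call(rbind, lapply(seq_along(members), function(s) {
    mem <- members[[s]]
    w <- ions$intensity[mem]
    if (sum(w) <= 0) w <- rep(1, length(mem))
    data.frame(species = s,
               mass = mean(ions$mass_est[mem]),
               rt = sum(ions$rt[mem] * w) / sum(w),
               n_ions = length(mem),
               confirmed = length(mem) >= 2L)
  }))
  ions$species <- assign_id
  structure(list(species = sp, ions = ions), class = "deconvolved")
}

#' @export
print.deconvolved <- function(x, ...) {
  cat("<deconvolved> ", nrow(x$species), " species from ", nrow(x$ions),
      " ions (", sum(x$species$confirmed), " confirmed by ion pairing)\n",
      sep = "")
  invisible(x)
}
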