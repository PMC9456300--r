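# Independent oracles used across the suite. These deliberately share no
# code with the package: masses come from a separately transcribed constant
# table and the isotope oracle enumerates isotopologues atom by atom.

# per-atom monoisotopic masses, transcribed independently (CODATA/AME)
ORACLE_MONO <- c(H = 1.00782503207, C = 12.0, N = 14.0030740048,
                 O = 15.9949146196, P = 30.97376163, S = 31.97207100)

# brute-force monoisotopic mass: explicit per-atom summation loop
oracle_mono_mass <- function(counts) {
  total <- 0
  for (el in names(counts)) {
    for (k in seq_len(counts[[el]])) total <- total + ORACLE_MONO[[el]]
  }
  total
}

# brute-force isotope envelope: enumerate the isotope choice of every atom
# via expand.grid, then aggregate on the nominal-offset grid. Only feasible
# for small formulas (product of isotope-count^atoms kept modest).
oracle_isotope_envelope <- function(counts, iso_table) {
  atoms <- unlist(mapply(function(el, n) rep(el, n), names(counts), counts,
                         SIMPLIFY = FALSE), use.names = FALSE)
  choices <- lapply(atoms, function(el) seq_len(nrow(iso_table[[el]])))
  grid <- expand.grid(choices)
  p <- rep(1, nrow(grid)); m <- rep(0, nrow(grid)); off <- rep(0L, nrow(grid))
  for (j in seq_along(atoms)) {
    iso <- iso_table[[atoms[j]]]
    idx <- grid[[j]]
    p <- p * iso$abundance[idx]
    m <- m + iso$mass[idx]
    off <- off + as.integer(round(iso$mass[idx] - iso$mass[1]))
  }
  agg_p <- tapply(p, off, sum)
  agg_m <- tapply(p * m, off, sum) / agg_p
  data.frame(off = as.integer(names(agg_p)), p = as.numeric(agg_p),
             m = as.numeric(agg_m))
}

# random small formula for property tests
random_formula <- function(max_atoms = 30) {
  n <- c(C = sample(0:8, 1), H = sample(0:12, 1), N = sample(0:4, 1),
         O = sample(0:6, 1), P = sample(0:2, 1), S = sample(0:2, 1))
  if (sum(n) == 0) n["C"] <- 1L
  do.call(formula, as.list(n))
}

# random short oligo for enumeration property tests
random_oligo <- function(n) {
  modified_oligo(sample(c("mU", "mC", "A", "G"), n, replace = TRUE))
}
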