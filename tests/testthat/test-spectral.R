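test_that("isotope patterns reproduce simple closed-form ratios", {
  e0 <- isotope_pattern(formula(), z = 1, prune = 0)
  expect_equal(nrow(e0), 1)
  expect_equal(e0$abundance, 1)
  c2 <- isotope_pattern(formula(C = 2), z = 1, prune = 0)
  expect_equal(c2$abundance[2] / c2$abundance[1], 2 * 0.0107 / 0.9893,
               tolerance = 1e-6)
  s1 <- isotope_pattern(formula(S = 1), z = 1, prune = 0)
  # +2 peak relative to base
  expect_equal(s1$abundance[3] / s1$abundance[1], 0.0425 / 0.9499,
               tolerance = 1e-4)
  expect_error(isotope_pattern(formula(C = 1), z = 0), "charge")
})

test_that("elemental convolution equals brute-force isotopologue enumeration", {
  cases <- list(formula(H = 2, O = 1),
                formula(C = 3, H = 6, O = 1),
                formula(C = 2, H = 3, N = 2, O = 2, S = 1),
                formula(C = 4, O = 4, P = 2, S = 2))
  for (f in cases) {
    expect_lte(sum(f), 12)
    oracle <- oracle_isotope_envelope(f[f > 0], isotope_table)
    oracle$p <- oracle$p / sum(oracle$p)
    env <- isotope_pattern(f, z = 1, prune = 0)
    # align on the nominal-offset grid; bins absent from the envelope carry
    # abundance below the numeric floor and must be < 1e-9 in the oracle too
    got <- env$abundance[match(oracle$off, attr(env, "offset"))]
    mz_got <- env$mz[match(oracle$off, attr(env, "offset"))]
    miss <- is.na(got)
    expect_true(all(oracle$p[miss] < 1e-9))
    expect_lt(max(abs(got[!miss] - oracle$p[!miss])), 1e-9)
    expect_lt(max(abs(mz_got[!miss] - mz_from_mass(oracle$m[!miss], 1))), 1e-9)
  }
})

test_that("envelope invariants hold: spacing 1/z, normalized, increasing", {
  f <- oligo_formula(modified_oligo(c("G", "G"),
                                    terminals = c("hydroxyl", "thiophosphate")))
  for (z in 1:3) {
    env <- isotope_pattern(f, z, prune = 1e-4)
    expect_true(all(diff(env$mz) > 0))
    expect_equal(sum(env$abundance), 1, tolerance = 1e-6)
    expect_true(all(abs(diff(env$mz) - 1 / z) < 0.01))
  }
})

test_that("charge is recovered from isotope spacing", {
  expect_equal(charge_from_spacing(c(1000, 1001.003, 1002.006)), 1L)
  expect_equal(charge_from_spacing(c(500, 500.5006, 501.0012)), 2L)
  expect_true(is.na(charge_from_spacing(c(100, 100.21))))
  expect_true(is.na(charge_from_spacing(c(100, 100.5, 101.0, 101.4))))
  # round-trip over generated envelopes of random candidates
  set.seed(13)
  space <- enumerate_truncations(NUSINERSEN, 2, 4)
  for (i in sample(nrow(space), 6)) {
    f <- formula_parse(space$formula[i])
    for (z in 1:3)
      expect_equal(charge_from_spacing(isotope_pattern(f, z, 1e-3)$mz), z)
  }
})

test_that("neutral mass and m/z conversion are exact inverses", {
  expect_equal(neutral_mass(855.30, 1), 856.31, tolerance = 0.02)
  expect_equal(neutral_mass(731.31, 2), 1464.63, tolerance = 0.02)
  expect_equal(mz_from_mass(1237.47, 1), 1236.46, tolerance = 0.02)
  expect_equal(mz_from_mass(101.007276, 1), 100.0)
  expect_error(mz_from_mass(2.014552, 2), "nonpositive")
  set.seed(17)
  for (i in 1:20) {
    mz <- runif(1, 450, 1700); z <- sample(1:4, 1)
    expect_equal(mz_from_mass(neutral_mass(mz, z), z), mz, tolerance = 1e-9)
  }
})

test_that("ion pairing joins -1/-2 pairs and separates near misses", {
  ions <- data.frame(mz = c(617.73, 1236.46), z = c(2, 1),
                     rt = c(10.45, 10.45), intensity = c(5, 10))
  dec <- pair_ions(ions, 0.2, 0.1)
  expect_equal(nrow(dec$species), 1)
  expect_true(dec$species$confirmed)
  expect_equal(dec$species$mass, 1237.47, tolerance = 0.02)

  # neutral masses ~0.97 Da apart AND 0.23 min apart: two species
  near <- data.frame(mz = c(696.76, 1395.51), z = c(2, 1),
                     rt = c(10.60, 10.83), intensity = c(5, 10))
  dec2 <- pair_ions(near, 0.2, 0.1)
  expect_equal(nrow(dec2$species), 2)
  expect_false(any(dec2$species$confirmed))

  single <- pair_ions(data.frame(mz = 855.30, z = 1, rt = 8.81, intensity = 1),
                      0.2, 0.1)
  expect_equal(nrow(single$species), 1)
  expect_false(single$species$confirmed)
})

test_that("pairing never merges beyond tolerance and ignores input order", {
  set.seed(19)
  for (rep in 1:5) {
    n <- 12
    M <- runif(n, 800, 1700)
    ions <- data.frame(mz = mz_from_mass(M, 1), z = 1,
                       rt = runif(n, 8, 11),
                       intensity = sample(seq(100, 10000, by = 100), n))
    dec <- pair_ions(ions, 0.2, 0.1)
    for (s in unique(dec$ions$species)) {
      est <- dec$ions$mass_est[dec$ions$species == s]
      expect_lte(max(est) - min(est), 0.2)
    }
    shuffled <- ions[sample(n), ]
    dec2 <- pair_ions(shuffled, 0.2, 0.1)
    expect_equal(nrow(dec2$species), nrow(dec$species))
    expect_equal(sort(dec2$species$mass), sort(dec$species$mass))
  }
})
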