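space <- default_candidate_space()

test_that("truth generation is seeded, distinct and in-window", {
  cfg <- synth_config(n_metabolites = 20, seed = 42)
  t1 <- generate_truth(config = cfg, candidates = space)
  t2 <- generate_truth(config = cfg, candidates = space)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 20)
  expect_false(anyDuplicated(t1[, c("start", "end", "term_left",
                                    "term_right", "losses")]) > 0)
  expect_true(all(t1$rt >= 8.5 & t1$rt <= 11))
  d <- as.matrix(stats::dist(t1$rt))
  expect_gte(min(d[upper.tri(d)]), cfg$rt_min_spacing)
  expect_error(generate_truth(config = synth_config(n_metabolites = 1e5,
                                                    seed = 1),
                              candidates = space),
               "exceeds")
})

test_that("planting the whole space uses every candidate once", {
  small <- enumerate_truncations(modified_oligo(c("G", "A", "mU")), 2, 3,
                                 include_full = TRUE)
  cfg <- synth_config(n_metabolites = nrow(small), rt_window = c(8.5, 11),
                      rt_min_spacing = 0.05, seed = 9)
  truth <- generate_truth(config = cfg, candidates = small)
  expect_equal(sort(paste(truth$start, truth$end)),
               sort(paste(small$start, small$end)))
})

test_that("zero-noise samples place monoisotopic ions at exact masses", {
  cfg <- synth_config(n_metabolites = 1, mz_sd = 0, intensity_cv = 0,
                      n_matrix = 0, seed = 4)
  truth <- generate_truth(config = cfg, candidates = space)
  smp <- generate_sample(truth, cfg)
  mono <- smp$manifest[smp$manifest$monoisotopic_peak, ]
  expect_equal(nrow(mono), 2)  # one per charge state
  expect_equal(sort(mono$z), c(1, 2))
  for (i in seq_len(nrow(mono)))
    expect_equal(neutral_mass(mono$mz[i], mono$z[i]), truth$monoisotopic[1],
                 tolerance = 1e-6)
  # same seed: identical outputs
  smp2 <- generate_sample(truth, cfg)
  expect_identical(smp$peaklist, smp2$peaklist)
})

test_that("every emitted peak is attributable to truth or matrix", {
  cfg <- synth_config(n_metabolites = 5, seed = 8)
  truth <- generate_truth(config = cfg, candidates = space)
  smp <- generate_sample(truth, cfg)
  expect_equal(nrow(smp$manifest), nrow(smp$peaklist))
  expect_true(all(smp$manifest$source %in%
                  c("matrix", as.character(truth$truth_id))))
  expect_equal(sum(smp$manifest$source == "matrix"), cfg$n_matrix)
  # matrix peaks stay in the dead-time region, planted ions in the window
  expect_true(all(smp$manifest$rt[smp$manifest$source == "matrix"] < 4))
  expect_true(all(smp$manifest$rt[smp$manifest$source != "matrix"] >= 8.5))
})

test_that("species one Da and 0.23 min apart are reported separately", {
  # emulates the resolved near-isobaric pair: two planted fragments whose
  # neutral masses differ by about one Da, eluting 0.23 min apart
  pair <- rbind(
    space[space$sequence == "mU*mC" & space$term_left == "hydroxyl" &
          space$term_right == "hydroxyl", ][1, ],
    space[space$sequence == "mU*mU" & space$term_left == "hydroxyl" &
          space$term_right == "hydroxyl", ][1, ])
  expect_equal(diff(pair$monoisotopic), 0.98, tolerance = 0.02)
  truth <- pair
  truth$truth_id <- 1:2
  truth$rt <- c(10.60, 10.83)
  truth$abundance <- c(1e5, 1e5)
  cfg <- synth_config(n_metabolites = 2, mz_sd = 0, intensity_cv = 0,
                      n_matrix = 0, seed = 3)
  smp <- generate_sample(truth, cfg)
  icfg <- identify_config()
  tab <- run_identification(smp$peaklist, icfg, candidates = space)
  # both monoisotopic species present and distinct, each pair-confirmed;
  # the second species elutes 0.23 min later, which is what separates it
  # from the first species' +1 isotopologue at almost the same mass
  hit1 <- which(abs(tab$mass - pair$monoisotopic[1]) < 0.05 &
                abs(tab$rt - 10.60) < 0.05)
  hit2 <- which(abs(tab$mass - pair$monoisotopic[2]) < 0.05 &
                abs(tab$rt - 10.83) < 0.05)
  expect_length(hit1, 1)
  expect_length(hit2, 1)
  expect_true(tab$confirmed[hit1] && tab$confirmed[hit2])
  sc <- score_identification(tab, smp, icfg)
  expect_equal(sc$n_mergers, 0)
  expect_equal(sc$recall, 1)
})

test_that("identification recall degrades monotonically with m/z noise", {
  recalls <- vapply(c(0.01, 0.05, 0.2), function(sd) {
    cfg <- synth_config(n_metabolites = 10, mz_sd = sd, seed = 27)
    truth <- generate_truth(config = cfg, candidates = space)
    smp <- generate_sample(truth, cfg)
    icfg <- identify_config()
    tab <- run_identification(smp$peaklist, icfg, candidates = space)
    score_identification(tab, smp, icfg)$recall
  }, numeric(1))
  expect_true(all(diff(recalls) <= 0))
  expect_gte(recalls[1], 0.9)
})
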