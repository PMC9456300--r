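test_that("truncation enumeration matches the closed-form span counts", {
  expect_equal(nrow(enumerate_truncations(NUSINERSEN, 1, 17)), 170)
  expect_equal(nrow(enumerate_truncations(NUSINERSEN, 2, 4)), 48)
  full <- enumerate_truncations(NUSINERSEN, 18, 18, include_full = TRUE)
  expect_equal(nrow(full), 1)
  expect_equal(full$a, 0)
  expect_equal(full$b, 0)
  expect_equal(full$label, "intact")
  expect_error(enumerate_truncations(NUSINERSEN, 5, 2), "min_len")
})

test_that("every span appears exactly once for random small parents", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(2:8, 1)
    oligo <- random_oligo(n)
    lo <- sample.int(n, 1); hi <- lo + sample.int(n - lo + 1, 1) - 1L
    cand <- enumerate_truncations(oligo, lo, hi, include_full = TRUE)
    expected <- sum(vapply(lo:hi, function(L) n - L + 1L, integer(1)))
    expect_equal(nrow(cand), expected)
    expect_false(anyDuplicated(cand[, c("start", "end")]) > 0)
    # label <-> span bijection for fixed parent length
    expect_false(anyDuplicated(cand[, c("a", "b")]) > 0)
    expect_equal(cand$a, cand$start - 1L)
    expect_equal(cand$b, n - cand$end)
  }
})

test_that("terminal policy expands candidates with recomputed masses", {
  gg <- enumerate_truncations(modified_oligo(c("G", "G")), 2, 2,
                              include_full = TRUE)
  all4 <- apply_terminal_policy(gg)
  expect_equal(nrow(all4), 4)
  expect_false(anyDuplicated(all4[, c("start", "end", "term_left",
                                      "term_right", "losses")]) > 0)
  ht <- all4[all4$term_left == "hydroxyl" & all4$term_right == "thiophosphate", ]
  expect_equal(ht$monoisotopic, 856.143, tolerance = 0.005)
  hh <- all4[all4$term_left == "hydroxyl" & all4$term_right == "hydroxyl", ]
  expect_equal(hh$monoisotopic, 760.199, tolerance = 0.005)
  expect_error(apply_terminal_policy(gg, data.frame(left = character(0),
                                                    right = character(0))),
               "non-empty")
})

test_that("base-loss expansion follows the abasic composition rule", {
  tri <- enumerate_truncations(modified_oligo(c("mU", "A", "mC")), 3, 3,
                               include_full = TRUE)
  expanded <- enumerate_base_losses(tri, 1)
  expect_equal(nrow(expanded), 4)  # original + one loss at each position
  adenine <- formula(C = 5, H = 5, N = 5)
  orig <- formula_parse(tri$formula[1])
  a_loss <- expanded[expanded$losses == "2", ]
  expect_equal(formula_parse(a_loss$formula),
               formula_add(formula_diff(orig, adenine), formula(H = 2, O = 1)))
  expect_true(grepl("MoeR", a_loss$sequence))
  # max_losses 0 is the identity
  expect_identical(enumerate_base_losses(tri, 0), tri)
})

test_that("symmetric losses collapse in the formula-dedup view only", {
  gg <- enumerate_truncations(modified_oligo(c("G", "G")), 2, 2,
                              include_full = TRUE)
  expanded <- enumerate_base_losses(gg, 1)
  losses <- expanded[expanded$n_losses == 1, ]
  expect_equal(nrow(losses), 2)          # retained individually
  expect_equal(length(unique(losses$formula)), 1)  # one distinct composition
  grp <- formula_groups(expanded)
  expect_equal(sum(grp$n_candidates), nrow(expanded))  # partition
})

test_that("adjacent-run counting is orientation-free", {
  expect_equal(count_adjacent_runs(NUSINERSEN, c("mU", "mC")), 4)
  expect_equal(count_adjacent_runs(NUSINERSEN, c("G", "G")), 1)
  expect_equal(count_adjacent_runs(NUSINERSEN, c("A", "A")), 1)
  expect_equal(count_adjacent_runs(NUSINERSEN, c("mC", "mU")), 4)  # unordered
  expect_equal(count_adjacent_runs(modified_oligo(c("A", "G")),
                                   c("A", "A", "A")), 0)
})

test_that("truncation labels render in shortmer notation", {
  expect_equal(truncation_label(0, 16), "3'N-16")
  expect_equal(truncation_label(7, 8), "5'N-7+3'N-8")
  expect_equal(truncation_label(16, 0), "5'N-16")
  cand <- enumerate_truncations(NUSINERSEN, 2, 3)
  span <- cand[cand$start == 8 & cand$end == 10, ]
  expect_equal(span$label, "5'N-7+3'N-8")
})

test_that("candidate masses agree with independent per-atom summation", {
  space <- default_candidate_space()
  expect_equal(nrow(space), 760)
  set.seed(21)
  for (i in sample(nrow(space), 15)) {
    f <- formula_parse(space$formula[i])
    expect_equal(space$monoisotopic[i], oracle_mono_mass(f[f > 0]),
                 tolerance = 1e-6)
  }
})

test_that("candidate tables round-trip through TSV", {
  cand <- enumerate_truncations(modified_oligo(c("G", "A", "mU")), 2, 3,
                                include_full = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(cand, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$formula, cand$formula)
  expect_equal(back$monoisotopic, cand$monoisotopic, tolerance = 1e-9)
})
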