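test_that("region extraction uses 1-based inclusive coordinates with provenance", {
  parent <- latarcin_peptides()$`Ltc-3a`
  frag <- extract_region(parent, 5, 17)
  expect_identical(as.character(frag), "MAKKLKEYMEKLK")
  expect_identical(length(frag), 13L)
  expect_identical(attr(frag, "offset"), 5L)
  expect_match(frag$name, "Ltc-3a\\[5-17\\]")

  expect_identical(as.character(extract_region(parent, 1, 20)),
                   as.character(parent))
  expect_error(extract_region(parent, 0, 17), "out of range")
  expect_error(extract_region(parent, 5, 21), "out of range")
})

test_that("composition divergence is a position-free multiset distance", {
  frag <- "MAKKLKEYMEKLK"
  expect_equal(composition_divergence("LAKKLKEYLEKLV", frag), 3 / 13)
  expect_equal(composition_divergence("LIKKLKEYLKKLI", frag), 4 / 13)
  expect_equal(composition_divergence("LAKKLAKYLKKAL", frag), 4 / 13)
  expect_equal(composition_divergence(frag, frag), 0)
  # any permutation has zero divergence
  expect_equal(composition_divergence("KKKMMAELLEYKK", frag), 0)
  expect_error(composition_divergence("MAK", frag), "equal-length")
})

test_that("scoring rewards charge and amphipathicity gains over the parent", {
  parent <- describe_peptide("MAKKLKEYMEKLK")
  expect_equal(score_candidate(parent, parent), 0)
  s1 <- score_candidate(describe_peptide("LAKKLKEYLEKLV"), parent)
  s2 <- score_candidate(describe_peptide("LIKKLKEYLKKLI"), parent)
  s3 <- score_candidate(describe_peptide("LAKKLAKYLKKAL"), parent)
  expect_true(s3 >= s2 && s2 >= s1)
  # zero weights tie everything at 0
  w0 <- c(z = 0, muh = 0, h_penalty = 0)
  expect_equal(score_candidate(describe_peptide("LAKKLAKYLKKAL"), parent,
                               weights = w0), 0)
})

test_that("enumeration under the design substitution classes recovers all three analogs", {
  frag <- extract_region(latarcin_peptides()$`Ltc-3a`, 5, 17)
  cand <- enumerate_analogs(frag, design_constraints(), limit = 25)
  feasible <- attr(cand, "feasible_sequences")
  expect_true(all(c("LAKKLKEYLEKLV", "LIKKLKEYLKKLI", "LAKKLAKYLKKAL") %in%
                    feasible))

  # every returned candidate satisfies the active (tolerant) divergence cap
  # and the helix guard
  max_units <- floor(0.30 * 13) + 1
  for (i in seq_len(nrow(cand))) {
    expect_lte(round(cand$composition_divergence[i] * 13), max_units)
    expect_false(grepl("[PG]", cand$sequence[i]))
  }
  # ... and the whole feasible set respects the cap too
  divs <- vapply(feasible[seq(1, length(feasible), length.out = 200)],
                 function(s) composition_divergence(s, frag), numeric(1))
  expect_true(all(round(divs * 13) <= max_units))
  expect_false(any(grepl("[PG]", feasible)))

  # ranked output is sorted by score with deterministic tie-breaks
  expect_true(all(diff(cand$score) <= 1e-12))
})

test_that("strict divergence mode drops the two 4-unit analogs but keeps the 3-unit one", {
  frag <- "MAKKLKEYMEKLK"
  cand <- enumerate_analogs(frag, design_constraints(divergence_mode = "strict"),
                            limit = 10)
  feasible <- attr(cand, "feasible_sequences")
  expect_true("LAKKLKEYLEKLV" %in% feasible) # 3/13 = 0.231
  expect_false("LIKKLKEYLKKLI" %in% feasible) # 4/13 = 0.308 > 0.30
  expect_false("LAKKLAKYLKKAL" %in% feasible)
})

test_that("an empty rule set returns only the parent", {
  cand <- enumerate_analogs("MAKKLK",
                            design_constraints(substitution_rules = list()))
  expect_identical(attr(cand, "feasible_sequences"), "MAKKLK")
  expect_identical(cand$n_substitutions, 0L)
  expect_equal(cand$score, 0)
})

test_that("enumeration is deterministic for identical inputs and seed", {
  cons <- design_constraints()
  a <- enumerate_analogs("MAKKLK", cons, limit = 20, seed = 7)
  b <- enumerate_analogs("MAKKLK", cons, limit = 20, seed = 7)
  expect_identical(a, b)
  # sampling path is seed-deterministic too
  big_rules <- setNames(
    rep(list(c("A", "I", "K", "L", "V", "E", "M")), 5),
    c("M", "A", "K", "L", "E")
  )
  cons_big <- design_constraints(substitution_rules = big_rules)
  s1 <- enumerate_analogs("MAKKLKEYMEKLK", cons_big, limit = 10, seed = 3,
                          max_space = 1e4, n_sample = 5e3)
  s2 <- enumerate_analogs("MAKKLKEYMEKLK", cons_big, limit = 10, seed = 3,
                          max_space = 1e4, n_sample = 5e3)
  expect_identical(s1, s2)
  expect_true(all(!grepl("[PG]", s1$sequence)))
})

test_that("helix guard blocks Pro/Gly introduction but not native residues", {
  cand <- enumerate_analogs(
    "MAK", design_constraints(substitution_rules = list(A = c("P", "L")))
  )
  feasible <- attr(cand, "feasible_sequences")
  expect_true("MLK" %in% feasible)
  expect_false(any(grepl("P", feasible)))
  # a native proline is retained even though P cannot be introduced
  candP <- enumerate_analogs(
    "MPK", design_constraints(substitution_rules = list(M = "L"))
  )
  expect_true(all(grepl("P", attr(candP, "feasible_sequences"))))
})
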