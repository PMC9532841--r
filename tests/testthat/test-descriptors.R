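test_that("net charge follows the side-chains-only model", {
  expect_identical(net_charge("LAKKLAKYLKKAL"), 5L)
  expect_identical(net_charge("MAKKLKEYMEKLK"), 3L)
  expect_identical(net_charge("AAAAA"), 0L)
  expect_identical(net_charge("HHHH"), 0L) # His neutral
  expect_identical(net_charge("KRDE"), 0L)
})

test_that("include-termini charge adds the N-terminal amine", {
  # reproduces the database-style +6 for the parent peptide
  expect_identical(net_charge("SWKSMAKKLKEYMEKLKQRA",
                              model = "include-termini"), 6L)
  # counting the free-acid C-terminus as well cancels it back
  expect_identical(net_charge("SWKSMAKKLKEYMEKLKQRA",
                              model = "include-termini",
                              include_c_term = TRUE), 5L)
})

test_that("mean hydrophobicity on the Fauchere-Pliska scale matches the study table", {
  expect_equal(mean_hydrophobicity("SWKSMAKKLKEYMEKLKQRA"), 0.058)
  expect_equal(mean_hydrophobicity("LAKKLKEYLEKLV"), 0.312)
  expect_equal(mean_hydrophobicity("LIKKLKEYLKKLI"), 0.444)
  expect_equal(mean_hydrophobicity("LAKKLAKYLKKAL"), 0.288)
  # mean of one residue is the scale value itself
  fp <- hydrophobicity_scale("fauchere-pliska")
  expect_equal(mean_hydrophobicity("L", digits = NA), unname(unclass(fp)["L"]))
})

test_that("hydrophobic percentage truncates toward zero", {
  expect_identical(hydrophobic_fraction("SWKSMAKKLKEYMEKLKQRA"), 35L) # 7/20
  expect_identical(hydrophobic_fraction("LAKKLAKYLKKAL"), 53L) # 7/13 = 53.8
  expect_identical(hydrophobic_fraction("LAKKLKEYLEKLV"), 46L) # 6/13
  expect_identical(hydrophobic_fraction("KKKKK"), 0L)
})

test_that("hydrophobic moment at 100 deg/residue matches the study table", {
  expect_equal(hydrophobic_moment("SWKSMAKKLKEYMEKLKQRA"), 0.575)
  expect_equal(hydrophobic_moment("LAKKLKEYLEKLV"), 0.740)
  expect_equal(hydrophobic_moment("LIKKLKEYLKKLI"), 0.839)
  expect_equal(hydrophobic_moment("LAKKLAKYLKKAL"), 0.701)
})

test_that("moment vanishes for homopolymers completing whole turns", {
  # 18 residues x 100 deg = 5 full turns
  for (r in c("A", "L", "W")) {
    expect_equal(hydrophobic_moment(strrep(r, 18), digits = NA), 0,
                 tolerance = 1e-12)
  }
  # any length L with (L * delta) %% 360 == 0
  expect_equal(hydrophobic_moment(strrep("F", 36), digits = NA), 0,
               tolerance = 1e-12)
  expect_equal(hydrophobic_moment(strrep("K", 10), delta = 36, digits = NA),
               0, tolerance = 1e-12)
})

test_that("moment is non-negative and invariant under reversal with delta -> -delta", {
  set.seed(7)
  for (i in 1:50) {
    s <- random_peptide()
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    mu <- hydrophobic_moment(s, digits = NA)
    expect_gte(mu, 0)
    expect_equal(mu, hydrophobic_moment(rev_s, delta = -100, digits = NA),
                 tolerance = 1e-9)
    # sign of delta is irrelevant to the magnitude
    expect_equal(mu, hydrophobic_moment(s, delta = -100, digits = NA),
                 tolerance = 1e-12)
  }
})

test_that("moment agrees with the complex-exponential oracle on short sequences", {
  fp <- unclass(hydrophobicity_scale("fauchere-pliska"))
  set.seed(11)
  for (i in 1:100) {
    s <- random_peptide(min_len = 1, max_len = 6)
    expect_equal(hydrophobic_moment(s, digits = NA), oracle_muH(s, fp),
                 tolerance = 1e-9)
  }
})

test_that("wheel projection places residues at (n-1)*delta mod 360", {
  w <- wheel_projection("LAKKLAKYLKKAL")
  expect_equal(w$wheel$angle[1], 0)
  expect_equal(w$wheel$angle[4], 300) # 3 * 100 mod 360
  expect_identical(nrow(w$wheel), 13L)
  expect_true(all(w$wheel$angle >= 0 & w$wheel$angle < 360))

  # the four leucines of Lt-MAP3 sit on the hydrophobic face
  leu <- w$wheel[w$wheel$residue == "L", ]
  expect_identical(nrow(leu), 4L)
  expect_true(all(on_hydrophobic_face(w, leu$angle)))
  # face arc is the half-plane around the moment direction
  expect_false(on_hydrophobic_face(w, w$mu_angle + 135))
  expect_true(on_hydrophobic_face(w, w$mu_angle + 89.9))
})

test_that("describe_peptide bundles the table-exact descriptor set", {
  d1 <- describe_peptide("LAKKLKEYLEKLV")
  expect_equal(d1[c("Z", "H", "H_pct", "muH")],
               list(Z = 2L, H = 0.312, H_pct = 46L, muH = 0.740))
  d3 <- describe_peptide("LAKKLAKYLKKAL")
  expect_equal(d3[c("Z", "H", "H_pct", "muH")],
               list(Z = 5L, H = 0.288, H_pct = 53L, muH = 0.701))
  gg <- describe_peptide("GG")
  expect_equal(gg$Z, 0L)
  expect_equal(gg$H, 0) # mean of two glycines
  expect_equal(gg$H_pct, 0L)
  expect_equal(gg$muH, 0) # G is 0 on Fauchere-Pliska, so the moment is 0
})

test_that("descriptor results leave the scale untouched", {
  fp <- hydrophobicity_scale()
  before <- unclass(fp)
  invisible(describe_peptide("SWKSMAKKLKEYMEKLKQRA", scale = fp))
  expect_identical(unclass(fp), before)
})
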