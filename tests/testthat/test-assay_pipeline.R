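make_plate <- function(g, concs = c(128, 64, 32, 16, 8, 4), nrep = 3,
                       control = 0.5, blank = 0.05, wavelength = 600) {
  # exact two-level plate with growth fraction g per concentration
  readings <- matrix(rep(blank + g * (control - blank), nrep),
                     nrow = length(concs))
  plate_assay(concs, readings, growth_control = rep(control, nrep),
              sterile_blank = rep(blank, nrep), wavelength = wavelength)
}

test_that("MIC is the lowest concentration of an inhibited-from-the-top run", {
  expect_equal(call_mic(make_plate(c(0, 0, 0, 1, 1, 1)))$value, 32)
  # growth everywhere: censored above the top concentration
  e <- call_mic(make_plate(rep(1, 6)))
  expect_true(e$censored)
  expect_identical(e$label, ">128")
  # full inhibition: lowest tested concentration
  expect_equal(call_mic(make_plate(rep(0, 6)))$value, 4)
  # an isolated skipped well below the run does not move the endpoint
  expect_equal(call_mic(make_plate(c(0, 0, 1, 0, 1, 1)))$value, 64)
})

test_that("MIC calls are monotone in the inhibition threshold", {
  set.seed(21)
  for (i in 1:20) {
    plate <- gen_mic_plate(generator_spec(seed = i, true_mic = 32,
                                          noise_sd = 0.05))
    vals <- vapply(c(0.05, 0.10, 0.25, 0.5), function(thr) {
      e <- call_mic(plate, inhibition_threshold = thr)
      if (e$censored) 2 * max(plate$concentrations) else e$value
    }, numeric(1))
    expect_true(all(diff(vals) <= 0)) # higher threshold never raises the MIC
  }
})

test_that("endpoints are tested concentrations or censored, never interpolated", {
  set.seed(31)
  for (i in 1:20) {
    plate <- gen_mic_plate(generator_spec(seed = i,
                                          true_mic = sample(c(NA, 128, 32, 4), 1),
                                          noise_sd = 0.1))
    e <- call_mic(plate)
    expect_true(e$censored || e$value %in% plate$concentrations)
  }
})

test_that("uninterpretable plates error on degenerate controls", {
  p <- make_plate(rep(0.5, 6))
  p$growth_control <- rep(0.05, 3) # control does not exceed blank
  expect_error(call_mic(p), "uninterpretable")
})

test_that("MBC is the lowest concentration with no surviving colonies", {
  concs <- c(128, 64, 32, 16, 8)
  expect_equal(call_mbc(concs, c(0, 0, 0, 12, 300))$value, 32)
  expect_equal(call_mbc(concs, c(0, 0, 0, 0, 0))$value, 8)
  e <- call_mbc(concs, c(5, 9, 20, 80, 200))
  expect_true(e$censored)
  expect_identical(e$label, ">128")
})

test_that("MBIC applies the MIC rule to crystal-violet signal", {
  expect_equal(call_mbic(make_plate(c(0, 0, 0, 0, 1, 1), control = 0.8,
                                    blank = 0.08, wavelength = 595))$value, 16)
  # no biofilm anywhere (signal = blank): lowest tested concentration
  expect_equal(call_mbic(make_plate(rep(0, 6), wavelength = 595))$value, 4)
  # unaffected biofilm: censored
  expect_true(call_mbic(make_plate(rep(1, 6), wavelength = 595))$censored)
})

test_that("hemolysis percent is the blank/Triton-bracketed linear scale", {
  expect_equal(hemolysis_percent(1.2, 0.1, 1.2), 100)
  expect_equal(hemolysis_percent(0.1, 0.1, 1.2), 0)
  expect_equal(hemolysis_percent(0.65, 0.1, 1.2), 50)
  # clamped to [0, 100]
  expect_equal(hemolysis_percent(1.5, 0.1, 1.2), 100)
  expect_equal(hemolysis_percent(0.05, 0.1, 1.2), 0)
  expect_error(hemolysis_percent(0.5, 1.2, 0.1), "degenerate")
})

test_that("viability percent and the 60% cell-death activity rule", {
  expect_equal(viability_percent(0.9, 0.9, 0.1), 100)
  expect_equal(viability_percent(0.1, 0.9, 0.1), 0)
  expect_equal(viability_percent(0.5, 0.9, 0.1), 50)
  expect_error(viability_percent(0.5, 0.1, 0.9), "degenerate")

  expect_true(activity_flag(60))
  expect_false(activity_flag(59.9))
  expect_true(activity_flag(100))
  expect_error(activity_flag(-1))
})

test_that("noise-free 4PL responses recover the generating EC50 within 1%", {
  x <- c(128, 64, 32, 16, 8, 4)
  for (true in c(127, 20, 60)) {
    y <- 100 / (1 + (x / true)^1.5)
    fit <- fit_dose_response(x, y)
    expect_equal(fit$EC50, true, tolerance = 0.01)
    expect_equal(fit$top, 100, tolerance = 0.02)
    expect_equal(fit$bottom, 0, tolerance = 1)
  }
  # increasing (hemolysis-shaped) curves work through the same interface
  yh <- 100 / (1 + (127 / x)^2)
  expect_equal(fit_dose_response(x, yh)$EC50, 127, tolerance = 0.01)
})

test_that("constant responses are reported as non-convergent, not fitted", {
  x <- c(128, 64, 32, 16, 8, 4)
  expect_error(fit_dose_response(x, rep(50, 6)), "unidentifiable")
  expect_error(fit_dose_response(x[1:3], c(1, 2, 3)), "4 distinct")
})

test_that("step response with fixed asymptotes lands between the two highest doses", {
  x <- c(128, 64, 32, 16, 8, 4)
  # hemolysis-shaped step: only the highest dose reaches the top
  y <- c(100, 0, 0, 0, 0, 0)
  fit <- fit_dose_response(x, y, bottom = 0, top = 100)
  # brute-force grid oracle over (EC50, hill)
  grid <- expand.grid(ec50 = exp(seq(log(4), log(512), length.out = 400)),
                      hill = -c(seq(0.2, 20, length.out = 300)))
  rss <- mapply(function(e, h) sum((0 + 100 / (1 + (x / e)^h) - y)^2),
                grid$ec50, grid$hill)
  best <- grid[which.min(rss), ]
  expect_gte(fit$EC50, 64)
  expect_lte(fit$EC50, 128)
  expect_gte(best$ec50, 64)
  expect_lte(best$ec50, 128)
  expect_lte(fit$rss, min(rss) + 1e-6) # fit at least as good as the grid
})

test_that("plate CSV round-trips through the sidecar format", {
  plate <- gen_mic_plate(generator_spec(seed = 2, true_mic = 16))
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(c(f, paste0(f, ".json"))))
  write_plate_csv(plate, f)
  back <- read_plate_csv(f)
  expect_equal(back$concentrations, plate$concentrations)
  expect_equal(unname(back$readings), unname(plate$readings),
               tolerance = 1e-10)
  expect_equal(back$wavelength, 600)
  expect_identical(call_mic(back)$value, call_mic(plate)$value)
})
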