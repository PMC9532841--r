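# Seeded generators emulating every input the pipeline consumes: two-level
# microdilution OD600 plates with a known true MIC, crystal-violet A595
# biofilm plates, 4PL dose-response curves with a known EC50, and jittered
# b/y peak lists. All are bit-reproducible given the spec (which carries the
# seed).

#' Generator specification for synthetic assay data
#'
#' @param seed Integer seed; every generator derives all randomness from it.
#' @param true_mic True endpoint concentration (must be in the series), or
#'   `NA` for a fully resistant plate.
#' @param true_ec50 True EC50 for dose-response curves, ug/ml.
#' @param hill True hill slope (default 1.5, the steep curves typical of
#'   membrane-lytic peptides).
#' @param noise_sd Gaussian noise sd: absorbance units for plates (default
#'   0.02), percentage points for dose-response responses.
#' @param n_replicates Replicates per concentration (default 3, matching
#'   standard triplicate microdilution practice).
#' @param concentration_series Strictly decreasing series, default the
#'   two-fold 128..4 ug/ml dilution.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(seed = 1L, true_mic = 32, true_ec50 = 32,
                           hill = 1.5, noise_sd = 0.02, n_replicates = 3L,
                           concentration_series = c(128, 64, 32, 16, 8, 4)) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (any(diff(concentration_series) >= 0)) {
    stop("concentration_series must be strictly decreasing")
  }
  if (!is.na(true_mic) && !(true_mic %in% concentration_series)) {
    stop("true_mic must be one of the tested concentrations (or NA)")
  }
  structure(
    list(seed = as.integer(seed), true_mic = true_mic, true_ec50 = true_ec50,
         hill = hill, noise_sd = noise_sd,
         n_replicates = as.integer(n_replicates),
         concentration_series = as.numeric(concentration_series)),
    class = "generator_spec"
  )
}

# Two-level well model: inhibited wells read near the sterile blank,
# uninhibited wells near the growth control.
.gen_two_level_plate <- function(spec, control_mu, blank_mu, wavelength) {
  set.seed(spec$seed)
  concs <- spec$concentration_series
  nrep <- spec$n_replicates
  inhibited <- if (is.na(spec$true_mic)) {
    rep(FALSE, length(concs))
  } else {
    concs >= spec$true_mic
  }
  mu <- ifelse(inhibited, blank_mu, control_mu)
  readings <- matrix(
    pmax(0, rnorm(length(concs) * nrep, mean = rep(mu, nrep),
                  sd = spec$noise_sd)),
    nrow = length(concs), ncol = nrep
  )
  plate_assay(
    concentrations = concs,
    readings = readings,
    growth_control = pmax(0, rnorm(nrep, control_mu, spec$noise_sd)),
    sterile_blank = pmax(0, rnorm(nrep, blank_mu, spec$noise_sd)),
    wavelength = wavelength
  )
}

#' Generate a synthetic microdilution MIC plate
#'
#' Wells at concentrations at or above `true_mic` draw near-blank OD600
#' (0.05 AU), wells below draw near-control OD600 (0.5 AU), with truncated
#' Gaussian noise; growth-control and sterile-blank wells included.
#'
#' @param spec A [generator_spec()].
#' @return A [plate_assay()] at 600 nm.
#' @examples
#' call_mic(gen_mic_plate(generator_spec(seed = 7, true_mic = 64)))
#' @export
gen_mic_plate <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  .gen_two_level_plate(spec, control_mu = 0.5, blank_mu = 0.05,
                       wavelength = 600)
}

#' Generate a synthetic crystal-violet biofilm plate
#'
#' Same two-level well model as [gen_mic_plate()] but for solubilized
#' crystal-violet A595 signal (control biofilm 0.8 AU, blank 0.08 AU);
#' `spec$true_mic` plays the role of the true MBIC.
#'
#' @param spec A [generator_spec()].
#' @return A [plate_assay()] at 595 nm.
#' @export
gen_biofilm_plate <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  .gen_two_level_plate(spec, control_mu = 0.8, blank_mu = 0.08,
                       wavelength = 595)
}

#' Generate a synthetic dose-response curve
#'
#' 4PL responses (top 100, bottom 0) at the spec's concentration series with
#' additive Gaussian noise in percentage points; `n_replicates` responses
#' per concentration.
#'
#' @param spec A [generator_spec()]; `true_ec50`, `hill` (> 0, response
#'   decreasing in concentration) and `noise_sd` (percent) are used.
#' @return List with `concentrations` and `responses` (both length
#'   n_conc x n_replicates) plus `true_ec50`.
#' @export
gen_dose_response <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$hill <= 0) stop("hill must be positive")
  set.seed(spec$seed)
  x <- rep(spec$concentration_series, each = spec$n_replicates)
  y0 <- .fourpl(x, bottom = 0, top = 100, ec50 = spec$true_ec50,
                hill = spec$hill)
  y <- y0 + rnorm(length(x), 0, spec$noise_sd)
  list(concentrations = x, responses = y, true_ec50 = spec$true_ec50)
}

#' Generate a synthetic observed peak list for a peptide
#'
#' Takes the theoretical singly charged b/y ladder, drops each fragment peak
#' independently with probability `dropout`, adds Gaussian m/z jitter, and
#' always retains the parent \[M+H\]+ ion.
#'
#' @param seq A `peptide` or character scalar (length >= 2).
#' @param dropout Fragment dropout probability in \[0, 1).
#' @param jitter_sd m/z jitter sd in Da.
#' @param seed Integer seed.
#' @param tolerance Tolerance stored on the returned [peak_list()].
#' @return A `peak_list`.
#' @export
gen_peaklist <- function(seq, dropout = 0.2, jitter_sd = 0.05, seed = 1L,
                         tolerance = 0.5) {
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (jitter_sd < 0) stop("jitter_sd must be non-negative")
  fs <- by_series(seq)
  set.seed(seed)
  frag <- c(fs$b_ions, fs$y_ions)
  keep <- runif(length(frag)) >= dropout
  mz <- c(frag[keep], fs$parent_MH)
  mz <- mz + rnorm(length(mz), 0, jitter_sd)
  peak_list(mz, tolerance = tolerance)
}
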