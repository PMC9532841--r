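# Per-residue property tables. Both hydrophobicity scales are in their
# published octanol/consensus units; the Fauchere-Pliska values are the ones
# used by the HeliQuest helical-wheel server and are the package default.

.FAUCHERE_PLISKA <- c(
  A =  0.31, R = -1.01, N = -0.60, D = -0.77, C =  1.54,
  Q = -0.22, E = -0.64, G =  0.00, H =  0.13, I =  1.80,
  L =  1.70, K = -0.99, M =  1.23, F =  1.79, P =  0.72,
  S = -0.04, T =  0.26, W =  2.25, Y =  0.96, V =  1.22
)

.EISENBERG <- c(
  A =  0.62, R = -2.53, N = -0.78, D = -0.90, C =  0.29,
  Q = -0.85, E = -0.74, G =  0.48, H = -0.40, I =  1.38,
  L =  1.06, K = -1.50, M =  0.64, F =  1.19, P =  0.12,
  S = -0.18, T = -0.05, W =  0.81, Y =  0.26, V =  1.08
)

#' Residue hydrophobicity scale
#'
#' Returns a named per-residue hydrophobicity map covering all 20 canonical
#' residues. `"fauchere-pliska"` (the HeliQuest default, octanol-partition
#' units) is the package default; the Eisenberg consensus scale is available
#' as an alternative.
#'
#' @param name Scale identifier: `"fauchere-pliska"` or `"eisenberg"`.
#' @return A `residue_scale`: named numeric vector of length 20 with
#'   attribute `scale_name`.
#' @export
hydrophobicity_scale <- function(name = c("fauchere-pliska", "eisenberg")) {
  name <- match.arg(name)
  values <- switch(name,
    "fauchere-pliska" = .FAUCHERE_PLISKA,
    "eisenberg" = .EISENBERG
  )
  structure(values[AA_ALPHABET], scale_name = name, class = "residue_scale")
}

#' @export
print.residue_scale <- function(x, ...) {
  cat(sprintf("<residue_scale> %s (20 residues)\n", attr(x, "scale_name")))
  print(unclass(x)[order(names(unclass(x)))])
  invisible(x)
}

scale_lookup <- function(scale, residues) {
  if (!all(residues %in% names(scale))) {
    stop("scale does not cover residue(s): ",
         paste(setdiff(residues, names(scale)), collapse = ", "))
  }
  unname(unclass(scale)[residues])
}

# IUPAC residue masses (Da). "Residue" = amino acid minus one water.
.MASS_MONO <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276, V =  99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.MASS_AVG <- c(
  G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167, V =  99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

#' Residue mass table and constants
#'
#' Standard IUPAC average and monoisotopic residue masses together with the
#' water and proton constants used throughout the mass/fragment calculus.
#' C-terminal amidation replaces the carboxyl OH by NH2: -0.98402 Da
#' monoisotopic, -0.98476 Da average.
#'
#' @return List with `average`, `monoisotopic` (named numeric, 20 residues),
#'   `water_avg`, `water_mono`, `proton`, `amide_corr_mono`,
#'   `amide_corr_avg`.
#' @export
mass_table <- function() {
  list(
    average        = .MASS_AVG[AA_ALPHABET],
    monoisotopic   = .MASS_MONO[AA_ALPHABET],
    water_avg      = 18.0153,
    water_mono     = 18.01056,
    proton         = 1.00728,
    amide_corr_mono = 0.98402,
    amide_corr_avg  = 0.98476
  )
}
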