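# Peptide mass calculus and singly charged b/y fragment ladders, as read off
# MALDI LIFT spectra: b_i = sum of N-terminal residues 1..i + proton;
# y_j = sum of C-terminal residues + water + proton. Complementarity
# b_i + y_(N-i) = [M+H]+ + proton holds exactly by construction.

#' Theoretical peptide masses
#'
#' Average and monoisotopic neutral masses plus the singly protonated
#' \[M+H\]+ monoisotopic ion. C-terminal amidation (the `c_term` flag on the
#' peptide) replaces OH by NH2 and lowers the monoisotopic mass by
#' 0.98402 Da (0.98476 Da average).
#'
#' @param seq A `peptide` or character scalar.
#' @return A `mass_result`: list with `M_avg`, `M_mono`, `MH_plus`, `c_term`.
#' @examples
#' peptide_mass(latarcin_peptides()$`Ltc-3a`) # M_avg 2484.0
#' @export
peptide_mass <- function(seq) {
  p <- as_peptide(seq)
  mt <- mass_table()
  m_avg <- sum(mt$average[p$residues]) + mt$water_avg
  m_mono <- sum(mt$monoisotopic[p$residues]) + mt$water_mono
  if (p$c_term == "amide") {
    m_avg <- m_avg - mt$amide_corr_avg
    m_mono <- m_mono - mt$amide_corr_mono
  }
  structure(
    list(M_avg = m_avg, M_mono = m_mono, MH_plus = m_mono + mt$proton,
         c_term = p$c_term),
    class = "mass_result"
  )
}

#' @export
print.mass_result <- function(x, ...) {
  cat(sprintf(
    "<mass_result> M_avg = %.2f Da  M_mono = %.3f Da  [M+H]+ = %.3f Da  (C-term %s)\n",
    x$M_avg, x$M_mono, x$MH_plus, x$c_term
  ))
  invisible(x)
}

#' Singly charged b/y fragment ion series
#'
#' Theoretical monoisotopic m/z ladders for the b (N-terminal) and y
#' (C-terminal) ion series, indexed 1..N-1, plus the parent \[M+H\]+.
#' Only singly charged, unmodified ions are produced (MALDI LIFT context);
#' a C-terminal amide shifts every y ion and the parent down by 0.98402 Da
#' and leaves b ions unchanged.
#'
#' @param seq A `peptide` or character scalar, length >= 2.
#' @return A `fragment_series`: list with `b_ions`, `y_ions` (numeric,
#'   names b1.., y1..), `parent_MH`, `sequence`, `name`.
#' @examples
#' by_series("LAKKLAKYLKKAL")$b_ions[1] # b1 = 114.091
#' @export
by_series <- function(seq) {
  p <- as_peptide(seq)
  n <- length(p$residues)
  if (n < 2L) stop("fragment series requires a peptide of length >= 2")
  mt <- mass_table()
  mono <- unname(mt$monoisotopic[p$residues])
  amide <- if (p$c_term == "amide") mt$amide_corr_mono else 0
  b <- cumsum(mono)[-n] + mt$proton
  y <- rev(cumsum(rev(mono))[-n]) + mt$water_mono + mt$proton - amide
  structure(
    list(
      b_ions = setNames(b, paste0("b", seq_len(n - 1L))),
      y_ions = setNames(rev(y), paste0("y", seq_len(n - 1L))),
      parent_MH = sum(mono) + mt$water_mono + mt$proton - amide,
      sequence = as.character(p),
      name = p$name
    ),
    class = "fragment_series"
  )
}

#' @export
print.fragment_series <- function(x, ...) {
  cat(sprintf("<fragment_series> %s  [M+H]+ = %.3f\n", x$name, x$parent_MH))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.fragment_series <- function(x, ...) {
  n1 <- length(x$b_ions)
  data.frame(
    position = seq_len(n1),
    b_mz = round(unname(x$b_ions), 3),
    y_mz = round(unname(x$y_ions), 3)
  )
}

#' Write a fragment ladder as TSV
#'
#' Columns: position, b_mz, y_mz; the parent ion goes in a comment header.
#'
#' @param series A `fragment_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragment_tsv <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s parent_MH=%.3f", series$name, series$parent_MH),
             con)
  write.table(as.data.frame(series), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Construct an observed peak list
#'
#' @param mz_values Numeric m/z values (sorted ascending on construction).
#' @param tolerance Matching tolerance in Da (default 0.5, wide enough for
#'   externally calibrated MALDI parental ions that deviate up to ~0.3 Da
#'   from theory).
#' @return A `peak_list`.
#' @export
peak_list <- function(mz_values, tolerance = 0.5) {
  if (tolerance <= 0) stop("tolerance must be positive")
  mz <- sort(as.numeric(mz_values))
  if (any(mz <= 0)) stop("m/z values must be positive")
  structure(list(mz_values = mz, tolerance = tolerance), class = "peak_list")
}

#' Read a peak list from text
#'
#' Accepts single-column text (m/z per line) or two-column TSV
#' (m/z, intensity); intensity is ignored. Lines starting with `#` are
#' skipped.
#'
#' @param path Input file.
#' @inheritParams peak_list
#' @return A `peak_list`.
#' @export
read_peaklist <- function(path, tolerance = 0.5) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) return(peak_list(numeric(0), tolerance))
  mz <- vapply(strsplit(lines, "[\t ,]+"), function(f) as.numeric(f[[1]]),
               numeric(1))
  peak_list(mz, tolerance)
}

#' Match observed peaks against a theoretical fragment series
#'
#' Assigns each observed peak to the nearest theoretical ion (b, y or
#' parent) within the peak list's tolerance, and reports per-series
#' coverage: the fraction of b and y ladder positions hit by at least one
#' observed peak.
#'
#' @param theory A `fragment_series`.
#' @param observed A `peak_list`.
#' @return A `peak_match`: list with `assignments` (data.frame: mz, ion,
#'   theoretical_mz, error_da), `b_coverage`, `y_coverage`, `parent_matched`,
#'   `n_matched`, `n_observed`.
#' @export
match_peaks <- function(theory, observed) {
  stopifnot(inherits(theory, "fragment_series"), inherits(observed, "peak_list"))
  ions <- c(theory$b_ions, theory$y_ions, parent = theory$parent_MH)
  mz <- observed$mz_values
  if (length(mz) == 0L) {
    assignments <- data.frame(mz = numeric(0), ion = character(0),
                              theoretical_mz = numeric(0),
                              error_da = numeric(0),
                              stringsAsFactors = FALSE)
  } else {
    idx <- vapply(mz, function(m) which.min(abs(ions - m)), integer(1))
    err <- mz - unname(ions[idx])
    hit <- abs(err) <= observed$tolerance
    assignments <- data.frame(
      mz = mz,
      ion = ifelse(hit, names(ions)[idx], NA_character_),
      theoretical_mz = ifelse(hit, unname(ions[idx]), NA_real_),
      error_da = ifelse(hit, err, NA_real_),
      stringsAsFactors = FALSE
    )
  }
  hit_ions <- unique(assignments$ion[!is.na(assignments$ion)])
  structure(
    list(
      assignments = assignments,
      b_coverage = mean(names(theory$b_ions) %in% hit_ions),
      y_coverage = mean(names(theory$y_ions) %in% hit_ions),
      parent_matched = "parent" %in% hit_ions,
      n_matched = sum(!is.na(assignments$ion)),
      n_observed = length(mz)
    ),
    class = "peak_match"
  )
}

#' @export
print.peak_match <- function(x, ...) {
  cat(sprintf(
    "<peak_match> %d/%d peaks assigned  b coverage %.0f%%  y coverage %.0f%%  parent %s\n",
    x$n_matched, x$n_observed, 100 * x$b_coverage, 100 * x$y_coverage,
    if (x$parent_matched) "matched" else "not matched"
  ))
  invisible(x)
}
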