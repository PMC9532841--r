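# Pairwise identity between designed analogs and the parent helix fragment.
# Equal-length pairs are compared position-wise without gaps (the designed
# analogs are all the same length as the parent region); unequal lengths go
# through a global alignment (match +1, mismatch 0, linear gap -1) before
# counting identities over alignment columns.

#' Percent identity between two peptides
#'
#' Equal-length sequences are compared column by column with no gaps.
#' Unequal-length sequences are first globally aligned (Needleman-Wunsch via
#' Biostrings, match +1, mismatch 0, linear gap penalty -1) and identity is
#' counted over alignment columns. The percentage is rounded half-up to one
#' decimal.
#'
#' @param a,b `peptide` objects or character scalars.
#' @return An `identity_result`: list with `matches`, `alignment_length`,
#'   `identity_pct`.
#' @examples
#' percent_identity("LAKKLKEYLEKLV", "MAKKLKEYMEKLK") # 76.9
#' @export
percent_identity <- function(a, b) {
  pa <- as_peptide(a)
  pb <- as_peptide(b)
  sa <- as.character(pa)
  sb <- as.character(pb)
  if (nchar(sa) == nchar(sb)) {
    ra <- pa$residues
    rb <- pb$residues
    matches <- sum(ra == rb)
    alen <- length(ra)
  } else {
    mat <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
    diag(mat) <- 1
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(sa), Biostrings::AAString(sb),
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 1,
      type = "global"
    )
    qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    qb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    matches <- sum(qa == qb & qa != "-")
    alen <- length(qa)
  }
  # round half-up to 1 decimal (base round() rounds half-to-even)
  pct <- floor(1000 * matches / alen + 0.5) / 10
  structure(
    list(matches = as.integer(matches), alignment_length = as.integer(alen),
         identity_pct = pct),
    class = "identity_result"
  )
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf("<identity_result> %d/%d columns identical (%.1f%%)\n",
              x$matches, x$alignment_length, x$identity_pct))
  invisible(x)
}

#' Position-wise substitutions between equal-length peptides
#'
#' Lists the 1-based positions where two equal-length sequences differ.
#' `offset` renumbers positions to the parent's full-sequence coordinates:
#' passing the 1-based start of the compared region on the parent (e.g. 5
#' for a region spanning parent residues 5-17) reports parent positions.
#'
#' @param a,b `peptide` objects or character scalars of equal length.
#' @param offset 1-based start position of the region on the parent
#'   (default 1 = report region-local positions).
#' @return data.frame with columns `position`, `from`, `to` (`from` is the
#'   residue in `b`, the reference; `to` the residue in `a`).
#' @examples
#' position_diffs("LIKKLKEYLKKLI", "MAKKLKEYMEKLK", offset = 5)
#' @export
position_diffs <- function(a, b, offset = 1L) {
  pa <- as_peptide(a)
  pb <- as_peptide(b)
  if (length(pa$residues) != length(pb$residues)) {
    stop("position_diffs requires equal-length sequences")
  }
  i <- which(pa$residues != pb$residues)
  data.frame(
    position = i + as.integer(offset) - 1L,
    from = pb$residues[i],
    to = pa$residues[i],
    stringsAsFactors = FALSE
  )
}
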