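#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef median rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

# Canonical one-letter amino acid alphabet. Everything in the package is
# restricted to these 20 codes; B/J/O/U/X/Z are rejected at validation time.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Validate and normalize a peptide sequence
#'
#' Uppercases a one-letter-code sequence, checks every residue against the
#' 20-canonical alphabet and returns a `peptide` object. The N-terminus is
#' always a free amine; the C-terminus is a free carboxylate by default
#' (`c_term = "free-acid"`), matching the chemistry assumed by the mass and
#' charge calculations, with `"amide"` available as a flag.
#'
#' @param seq Character scalar, one-letter amino acid codes (any case).
#' @param name Name for the peptide (free text).
#' @param c_term C-terminal chemistry, `"free-acid"` (default) or `"amide"`.
#' @return A `peptide` object: list with `name`, `residues` (character
#'   vector) and `c_term`.
#' @examples
#' validate_sequence("likklkeylkkli", name = "Lt-MAP2")
#' @export
validate_sequence <- function(seq, name = "peptide",
                              c_term = c("free-acid", "amide")) {
  c_term <- match.arg(c_term)
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("`seq` must be a single character string")
  }
  seq <- toupper(gsub("[[:space:]]", "", seq))
  if (nchar(seq) < 1L) {
    stop("empty sequence: a peptide must contain at least one residue")
  }
  residues <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!(residues %in% AA_ALPHABET))
  if (length(bad) > 0L) {
    stop(sprintf(
      "non-canonical residue '%s' at position %d in '%s'",
      residues[bad[1L]], bad[1L], name
    ))
  }
  structure(
    list(name = name, residues = residues, c_term = c_term),
    class = "peptide"
  )
}

#' Coerce to a peptide object
#'
#' Accepts a `peptide` as-is, or validates a character scalar.
#'
#' @param x A `peptide` or character scalar.
#' @param ... Passed to [validate_sequence()] for character input.
#' @return A `peptide` object.
#' @export
as_peptide <- function(x, ...) {
  if (inherits(x, "peptide")) return(x)
  validate_sequence(x, ...)
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf(
    "<peptide> %s  %s  (%d aa, C-term %s)\n",
    x$name, paste(x$residues, collapse = ""), length(x$residues), x$c_term
  ))
  invisible(x)
}

#' @export
length.peptide <- function(x) length(x$residues)

#' @export
as.character.peptide <- function(x, ...) paste(x$residues, collapse = "")

#' Parse peptides from FASTA
#'
#' Reads a multi-record FASTA file (or literal FASTA text), uppercases each
#' sequence and validates it against the canonical 20-letter alphabet.
#' Record order is preserved and each record yields one `peptide`.
#'
#' @param input Path to a FASTA file, or a character scalar containing FASTA
#'   text (detected by a leading `>`).
#' @param c_term C-terminal chemistry applied to every record.
#' @return Named list of `peptide` objects, in file order.
#' @export
parse_fasta <- function(input, c_term = c("free-acid", "amide")) {
  c_term <- match.arg(c_term)
  if (length(input) == 1L && grepl("^>", input)) {
    path <- tempfile(fileext = ".fa")
    on.exit(unlink(path), add = TRUE)
    writeLines(input, path)
  } else {
    path <- input
    if (!file.exists(path)) stop("FASTA file not found: ", path)
  }
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("empty FASTA: no records found")
  nms <- sub("\\s.*$", "", names(aas))
  out <- vector("list", length(aas))
  for (i in seq_along(aas)) {
    out[[i]] <- validate_sequence(as.character(aas[[i]]),
                                  name = nms[i], c_term = c_term)
  }
  names(out) <- nms
  out
}

#' Write peptides to FASTA
#'
#' @param peptides List of `peptide` objects (or character vector).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(peptides, path) {
  if (is.character(peptides)) {
    peptides <- lapply(seq_along(peptides), function(i) {
      nm <- names(peptides)[i]
      if (is.null(nm) || !nzchar(nm)) nm <- paste0("seq", i)
      validate_sequence(peptides[i], name = nm)
    })
  }
  seqs <- vapply(peptides, as.character, character(1))
  nms <- vapply(peptides, function(p) p$name, character(1))
  aas <- Biostrings::AAStringSet(setNames(seqs, nms))
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

#' Reference latarcin peptide set
#'
#' The parent spider-venom peptide latarcin-3a (from *Lachesana tarabaevi*)
#' and its three rationally designed Lt-MAP analogs, plus the 13-residue
#' helical core region (parent positions 5-17) that the analogs were designed
#' from. All carry free-acid C-termini.
#'
#' @param include_fragment Also include the `Ltc-3a-frag` core region record.
#' @return Named list of `peptide` objects.
#' @examples
#' latarcin_peptides()$`Lt-MAP3`
#' @export
latarcin_peptides <- function(include_fragment = FALSE) {
  seqs <- c(
    "Ltc-3a"  = "SWKSMAKKLKEYMEKLKQRA",
    "Lt-MAP1" = "LAKKLKEYLEKLV",
    "Lt-MAP2" = "LIKKLKEYLKKLI",
    "Lt-MAP3" = "LAKKLAKYLKKAL"
  )
  if (include_fragment) {
    seqs <- c(seqs, "Ltc-3a-frag" = "MAKKLKEYMEKLK")
  }
  out <- lapply(names(seqs), function(n) validate_sequence(seqs[[n]], name = n))
  setNames(out, names(seqs))
}
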