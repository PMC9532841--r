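# Independent oracles used by the property tests. These deliberately avoid
# the package's residue-mass table and moment code paths.

# Atomic composition of each residue (amino acid minus water), for the
# brute-force atom-count mass oracle.
.residue_atoms <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

.atom_mono <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                O = 15.9949146221, S = 31.97207069)
.atom_avg <- c(C = 12.0107, H = 1.00794, N = 14.0067, O = 15.9994,
               S = 32.065)

# Neutral peptide mass by summing atoms of every residue plus one water.
oracle_mass <- function(seq, kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  residues <- strsplit(seq, "")[[1]]
  atoms <- Reduce(`+`, .residue_atoms[residues])
  atoms[["H"]] <- atoms[["H"]] + 2
  atoms[["O"]] <- atoms[["O"]] + 1
  w <- if (kind == "mono") .atom_mono else .atom_avg
  sum(atoms * w[names(atoms)])
}

# Hydrophobic moment by direct complex-exponential summation.
oracle_muH <- function(seq, scale_values, delta = 100) {
  h <- scale_values[strsplit(seq, "")[[1]]]
  z <- sum(h * exp(1i * (seq_along(h) - 1) * delta * pi / 180))
  Mod(z) / length(h)
}

random_peptide <- function(min_len = 2, max_len = 30) {
  n <- sample(min_len:max_len, 1)
  paste(sample(ltmap:::AA_ALPHABET, n, replace = TRUE), collapse = "")
}

study_sequences <- function() {
  c("Ltc-3a"  = "SWKSMAKKLKEYMEKLKQRA",
    "Lt-MAP1" = "LAKKLKEYLEKLV",
    "Lt-MAP2" = "LIKKLKEYLKKLI",
    "Lt-MAP3" = "LAKKLAKYLKKAL",
    fragment  = "MAKKLKEYMEKLK")
}
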