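# Constrained analog design over a parent helix region: substitution classes
# applied on the helical wheel, a composition-divergence cap ("maximum 30%
# difference in amino acid composition", approximately three residues), a
# helix guard excluding Pro/Gly introductions, and ranking by net-charge and
# hydrophobic-moment objectives.

#' Extract a contiguous region of a parent peptide
#'
#' 1-based inclusive coordinates; provenance (parent name and offsets) is
#' kept in the region's name.
#'
#' @param parent A `peptide` or character scalar.
#' @param start,end 1-based inclusive bounds.
#' @return A `peptide` named `<parent>[start-end]` with attribute `offset`
#'   (= `start`).
#' @examples
#' extract_region(latarcin_peptides()$`Ltc-3a`, 5, 17) # MAKKLKEYMEKLK
#' @export
extract_region <- function(parent, start, end) {
  p <- as_peptide(parent)
  n <- length(p$residues)
  if (start < 1L || end > n || start > end) {
    stop(sprintf("region [%d, %d] out of range for a %d-residue peptide (1-based)",
                 start, end, n))
  }
  out <- validate_sequence(
    paste(p$residues[start:end], collapse = ""),
    name = sprintf("%s[%d-%d]", p$name, start, end),
    c_term = p$c_term
  )
  attr(out, "offset") <- as.integer(start)
  out
}

#' Composition divergence between equal-length peptides
#'
#' A position-independent multiset distance on amino-acid composition:
#' 1 - (sum over residue types of min(count_a, count_b)) / length. Moving a
#' residue to another position costs nothing; swapping a residue type for a
#' new one costs 1/length.
#'
#' @param a,b `peptide` objects or character scalars of equal length.
#' @return Fraction in \[0, 1\].
#' @examples
#' composition_divergence("LAKKLKEYLEKLV", "MAKKLKEYMEKLK") # 3/13
#' @export
composition_divergence <- function(a, b) {
  pa <- as_peptide(a)
  pb <- as_peptide(b)
  n <- length(pa$residues)
  if (n != length(pb$residues)) {
    stop("composition_divergence requires equal-length sequences")
  }
  ca <- table(factor(pa$residues, levels = AA_ALPHABET))
  cb <- table(factor(pb$residues, levels = AA_ALPHABET))
  1 - sum(pmin(ca, cb)) / n
}

#' Substitution classes used for the Lt-MAP design
#'
#' The from -> to residue classes behind the published analogs: Met and the
#' helix-face alanines go to aliphatic Leu/Ile, acidic Glu goes to Lys
#' (charge increase), and Lys/Leu may be locally rearranged with small
#' aliphatics to reshape the hydrophobic face.
#'
#' @return Named list mapping a from-residue to its allowed replacement set.
#' @export
ltmap_substitution_rules <- function() {
  list(
    M = "L",
    A = c("L", "I"),
    E = "K",
    K = c("A", "I", "L", "V"),
    L = c("A", "L")
  )
}

#' Design constraints for analog enumeration
#'
#' @param region Optional `(start, end)` on the parent (informational;
#'   enumeration runs on the extracted region).
#' @param max_divergence Composition-divergence cap (default 0.30).
#' @param substitution_rules Named list: from-residue -> character vector of
#'   allowed replacements (see [ltmap_substitution_rules()]).
#' @param divergence_mode `"tolerant"` (default) admits one composition unit
#'   beyond `floor(max_divergence * N)` changed units; `"strict"` enforces
#'   divergence <= max_divergence exactly.
#' @param helix_guard Residues that must not be introduced in the designed
#'   region (default Pro and Gly, the classical helix breakers).
#' @param h_band Acceptable mean-hydrophobicity band `(min, max)` for the
#'   scoring penalty (default `c(0, 0.6)`).
#' @param weights Named numeric: `z` and `muh` weights plus `h_penalty`
#'   (default Z-dominant: z = 1, muh = 0.5, h_penalty = 1).
#' @return A `design_constraints` list.
#' @export
design_constraints <- function(region = NULL,
                               max_divergence = 0.30,
                               substitution_rules = ltmap_substitution_rules(),
                               divergence_mode = c("tolerant", "strict"),
                               helix_guard = c("P", "G"),
                               h_band = c(0, 0.6),
                               weights = c(z = 1, muh = 0.5, h_penalty = 1)) {
  divergence_mode <- match.arg(divergence_mode)
  if (max_divergence <= 0 || max_divergence > 1) {
    stop("max_divergence must be in (0, 1]")
  }
  stopifnot(all(c("z", "muh", "h_penalty") %in% names(weights)))
  structure(
    list(region = region, max_divergence = max_divergence,
         substitution_rules = substitution_rules,
         divergence_mode = divergence_mode, helix_guard = helix_guard,
         h_band = h_band, weights = weights),
    class = "design_constraints"
  )
}

#' Score an analog candidate against the parent descriptors
#'
#' Weighted sum of the net-charge gain and hydrophobic-moment gain over the
#' parent, minus a penalty for mean hydrophobicity outside the configured
#' band: `w_z * (Z - Z_p) + w_muh * (muH - muH_p) - w_h * dist(H, band)`.
#' Higher is better; the parent itself scores 0 when its own H lies in the
#' band.
#'
#' @param candidate A `descriptor_set` (or a `peptide`, described on the
#'   fly).
#' @param parent A `descriptor_set` for the parent region.
#' @param weights,h_band As in [design_constraints()].
#' @return Numeric score.
#' @export
score_candidate <- function(candidate, parent,
                            weights = c(z = 1, muh = 0.5, h_penalty = 1),
                            h_band = c(0, 0.6)) {
  if (!inherits(candidate, "descriptor_set")) {
    candidate <- describe_peptide(candidate)
  }
  stopifnot(inherits(parent, "descriptor_set"))
  h_out <- pmax(0, h_band[1] - candidate$H, candidate$H - h_band[2])
  p_out <- pmax(0, h_band[1] - parent$H, parent$H - h_band[2])
  unname(
    weights["z"] * (candidate$Z - parent$Z) +
      weights["muh"] * (candidate$muH - parent$muH) -
      weights["h_penalty"] * (h_out - p_out)
  )
}

# Per-position option sets under the substitution rules and helix guard.
.position_options <- function(residues, rules, helix_guard) {
  lapply(residues, function(r) {
    opts <- unique(c(r, rules[[r]]))
    # guard applies to introduced residues only; the parent's own residue
    # at that position always stays available
    opts[opts == r | !(opts %in% helix_guard)]
  })
}

#' Enumerate analog candidates under design constraints
#'
#' Applies the substitution rules at any subset of positions of the parent
#' region, filters by the composition-divergence cap and helix guard, scores
#' every feasible candidate against the parent's descriptors and returns the
#' top `limit`, deterministically ordered (score, then net charge, then
#' hydrophobic moment, then lower divergence, then sequence string).
#'
#' When the rule-induced search space has at most `max_space` candidates
#' (default 10^6) the enumeration is exhaustive; larger spaces are explored
#' by seeded uniform sampling of `n_sample` candidates with the same filters.
#'
#' @param parent_region A `peptide` or character scalar (the design region).
#' @param constraints A [design_constraints()] object.
#' @param limit Maximum number of candidates returned (default 50).
#' @param seed Integer seed (only consulted on the sampling path; the
#'   exhaustive path is deterministic by construction).
#' @param scale Hydrophobicity scale for descriptor computation.
#' @param max_space Exhaustive-enumeration cutoff.
#' @param n_sample Number of sampled candidates beyond the cutoff.
#' @return data.frame of class `analog_candidates` with columns `sequence`,
#'   `n_substitutions`, `composition_divergence`, `Z`, `H`, `H_pct`, `muH`,
#'   `score`; attribute `n_feasible` carries the total feasible-set size and
#'   `feasible_sequences` the full feasible set (character).
#' @examples
#' frag <- extract_region(latarcin_peptides()$`Ltc-3a`, 5, 17)
#' head(enumerate_analogs(frag, design_constraints(), limit = 5))
#' @export
enumerate_analogs <- function(parent_region,
                              constraints = design_constraints(),
                              limit = 50L, seed = 1L,
                              scale = hydrophobicity_scale(),
                              max_space = 1e6, n_sample = 2e5) {
  p <- as_peptide(parent_region)
  res <- p$residues
  n <- length(res)
  opts <- .position_options(res, constraints$substitution_rules,
                            constraints$helix_guard)
  n_opts <- lengths(opts)
  total <- prod(n_opts)

  if (total <= max_space) {
    # mixed-radix expansion of 0..total-1 over per-position option counts
    idx <- seq_len(total) - 1
    mat <- matrix("", nrow = total, ncol = n)
    base <- 1
    for (j in seq_len(n)) {
      mat[, j] <- opts[[j]][(idx %/% base) %% n_opts[j] + 1]
      base <- base * n_opts[j]
    }
  } else {
    set.seed(seed)
    mat <- matrix("", nrow = n_sample, ncol = n)
    for (j in seq_len(n)) {
      mat[, j] <- sample(opts[[j]], n_sample, replace = TRUE)
    }
    mat <- mat[!duplicated(apply(mat, 1, paste, collapse = "")), ,
               drop = FALSE]
  }

  # composition divergence against the parent, vectorized over candidates
  types <- unique(c(res, unlist(opts)))
  parent_counts <- table(factor(res, levels = types))
  shared <- numeric(nrow(mat))
  counts <- matrix(0L, nrow(mat), length(types),
                   dimnames = list(NULL, types))
  for (t in types) {
    counts[, t] <- rowSums(mat == t)
    shared <- shared + pmin(counts[, t], parent_counts[[t]])
  }
  units_changed <- n - shared
  max_units <- if (constraints$divergence_mode == "tolerant") {
    floor(constraints$max_divergence * n) + 1L
  } else {
    floor(constraints$max_divergence * n + 1e-9)
  }
  feasible <- units_changed <= max_units
  mat <- mat[feasible, , drop = FALSE]
  counts <- counts[feasible, , drop = FALSE]
  units_changed <- units_changed[feasible]
  if (nrow(mat) == 0L) {
    out <- data.frame(sequence = character(0), n_substitutions = integer(0),
                      composition_divergence = numeric(0), Z = integer(0),
                      H = numeric(0), H_pct = integer(0), muH = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE)
    attr(out, "n_feasible") <- 0L
    attr(out, "feasible_sequences") <- character(0)
    class(out) <- c("analog_candidates", class(out))
    return(out)
  }

  # vectorized descriptors over the feasible set
  zpos <- rowSums(counts[, intersect(c("K", "R"), types), drop = FALSE])
  zneg <- rowSums(counts[, intersect(c("D", "E"), types), drop = FALSE])
  Z <- as.integer(zpos - zneg)
  hmat <- matrix(unclass(scale)[mat], nrow = nrow(mat))
  H <- round(rowMeans(hmat), 3)
  H_pct <- as.integer(
    100 * rowSums(counts[, intersect(HYDROPHOBIC_SET, types), drop = FALSE]) / n
  )
  ang <- (seq_len(n) - 1) * 100 * pi / 180
  muH <- round(sqrt((hmat %*% cos(ang))^2 + (hmat %*% sin(ang))^2)[, 1] / n, 3)
  n_subs <- rowSums(mat != matrix(res, nrow(mat), n, byrow = TRUE))
  divergence <- units_changed / n

  parent_desc <- describe_peptide(p, scale = scale)
  w <- constraints$weights
  band <- constraints$h_band
  h_out <- pmax(0, band[1] - H, H - band[2])
  p_out <- pmax(0, band[1] - parent_desc$H, parent_desc$H - band[2])
  score <- unname(w["z"] * (Z - parent_desc$Z) +
                    w["muh"] * (muH - parent_desc$muH) -
                    w["h_penalty"] * (h_out - p_out))

  seqs <- apply(mat, 1, paste, collapse = "")
  ord <- order(-score, -Z, -muH, divergence, seqs, method = "radix")
  keep <- ord[seq_len(min(limit, length(ord)))]
  out <- data.frame(
    sequence = seqs[keep],
    n_substitutions = as.integer(n_subs[keep]),
    composition_divergence = round(divergence[keep], 4),
    Z = Z[keep], H = H[keep], H_pct = H_pct[keep], muH = muH[keep],
    score = round(score[keep], 4),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_feasible") <- length(seqs)
  attr(out, "feasible_sequences") <- seqs
  attr(out, "parent") <- as.character(p)
  class(out) <- c("analog_candidates", class(out))
  out
}
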