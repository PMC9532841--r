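# Physicochemical descriptor calculus for amphipathic helical peptides:
# net charge, mean hydrophobicity, hydrophobic-residue percentage, Eisenberg
# hydrophobic moment, and the helical-wheel projection behind it.

# Residues counted as hydrophobic for the H% descriptor.
HYDROPHOBIC_SET <- c("A", "C", "F", "I", "L", "M", "V", "W")

#' Peptide net charge at neutral pH
#'
#' The default side-chains-only model counts Lys and Arg as +1, Asp and Glu
#' as -1, and His as 0. The include-termini variant additionally counts the
#' free N-terminal amine as +1; the free-acid C-terminal carboxylate is
#' counted as -1 only when `include_c_term = TRUE` (an amidated C-terminus is
#' always neutral).
#'
#' @param seq A `peptide` or character scalar.
#' @param model `"side-chains"` (default) or `"include-termini"`.
#' @param include_c_term For `"include-termini"`, also count the free-acid
#'   C-terminus as -1. Default `FALSE`.
#' @return Integer net charge.
#' @examples
#' net_charge("LAKKLAKYLKKAL") # +5
#' @export
net_charge <- function(seq, model = c("side-chains", "include-termini"),
                       include_c_term = FALSE) {
  model <- match.arg(model)
  p <- as_peptide(seq)
  z <- sum(p$residues %in% c("K", "R")) - sum(p$residues %in% c("D", "E"))
  if (model == "include-termini") {
    z <- z + 1L
    if (include_c_term && p$c_term == "free-acid") z <- z - 1L
  }
  as.integer(z)
}

#' Mean per-residue hydrophobicity
#'
#' Arithmetic mean of the per-residue scale values, in the scale's units.
#'
#' @inheritParams net_charge
#' @param scale A `residue_scale` (default Fauchere-Pliska).
#' @param digits Rounding for the reported value (3 decimals by convention;
#'   `NA` for no rounding).
#' @return Numeric mean hydrophobicity.
#' @examples
#' mean_hydrophobicity("SWKSMAKKLKEYMEKLKQRA") # 0.058
#' @export
mean_hydrophobicity <- function(seq, scale = hydrophobicity_scale(),
                                digits = 3) {
  p <- as_peptide(seq)
  h <- mean(scale_lookup(scale, p$residues))
  if (!is.na(digits)) h <- round(h, digits)
  h
}

#' Hydrophobic-residue percentage
#'
#' 100 x (number of residues in \{A, C, F, I, L, M, V, W\}) / length,
#' truncated toward zero to an integer (53.8 reports as 53).
#'
#' @inheritParams net_charge
#' @return Integer percentage in \[0, 100\].
#' @examples
#' hydrophobic_fraction("LAKKLAKYLKKAL") # 53
#' @export
hydrophobic_fraction <- function(seq) {
  p <- as_peptide(seq)
  as.integer(100 * sum(p$residues %in% HYDROPHOBIC_SET) / length(p$residues))
}

#' Eisenberg hydrophobic moment
#'
#' Length-normalized magnitude of the vector sum of per-residue
#' hydrophobicities placed at successive helical angles:
#' \deqn{\mu_H = \frac{1}{N}\sqrt{\left(\sum_n h_n \cos\delta(n-1)\right)^2 +
#'   \left(\sum_n h_n \sin\delta(n-1)\right)^2}}
#' with \eqn{\delta} = 100 degrees/residue for an ideal alpha helix
#' (3.6 residues/turn).
#'
#' @inheritParams mean_hydrophobicity
#' @param delta Angular step in degrees per residue (default 100).
#' @return Numeric hydrophobic moment (scale units per residue).
#' @examples
#' hydrophobic_moment("LIKKLKEYLKKLI") # 0.839
#' @export
hydrophobic_moment <- function(seq, scale = hydrophobicity_scale(),
                               delta = 100, digits = 3) {
  p <- as_peptide(seq)
  h <- scale_lookup(scale, p$residues)
  ang <- (seq_along(h) - 1) * delta * pi / 180
  mu <- sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / length(h)
  if (!is.na(digits)) mu <- round(mu, digits)
  mu
}

#' Helical-wheel projection
#'
#' Places residue n at angle ((n-1) * delta) mod 360 on the wheel, flags
#' hydrophobic residues, and reports the hydrophobic face as the half-plane
#' arc perpendicular to the hydrophobic-moment vector (the 180-degree arc
#' centered on the moment direction).
#'
#' @inheritParams hydrophobic_moment
#' @return A `wheel_projection`: list with `wheel` (data.frame: index,
#'   residue, angle, hydrophobic), `delta`, `mu_angle` (degrees, direction of
#'   the moment vector) and `face_arc` (start/end angles of the hydrophobic
#'   face, degrees).
#' @export
wheel_projection <- function(seq, scale = hydrophobicity_scale(),
                             delta = 100) {
  p <- as_peptide(seq)
  n <- length(p$residues)
  angle <- ((seq_len(n) - 1) * delta) %% 360
  h <- scale_lookup(scale, p$residues)
  ang_rad <- (seq_len(n) - 1) * delta * pi / 180
  mu_x <- sum(h * cos(ang_rad))
  mu_y <- sum(h * sin(ang_rad))
  mu_angle <- (atan2(mu_y, mu_x) * 180 / pi) %% 360
  structure(
    list(
      wheel = data.frame(
        index = seq_len(n),
        residue = p$residues,
        angle = angle,
        hydrophobic = p$residues %in% HYDROPHOBIC_SET,
        stringsAsFactors = FALSE
      ),
      delta = delta,
      mu_angle = mu_angle,
      face_arc = c(start = (mu_angle - 90) %% 360, end = (mu_angle + 90) %% 360)
    ),
    class = "wheel_projection"
  )
}

#' @export
print.wheel_projection <- function(x, ...) {
  cat(sprintf(
    "<wheel_projection> %d residues, delta = %g deg, face centered at %.1f deg\n",
    nrow(x$wheel), x$delta, x$mu_angle
  ))
  print(x$wheel)
  invisible(x)
}

#' Is a wheel angle on the hydrophobic face?
#'
#' Membership of an angle in the face arc of a [wheel_projection()] (the
#' half-plane around the hydrophobic-moment direction).
#'
#' @param projection A `wheel_projection`.
#' @param angle Angle(s) in degrees.
#' @return Logical vector.
#' @export
on_hydrophobic_face <- function(projection, angle) {
  d <- (angle - projection$mu_angle) %% 360
  d <- pmin(d, 360 - d)
  d <= 90
}

#' Full descriptor set for a peptide
#'
#' Bundles net charge, mean hydrophobicity, hydrophobic percentage and
#' hydrophobic moment with the conventions used to compute them.
#'
#' @inheritParams hydrophobic_moment
#' @param charge_model Charge model passed to [net_charge()].
#' @return A `descriptor_set`: list with `name`, `sequence`, `length`, `Z`,
#'   `H`, `H_pct`, `muH`, `scale_name`, `charge_model`, `delta`.
#' @examples
#' describe_peptide(latarcin_peptides()$`Lt-MAP1`)
#' @export
describe_peptide <- function(seq, scale = hydrophobicity_scale(),
                             charge_model = c("side-chains",
                                              "include-termini"),
                             delta = 100) {
  charge_model <- match.arg(charge_model)
  p <- as_peptide(seq)
  structure(
    list(
      name = p$name,
      sequence = as.character(p),
      length = length(p$residues),
      Z = net_charge(p, model = charge_model),
      H = mean_hydrophobicity(p, scale = scale),
      H_pct = hydrophobic_fraction(p),
      muH = hydrophobic_moment(p, scale = scale, delta = delta),
      scale_name = attr(scale, "scale_name"),
      charge_model = charge_model,
      delta = delta
    ),
    class = "descriptor_set"
  )
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf(
    "<descriptor_set> %s (%d aa)  Z = %+d  H = %.3f  H%% = %d  muH = %.3f  [%s, delta %g]\n",
    x$name, x$length, x$Z, x$H, x$H_pct, x$muH, x$scale_name, x$delta
  ))
  invisible(x)
}

#' Descriptor table for a peptide collection
#'
#' Applies [describe_peptide()] and [peptide_mass()] to each peptide and
#' returns one row per peptide with the fixed column order used by
#' [write_descriptor_tsv()].
#'
#' @param peptides List of `peptide` objects (e.g. [latarcin_peptides()]).
#' @inheritParams describe_peptide
#' @return data.frame with columns name, sequence, length, Z, H, H_pct, muH,
#'   M_avg, M_mono, MH_plus.
#' @export
descriptor_table <- function(peptides, scale = hydrophobicity_scale(),
                             charge_model = "side-chains", delta = 100) {
  rows <- lapply(peptides, function(p) {
    d <- describe_peptide(p, scale = scale, charge_model = charge_model,
                          delta = delta)
    m <- peptide_mass(p)
    data.frame(
      name = d$name, sequence = d$sequence, length = d$length,
      Z = d$Z, H = d$H, H_pct = d$H_pct, muH = d$muH,
      M_avg = round(m$M_avg, 2), M_mono = round(m$M_mono, 3),
      MH_plus = round(m$MH_plus, 3),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a descriptor table as TSV
#'
#' @param table data.frame from [descriptor_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
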