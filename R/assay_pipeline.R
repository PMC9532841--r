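# Reduction of plate-format assay data to endpoints: MIC/MBC/MBIC calling
# on normalized growth signal, hemolysis and viability percentages against
# bracketed controls, the 60%-cell-death activity rule, and 4-parameter
# logistic EC50 fitting.

#' Construct a plate assay
#'
#' A concentration-by-replicate absorbance matrix with growth-control and
#' sterile-blank wells. Concentrations must be strictly decreasing (the
#' conventional serial-dilution layout, e.g. 128, 64, ..., 4 ug/ml).
#'
#' @param concentrations Strictly decreasing numeric vector, ug/ml.
#' @param readings Numeric matrix, rows = concentrations, cols = replicates.
#' @param growth_control Replicate readings with organism but no compound.
#' @param sterile_blank Replicate readings, medium only.
#' @param wavelength Reading wavelength in nm (600 for growth, 595 for
#'   crystal violet).
#' @return A `plate_assay` object.
#' @export
plate_assay <- function(concentrations, readings, growth_control,
                        sterile_blank, wavelength = 600) {
  readings <- as.matrix(readings)
  if (length(concentrations) < 2L) {
    stop("a plate needs at least 2 concentrations")
  }
  if (any(diff(concentrations) >= 0)) {
    stop("concentrations must be strictly decreasing")
  }
  if (nrow(readings) != length(concentrations)) {
    stop("readings must have one row per concentration")
  }
  if (any(readings < 0) || any(growth_control < 0) || any(sterile_blank < 0)) {
    stop("absorbance readings must be non-negative")
  }
  structure(
    list(concentrations = as.numeric(concentrations), readings = readings,
         growth_control = as.numeric(growth_control),
         sterile_blank = as.numeric(sterile_blank),
         wavelength = wavelength),
    class = "plate_assay"
  )
}

#' @export
print.plate_assay <- function(x, ...) {
  cat(sprintf(
    "<plate_assay> %d concentrations (%g-%g ug/ml) x %d replicates @ %g nm\n",
    length(x$concentrations), max(x$concentrations), min(x$concentrations),
    ncol(x$readings), x$wavelength
  ))
  invisible(x)
}

# Normalized growth fraction per concentration, clamped to [0, 1].
growth_fraction <- function(plate) {
  g0 <- mean(plate$growth_control)
  b0 <- mean(plate$sterile_blank)
  if (g0 <= b0) {
    stop("uninterpretable plate: growth control does not exceed sterile blank")
  }
  pmin(1, pmax(0, (rowMeans(plate$readings) - b0) / (g0 - b0)))
}

# Shared endpoint rule: lowest concentration whose growth signal is at or
# below threshold AND for which every higher tested concentration also is
# (monotone-from-the-top, robust to non-monotone noise below the endpoint).
.call_endpoint <- function(concentrations, inhibited, kind) {
  run <- cumprod(inhibited) # 1 while inhibited from the top, 0 after
  k <- sum(run)
  if (k == 0L) {
    value <- NA_real_
    label <- paste0(">", max(concentrations))
    censored <- TRUE
  } else {
    value <- concentrations[k]
    label <- format(value, trim = TRUE)
    censored <- FALSE
  }
  structure(
    list(kind = kind, value = value, censored = censored, label = label,
         tested = concentrations),
    class = "assay_endpoint"
  )
}

#' @export
print.assay_endpoint <- function(x, ...) {
  cat(sprintf("<assay_endpoint> %s = %s ug/ml\n", x$kind, x$label))
  invisible(x)
}

#' Call the minimum inhibitory concentration from a microdilution plate
#'
#' Growth fraction per concentration is
#' `(mean reading - mean blank) / (mean growth control - mean blank)`,
#' clamped to \[0, 1\]. The MIC is the lowest tested concentration with
#' growth fraction at or below `inhibition_threshold` such that every higher
#' tested concentration also inhibits; if no concentration qualifies the
#' endpoint is censored as `">max"`.
#'
#' @param plate A [plate_assay()].
#' @param inhibition_threshold Growth fraction regarded as "no significant
#'   growth" (default 0.10).
#' @return An `assay_endpoint` (kind "MIC").
#' @export
call_mic <- function(plate, inhibition_threshold = 0.10) {
  stopifnot(inherits(plate, "plate_assay"))
  g <- growth_fraction(plate)
  .call_endpoint(plate$concentrations, g <= inhibition_threshold, "MIC")
}

#' Call the minimum bactericidal concentration from colony counts
#'
#' Lowest concentration with zero colonies after plating, with the same
#' monotone-from-the-top rule as [call_mic()]; censored `">max"` when every
#' count is positive, and the lowest tested concentration when all are zero.
#'
#' @param concentrations Strictly decreasing numeric vector, ug/ml.
#' @param colony_counts Non-negative counts, one per concentration.
#' @return An `assay_endpoint` (kind "MBC").
#' @export
call_mbc <- function(concentrations, colony_counts) {
  if (length(concentrations) != length(colony_counts)) {
    stop("one colony count per concentration required")
  }
  if (any(diff(concentrations) >= 0)) {
    stop("concentrations must be strictly decreasing")
  }
  if (any(colony_counts < 0)) stop("colony counts must be non-negative")
  .call_endpoint(concentrations, colony_counts == 0, "MBC")
}

#' Call the minimum biofilm inhibitory concentration
#'
#' Applies the [call_mic()] normalized-threshold rule to a crystal-violet
#' biofilm plate read at 595 nm.
#'
#' @inheritParams call_mic
#' @return An `assay_endpoint` (kind "MBIC").
#' @export
call_mbic <- function(plate, inhibition_threshold = 0.10) {
  stopifnot(inherits(plate, "plate_assay"))
  g <- growth_fraction(plate)
  .call_endpoint(plate$concentrations, g <= inhibition_threshold, "MBIC")
}

#' Percent hemolysis against blank and Triton controls
#'
#' `100 * (A - A_blank) / (A_triton - A_blank)` clamped to \[0, 100\]:
#' erythrocytes in PBS define 0% and Triton X-100 lysis defines 100%.
#'
#' @param A Sample absorbance (vectorized), e.g. A415.
#' @param A_blank Mean blank (zero-hemolysis) absorbance.
#' @param A_triton Mean Triton (full-lysis) absorbance.
#' @return Percent hemolysis in \[0, 100\].
#' @export
hemolysis_percent <- function(A, A_blank, A_triton) {
  if (A_triton <= A_blank) {
    stop("degenerate controls: Triton reading must exceed blank")
  }
  pmin(100, pmax(0, 100 * (A - A_blank) / (A_triton - A_blank)))
}

#' Percent viability from a background-corrected metabolic signal
#'
#' `100 * (treated - blank) / (control - blank)`, clamped below at 0 (values
#' above 100 are possible and kept). Cell death percent is
#' `100 - viability`.
#'
#' @param treated Treated-well reading(s) (vectorized).
#' @param control Mean untreated-control reading.
#' @param blank Mean medium-only reading.
#' @return Percent viability, >= 0.
#' @export
viability_percent <- function(treated, control, blank) {
  if (control <= blank) {
    stop("degenerate controls: untreated control must exceed blank")
  }
  pmax(0, 100 * (treated - blank) / (control - blank))
}

#' Antitumor activity flag
#'
#' A compound is flagged active when it produces at least 60% cell death
#' (the screening rule adapted from NCI natural-product protocols).
#'
#' @param death_pct Percent cell death (100 - viability), >= 0.
#' @return Logical.
#' @export
activity_flag <- function(death_pct) {
  if (any(death_pct < 0)) stop("death percent must be non-negative")
  death_pct >= 60
}

# 4PL with hill > 0 decreasing in x (viability curves); hill < 0 increasing
# (hemolysis curves).
.fourpl <- function(x, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (x / ec50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom) / (1 + (x / EC50)^hill)` via
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]), with EC50 parameterized on
#' the log scale. Positive hill gives a response decreasing in
#' concentration (viability), negative hill an increasing one (hemolysis);
#' both signs are tried and the better fit kept unless `hill_sign` is
#' forced. Asymptotes may be fixed (e.g. `bottom = 0`, `top = 100`).
#'
#' @param concentrations Numeric, >= 4 distinct positive values.
#' @param responses Numeric responses in percent, same length.
#' @param bottom,top Fix an asymptote at this value, or `NULL` (default) to
#'   estimate it.
#' @param hill_sign Force the hill-slope sign: `"auto"` (default),
#'   `"decreasing"` or `"increasing"`.
#' @return A `dose_response_fit`: list with `EC50`, `hill`, `top`, `bottom`,
#'   `rss`, `fitted`, `data`.
#' @examples
#' x <- c(128, 64, 32, 16, 8, 4)
#' y <- 100 / (1 + (x / 30)^1.5)
#' fit_dose_response(x, y)$EC50 # ~30
#' @export
fit_dose_response <- function(concentrations, responses,
                              bottom = NULL, top = NULL,
                              hill_sign = c("auto", "decreasing",
                                            "increasing")) {
  hill_sign <- match.arg(hill_sign)
  x <- as.numeric(concentrations)
  y <- as.numeric(responses)
  if (length(x) != length(y)) stop("concentrations and responses differ in length")
  if (length(unique(x)) < 4L) {
    stop("dose-response fitting needs >= 4 distinct concentrations")
  }
  if (any(x <= 0)) stop("concentrations must be positive")
  if (diff(range(y)) < 1e-8) {
    stop("non-convergence: responses are constant, EC50 is unidentifiable")
  }

  fix_b <- !is.null(bottom)
  fix_t <- !is.null(top)
  b0 <- if (fix_b) bottom else min(y)
  t0 <- if (fix_t) top else max(y)

  try_fit <- function(h0, lec0) {
    start <- list(lec50 = lec0, hill = h0)
    lower <- c(lec50 = log(min(x)) - log(100), hill = if (h0 > 0) 0.05 else -20)
    upper <- c(lec50 = log(max(x)) + log(100), hill = if (h0 > 0) 20 else -0.05)
    if (!fix_b) {
      start$b <- b0; lower <- c(lower, b = -Inf); upper <- c(upper, b = Inf)
    }
    if (!fix_t) {
      start$t <- t0; lower <- c(lower, t = -Inf); upper <- c(upper, t = Inf)
    }
    form <- sprintf(
      "y ~ %s + (%s - %s) / (1 + (x / exp(lec50))^hill)",
      if (fix_b) "bottom" else "b",
      if (fix_t) "top" else "t",
      if (fix_b) "bottom" else "b"
    )
    env <- list(x = x, y = y)
    if (fix_b) env$bottom <- bottom
    if (fix_t) env$top <- top
    tryCatch(
      minpack.lm::nlsLM(stats::as.formula(form), data = env, start = start,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
  }

  hill_starts <- switch(hill_sign,
    auto = c(0.8, 1.5, 4, -0.8, -1.5, -4),
    decreasing = c(0.8, 1.5, 4),
    increasing = c(-0.8, -1.5, -4)
  )
  lec_starts <- unique(c(mean(log(range(x))), log(stats::quantile(x, c(0.25, 0.75)))))
  grid <- expand.grid(h0 = hill_starts, lec0 = lec_starts)
  fits <- Filter(Negate(is.null),
                 Map(try_fit, grid$h0, grid$lec0))
  if (length(fits) == 0L) {
    stop("non-convergence: 4PL fit failed (n = ", length(x),
         ", response range ", signif(diff(range(y)), 3), ")")
  }
  rss <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- coef(best)
  b_hat <- if (fix_b) bottom else unname(cf["b"])
  t_hat <- if (fix_t) top else unname(cf["t"])
  # orient so that `top` is the zero-dose asymptote and bottom <= top
  if (b_hat > t_hat) {
    tmp <- b_hat; b_hat <- t_hat; t_hat <- tmp
  }
  structure(
    list(
      EC50 = exp(unname(cf["lec50"])),
      hill = unname(cf["hill"]),
      top = t_hat, bottom = b_hat,
      rss = min(rss),
      fitted = stats::fitted(best),
      data = data.frame(concentration = x, response = y)
    ),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> EC50 = %.3g  hill = %.2f  top = %.1f  bottom = %.1f  (rss %.3g)\n",
    x$EC50, x$hill, x$top, x$bottom, x$rss
  ))
  invisible(x)
}

#' Write plate assay to CSV (+ JSON sidecar)
#'
#' Rows are labelled by concentration plus `growth_control` and
#' `sterile_blank`; a small JSON sidecar (`<path>.json`) records wavelength
#' and units.
#'
#' @param plate A `plate_assay`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  nrep <- ncol(plate$readings)
  pad <- function(v) c(v, rep(NA, nrep - length(v)))[seq_len(nrep)]
  m <- rbind(plate$readings, pad(plate$growth_control),
             pad(plate$sterile_blank))
  df <- data.frame(
    well = c(format(plate$concentrations, trim = TRUE), "growth_control",
             "sterile_blank"),
    m, check.names = FALSE
  )
  names(df) <- c("well", paste0("rep", seq_len(nrep)))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(wavelength = plate$wavelength, units = "ug/ml"),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a plate assay written by [write_plate_csv()]
#'
#' @param path CSV path (the `<path>.json` sidecar supplies the wavelength;
#'   600 nm is assumed if absent).
#' @return A `plate_assay`.
#' @export
read_plate_csv <- function(path) {
  df <- read.delim(path, sep = ",", stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".json")
  wl <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar)$wavelength
  } else 600
  is_gc <- df$well == "growth_control"
  is_bl <- df$well == "sterile_blank"
  num <- as.matrix(df[, -1, drop = FALSE])
  drop_na <- function(v) v[!is.na(v)]
  plate_assay(
    concentrations = as.numeric(df$well[!is_gc & !is_bl]),
    readings = num[!is_gc & !is_bl, , drop = FALSE],
    growth_control = drop_na(num[is_gc, ]),
    sterile_blank = drop_na(num[is_bl, ]),
    wavelength = wl
  )
}
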