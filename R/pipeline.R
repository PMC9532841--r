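# End-to-end driver chaining the stages: describe parents -> design analogs
# -> verify masses/fragments -> reduce (synthetic) assay plates. Every
# artifact lands in the output directory and is listed, with its md5
# checksum, in a JSON manifest that also records the full configuration so
# published numbers stay traceable to conventions.

#' Pipeline configuration
#'
#' @param peptides Named list of `peptide` objects (default
#'   [latarcin_peptides()]), or a FASTA path.
#' @param out_dir Output directory (created if missing).
#' @param stages Character subset of
#'   `c("describe", "design", "fragments", "assays")`.
#' @param region `(start, end)` of the design region on the first peptide
#'   (default `c(5, 17)`).
#' @param constraints [design_constraints()] for the design stage.
#' @param scale Hydrophobicity scale.
#' @param charge_model Charge model for descriptors.
#' @param delta Helical angular step, degrees/residue.
#' @param inhibition_threshold MIC/MBIC growth-fraction threshold.
#' @param seed Integer seed for the synthetic assay stage.
#' @param design_limit Candidates kept by the design stage.
#' @return A `run_config` list.
#' @export
run_config <- function(peptides = latarcin_peptides(),
                       out_dir = tempfile("ltmap-run-"),
                       stages = c("describe", "design", "fragments",
                                  "assays"),
                       region = c(5, 17),
                       constraints = design_constraints(),
                       scale = hydrophobicity_scale(),
                       charge_model = "side-chains",
                       delta = 100,
                       inhibition_threshold = 0.10,
                       seed = 1L,
                       design_limit = 50L) {
  stages <- match.arg(stages,
                      c("describe", "design", "fragments", "assays"),
                      several.ok = TRUE)
  if (is.character(peptides)) peptides <- parse_fasta(peptides)
  structure(
    list(peptides = peptides, out_dir = out_dir, stages = stages,
         region = region, constraints = constraints, scale = scale,
         charge_model = charge_model, delta = delta,
         inhibition_threshold = inhibition_threshold, seed = as.integer(seed),
         design_limit = design_limit),
    class = "run_config"
  )
}

#' Run the design-and-verification pipeline
#'
#' Executes the enabled stages in order and writes a `manifest.json` listing
#' every artifact with its md5 checksum, the seed, and the conventions used
#' (scale, charge model, delta, thresholds). Stage failures abort with a
#' stage-tagged error.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (list).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  add <- function(path) artifacts <<- c(artifacts, path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  peps <- config$peptides

  if ("describe" %in% config$stages) {
    stage("describe", {
      tab <- descriptor_table(peps, scale = config$scale,
                              charge_model = config$charge_model,
                              delta = config$delta)
      f <- file.path(config$out_dir, "descriptors.tsv")
      write_descriptor_tsv(tab, f)
      add(f)
    })
  }

  if ("design" %in% config$stages) {
    stage("design", {
      parent <- peps[[1L]]
      frag <- extract_region(parent, config$region[1], config$region[2])
      cand <- enumerate_analogs(frag, config$constraints,
                                limit = config$design_limit,
                                seed = config$seed, scale = config$scale)
      f <- file.path(config$out_dir, "candidates.tsv")
      write.table(as.data.frame(cand), f, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      add(f)
      if (length(peps) > 1L) {
        ident <- do.call(rbind, lapply(peps[-1L], function(p) {
          r <- percent_identity(p, frag)
          data.frame(name = p$name, reference = frag$name,
                     matches = r$matches,
                     alignment_length = r$alignment_length,
                     identity_pct = r$identity_pct,
                     stringsAsFactors = FALSE)
        }))
        f2 <- file.path(config$out_dir, "identity.tsv")
        write.table(ident, f2, sep = "\t", quote = FALSE, row.names = FALSE)
        add(f2)
      }
    })
  }

  if ("fragments" %in% config$stages) {
    stage("fragments", {
      for (p in peps) {
        f <- file.path(config$out_dir,
                       paste0("fragments_", gsub("[^A-Za-z0-9._-]", "_",
                                                 p$name), ".tsv"))
        write_fragment_tsv(by_series(p), f)
        add(f)
      }
    })
  }

  if ("assays" %in% config$stages) {
    stage("assays", {
      spec <- generator_spec(seed = config$seed)
      mic <- call_mic(gen_mic_plate(spec), config$inhibition_threshold)
      mbic <- call_mbic(gen_biofilm_plate(spec), config$inhibition_threshold)
      dr <- gen_dose_response(spec)
      fit <- fit_dose_response(dr$concentrations, dr$responses,
                               bottom = 0, top = 100)
      endpoints <- data.frame(
        endpoint = c("MIC", "MBIC", "EC50", "true_MIC", "true_EC50"),
        value = c(mic$label, mbic$label, format(round(fit$EC50, 2)),
                  format(spec$true_mic), format(spec$true_ec50)),
        stringsAsFactors = FALSE
      )
      f <- file.path(config$out_dir, "assay_endpoints.tsv")
      write.table(endpoints, f, sep = "\t", quote = FALSE, row.names = FALSE)
      add(f)
    })
  }

  manifest <- list(
    seed = config$seed,
    stages = config$stages,
    conventions = list(
      scale = attr(config$scale, "scale_name"),
      charge_model = config$charge_model,
      delta = config$delta,
      inhibition_threshold = config$inhibition_threshold,
      max_divergence = config$constraints$max_divergence,
      divergence_mode = config$constraints$divergence_mode
    ),
    artifacts = lapply(artifacts, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
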