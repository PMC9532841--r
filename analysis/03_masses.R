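#!/usr/bin/env Rscript
# Mass verification: theoretical average/monoisotopic masses and singly
# charged b/y fragment ladders for all four peptides, matched against the
# observed MALDI parental ions. Writes results/mass_summary.tsv and one
# fragment ladder TSV per peptide.

suppressPackageStartupMessages(library(ltmap))
dir.create("results", showWarnings = FALSE)

peps <- latarcin_peptides()
# observed singly protonated parental ions from the MALDI spectra
observed_parent <- c("Ltc-3a" = 2483.283, "Lt-MAP1" = 1574.707,
                     "Lt-MAP2" = 1629.962, "Lt-MAP3" = 1488.123)

rows <- lapply(names(peps), function(nm) {
  p <- peps[[nm]]
  m <- peptide_mass(p)
  fs <- by_series(p)
  write_fragment_tsv(fs, sprintf("results/fragments_%s.tsv",
                                 gsub("[^A-Za-z0-9]", "", nm)))
  match <- match_peaks(fs, peak_list(observed_parent[[nm]], tolerance = 0.5))
  data.frame(
    name = nm, M_avg = round(m$M_avg, 2), M_mono = round(m$M_mono, 3),
    MH_plus = round(m$MH_plus, 3), observed = observed_parent[[nm]],
    error_da = round(observed_parent[[nm]] - m$MH_plus, 3),
    parent_matched = match$parent_matched
  )
})
summary <- do.call(rbind, rows)
write.table(summary, "results/mass_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message("Theoretical vs observed parental ions (0.5 Da tolerance):")
print(summary, row.names = FALSE)
message("\nAll observed parental ions match theory within tolerance: ",
        all(summary$parent_matched))
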