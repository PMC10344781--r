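#!/usr/bin/env Rscript
# Contact footprints of the three antibody-pMHC complexes (synthetic
# stand-ins with the published interface statistics as designed geometry):
# the mouse template (OVA/H2-Kb), the human template (NY-ESO1/HLA-A*02:01)
# and the re-engineered MART1 binder.
#
# Finding: the re-engineered antibody concentrates its interface on the
# peptide -- 26 peptide-directed atom contacts with only 7 MHC residues
# touched (R65/K146/H151 carrying 80% of the MHC contacts), versus 14 MHC
# residues for the template it was derived from.

suppressPackageStartupMessages(library(tcrmtools))
dir.create("results", showWarnings = FALSE)

templates <- c(mouse_template = "25d116-ova-kb",
               human_template = "3m4e5-nyeso-a2",
               reengineered = "ma2-mart1-a2")

rows <- list()
for (nm in names(templates)) {
  cx <- synthetic_tcrm_complex(templates[[nm]])
  rep <- footprint_report(cx, cutoff = 4.0)
  cat("\n====", nm, "(", templates[[nm]], ") ====\n")
  print(rep)
  tab <- as.data.frame(rep$table)
  tab$complex <- nm
  rows[[nm]] <- tab
  s <- rep$summary
  cat(sprintf("summary: %d peptide / %d MHC atom contacts, %d MHC residues, BSA %0.f + %0.f A^2\n",
              s$n_contacts_peptide, s$n_contacts_mhc,
              s$n_mhc_residues_contacted, s$bsa_peptide, s$bsa_mhc))
}

all_rows <- do.call(rbind, rows)
write.table(all_rows, "results/footprint_tables.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nwrote results/footprint_tables.tsv\n")
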