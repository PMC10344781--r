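#!/usr/bin/env Rscript
# Focused randomization library designs from the two template footprints:
# randomize peptide-contacting CDR positions, preserve MHC-contacting ones.
#
# Finding: the mouse template yields 9 randomizable positions (20^9 =
# 5.12e11 theoretical sequences); the human template, restricted to peptide
# side-chain contacts, yields 7 (20^7 = 1.28e9).  Realized library sizes are
# transformant counts and sit well below these theoretical products.

suppressPackageStartupMessages(library(tcrmtools))
dir.create("results", showWarnings = FALSE)

mouse <- synthetic_tcrm_complex("25d116-ova-kb")
fp_mouse <- classify_ab_residues(find_contacts(mouse, restrict_to_cdrs = TRUE))
des_mouse <- select_positions(fp_mouse, design_policy(include_PM = TRUE))
cat("==== mouse template design ====\n")
rec_mouse <- design_report(des_mouse)

human <- synthetic_tcrm_complex("3m4e5-nyeso-a2")
fp_human <- classify_ab_residues(find_contacts(human, side_chain_only = TRUE,
                                               restrict_to_cdrs = TRUE))
des_human <- select_positions(fp_human, design_policy(side_chain_only = TRUE))
cat("\n==== human template design ====\n")
rec_human <- design_report(des_human)

jsonlite::write_json(list(mouse = rec_mouse, human = rec_human),
                     "results/library_designs.json", auto_unbox = TRUE,
                     pretty = TRUE, digits = NA)
cat("\nwrote results/library_designs.json\n")
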