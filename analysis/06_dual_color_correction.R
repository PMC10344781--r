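#!/usr/bin/env Rscript
# Dual-color double-counting correction (corrected count = A + B - 0.5*AB):
# bias measurement against synthetic ground truth.
#
# Finding: with two tags per molecule and equal color odds, half the
# molecules carry both colors; the printed 0.5*AB correction then removes
# only half of the double count even when every dual-labeled molecule is
# cotracked (expected ratio 1.25x truth), and missed cotracks (bleaching
# before 10 consecutive joint steps) push the ratio higher.  The corrected
# count is therefore an upper bound under this labeling model; we report the
# measured ratio rather than altering the printed formula.

suppressPackageStartupMessages(library(tcrmtools))
dir.create("results", showWarnings = FALSE)
seed <- 202L
field <- c(12, 12)

per_seed <- t(vapply(1:10, function(i) {
  cfg <- sim_config(true_density = 0.3, field = field,
                    label_model = "dual_color", diffusion_coeff = 0.1,
                    bleach_prob = 0.02, detection_prob = 0.9,
                    seed = seed + i)
  sim <- simulate_smlm(cfg)
  res <- quantify_density(sim$table, quant_config(vCSA = prod(field)))
  c(A = res$A, B = res$B, AB = res$AB,
    corrected = res$dual_corrected_count, truth = sim$truth$n_mobile)
}, numeric(5)))

print(round(as.data.frame(per_seed), 2))
ratio <- per_seed[, "corrected"] / per_seed[, "truth"]
cat(sprintf("corrected/truth ratio: %.3f +/- %.3f (theoretical floor 1.25 under full cotrack recovery)\n",
            mean(ratio), sd(ratio)))
write.table(as.data.frame(per_seed), "results/dual_color_bias.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("wrote results/dual_color_bias.tsv\n")
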