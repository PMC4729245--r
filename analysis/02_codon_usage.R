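#!/usr/bin/env Rscript
# Stage 2: codon usage bias.
#
# Per-species ENC on the fixture alignment, group means for social vs
# subsocial species with 1000-replicate codon-column bootstrap CIs, the
# 3-vs-7 permutation test, and base composition by codon position. Because
# the fixture evolves under uniform codon frequencies, the expected group
# difference is ~0 and the permutation test should not reject; a second run
# skews synonymous usage toward preferred codons in the subsocial species
# (the direction the selection-effectiveness hypothesis predicts: stronger
# codon bias where Ne is high), which the one-sided test should detect.

library(socialsel)

fx_dir <- "results/fixture"
if (!file.exists(file.path(fx_dir, "alignment.fasta")))
  stop("run analysis/01_simulate_fixture.R first")
aln <- read_codon_alignment(file.path(fx_dir, "alignment.fasta"))
labels <- read_mating_labels(file.path(fx_dir, "labels.tsv"))

rep0 <- enc_report(aln, labels, n_boot = 1000, n_perm = 1000, seed = 7)
print(rep0)

subsocial <- names(labels)[labels == "subsocial"]
skewed <- simulate_skewed_codon_usage(aln, 0.15, subsocial, seed = 8)
rep1 <- enc_report(skewed, labels, n_boot = 1000, n_perm = 1000, seed = 7)
cat("\nafter skewing synonymous usage of the subsocial species (strength 0.15):\n")
print(rep1)

dir.create("results/codon_usage", showWarnings = FALSE, recursive = TRUE)
tab <- rbind(
  data.frame(dataset = "uniform", species = names(rep0$per_species_enc),
             enc = rep0$per_species_enc, label = labels[names(rep0$per_species_enc)]),
  data.frame(dataset = "skewed", species = names(rep1$per_species_enc),
             enc = rep1$per_species_enc, label = labels[names(rep1$per_species_enc)])
)
write.table(tab, "results/codon_usage/enc_per_species.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
groups <- do.call(rbind, lapply(list(uniform = rep0, skewed = rep1), function(r)
  data.frame(group = names(r$group_means), mean = r$group_means,
             lower = r$group_ci[, "lower"], upper = r$group_ci[, "upper"],
             perm_p = r$permutation$p_value, mode = r$permutation$mode)))
groups$dataset <- rep(c("uniform", "skewed"), each = 2)
write.table(groups, "results/codon_usage/enc_groups.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nwrote results/codon_usage/{enc_per_species,enc_groups}.tsv\n")
cat(sprintf(
  "finding: uniform-usage data give P = %.3f (no group difference, as expected);\nskewing the subsocial group gives P = %.4f (social ENC relatively higher).\n",
  rep0$permutation$p_value, rep1$permutation$p_value
))
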