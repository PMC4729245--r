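#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Builds the 10-taxon fixture emulating the study design — three social
# species on short terminal branches, each sister to a subsocial species,
# 13 loci totalling 1583 codons (4749 coding nt) evolved under the 3-class
# branch model (dN/dS 0.17 internal / 0.25 social / 0.10 subsocial,
# kappa 2) — plus the 589-nt non-coding partition, and writes everything
# under results/fixture/.

library(socialsel)

seed <- 2026L
out <- "results/fixture"
fx <- make_study_fixture(seed = seed)
write_study_fixture(fx, out)

nc <- simulate_noncoding(fx$tree, 589, seed = seed + 1L)
writeLines(
  paste0(">", rownames(nc), "\n", apply(nc, 1, paste0, collapse = "")),
  file.path(out, "noncoding.fasta")
)

cat(sprintf("fixture written to %s: %d taxa x %d codons, %d loci, seed %d\n",
            out, nrow(fx$alignment$codons), ncol(fx$alignment$codons),
            nrow(fx$alignment$partitions), seed))
cat("generating dN/dS:",
    paste(sprintf("%s = %.2f", names(fx$truth$omega), fx$truth$omega),
          collapse = ", "), "\n")
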