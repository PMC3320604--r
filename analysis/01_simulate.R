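#!/usr/bin/env Rscript

## Stage 1: generate the synthetic study inputs with known ground truth.
##
## Emits a 1-Mb genome carrying 50 implanted RE1 motifs (canonical-biased
## spacer mix), binding-region intervals centred on each implant, 30
## heterozygous half-site SNVs, 25-nt reads at 200x site coverage with a
## 0.7 major-allele fraction, EMSA triplicate lanes and reporter readings.
## Everything downstream (02-04) consumes these files only.

suppressPackageStartupMessages(library(re1screen))

out <- "results/sim"
cfg <- sim_config(seed = 101)
sim <- simulate_bundle(cfg, dir = out)

cat("wrote synthetic bundle to", out, "\n")
cat(sprintf("  genome: %d bp, GC %.3f\n", nchar(sim$genome$chrS),
            mean(strsplit(sim$genome$chrS, "")[[1]] %in% c("G", "C"))))
cat(sprintf("  motifs: %d implanted (%d canonical), scores %.2f-%.2f\n",
            nrow(sim$truth$motifs), sum(sim$truth$motifs$spacer == 2),
            min(sim$truth$motifs$score), max(sim$truth$motifs$score)))
cat(sprintf("  SNVs: %d, all heterozygous, MAF %.3f-%.3f\n",
            nrow(sim$snps), min(sim$snps$maf), max(sim$snps$maf)))
cat(sprintf("  reads: %d x %d nt\n", nrow(sim$reads), cfg$read_length))
cat(sprintf("  EMSA lanes: %d (incl. Ideal/Mutated controls)\n",
            nrow(sim$lanes)))
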