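#!/usr/bin/env Rscript

## Stage 5: statistical calibration of the screen's two decision rules.
##
## (a) Allelic read-bias test: rejection rate at true allele ratio 0.5
##     (should sit at the exact test's size, ~0.05 at 356 reads) and at
##     0.85 (power).  (b) EMSA effect classification: DOWN recovery at a
##     true dFB of 0.4 and false-call rate under a null dFB of 0, at the
##     assay's noise level (sd 0.02, 3 replicates).
##
## This is a reduced version (300 simulations per condition) of the full
## calibration run by scripts/acceptance.R.

suppressPackageStartupMessages(library(re1screen))

dir.create("results/calibration", recursive = TRUE, showWarnings = FALSE)
half <- default_re1_pwm()
n_sim <- 300

bias_rate <- function(ratio, base_seed) {
  cfg <- sim_config(seed = base_seed, genome_length = 2e4, n_motifs = 3,
                    n_snps = 1, depth = 356L, true_allele_ratio = ratio)
  sim <- inject_snps(implant_motifs(simulate_genome(cfg), half, cfg),
                     half, cfg)
  ks <- filter_unique_kmers(
    enumerate_allele_kmers(sim$genome, sim$truth$snps[1, ],
                           cfg$read_length), sim$genome)
  rej <- 0L
  for (i in seq_len(n_sim)) {
    cfg_i <- cfg
    cfg_i$seed <- base_seed + i * 1009L
    res <- test_allelic_bias(count_allelic_reads(
      simulate_reads(sim, cfg_i)$reads$seq, ks))
    if (isTRUE(res$heterozygous) && res$p_value < 0.05) rej <- rej + 1L
  }
  rej / n_sim
}

emsa_rate <- function(fb_major, fb_minor, seed, what) {
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_sim)) {
    cls <- emsa_comparison_table(
      simulate_emsa_lanes(fb_major, fb_minor, 0.02, 3))$effect_class
    if (what == "down" && cls == "DOWN") hits <- hits + 1L
    if (what == "any" && cls != "NO_DIFFERENCE") hits <- hits + 1L
  }
  hits / n_sim
}

out <- data.frame(
  quantity = c("allelic_null_rejection", "allelic_power_0.85",
               "emsa_down_recovery", "emsa_null_false_call"),
  rate = c(bias_rate(0.5, 31000), bias_rate(0.85, 41000),
           emsa_rate(0.2, 0.6, 51, "down"), emsa_rate(0.3, 0.3, 61, "any")),
  n_sim = n_sim)
write_tsv(out, "results/calibration/rates.tsv")
print(out, row.names = FALSE)
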