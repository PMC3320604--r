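#!/usr/bin/env Rscript

## Stage 3: in vitro affinity comparison.
##
## Converts replicate gel-band quantifications to Fraction Bound, compares
## Major vs Minor alleles per competitor (pooled-variance one-sided t,
## uncorrected), classifies effects (DOWN = minor binds less strongly at
## |dFB| >= 0.1 and p < 0.05; UP = more strongly), profiles |dFB| by SNP
## position in the motif, and cross-checks the reporter assay readings.

suppressPackageStartupMessages(library(re1screen))

dir.create("results/emsa", recursive = TRUE, showWarnings = FALSE)
lanes <- read_emsa_lanes("results/sim/emsa_lanes.tsv")
tab <- emsa_comparison_table(lanes)
write_tsv(tab, "results/emsa/comparisons.tsv")

# control sanity: the Ideal competitor must bind far better than Mutated
fb <- fraction_bound(lanes$bound, lanes$unbound)
cat(sprintf("control FB: Ideal %.3f, Mutated %.3f\n",
            mean(fb[lanes$competitor_label == "Ideal"]),
            mean(fb[lanes$competitor_label == "Mutated"])))

s <- summarize_classes(tab)
cat(sprintf("effect classes: %d DOWN, %d UP, %d no difference; %d at p<0.05 alone\n",
            s$n_down, s$n_up, s$n_no_difference, s$n_p_significant))

# positional effect profile, joined to the catalogue from stage 2
catalogue <- read.table("results/screen/catalogue.tsv", header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
joined <- merge(catalogue, tab, by.x = "snp_id", by.y = "competitor_label")
prof <- position_effect_profile(joined)
write_tsv(prof[, setdiff(names(prof), "values")],
          "results/emsa/position_profile.tsv")
top <- prof[order(-prof$mean_abs_delta_fb), ][1, ]
cat(sprintf("strongest positional effect: motif position %d, mean |dFB| %.3f (n=%d)\n",
            top$motif_position, top$mean_abs_delta_fb, top$n))

# reporter assay: does repression track the EMSA class?
rep <- read.table("results/sim/reporter.tsv", header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
rows <- lapply(unique(rep$construct), function(cn) {
  sub <- rep[rep$construct == cn, ]
  cls <- tab$effect_class[tab$competitor_label == cn]
  r <- compare_reporter_alleles(sub$activity[sub$allele == "major"],
                                sub$activity[sub$allele == "minor"],
                                expected_class = cls)
  data.frame(construct = cn, emsa_class = cls, p_value = r$p_value,
             direction = r$direction, consistent = r$consistent)
})
rep_tab <- do.call(rbind, rows)
write_tsv(rep_tab, "results/emsa/reporter_comparisons.tsv")
cat(sprintf("reporter consistency with EMSA class: %d/%d constructs\n",
            sum(rep_tab$consistent), nrow(rep_tab)))
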