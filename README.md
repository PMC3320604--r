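# re1screen

Screening single-nucleotide variants that alter recruitment of the
transcriptional repressor REST (NRSF) to its DNA recognition element, the
RE1.

Most disease-associated variants are non-coding, and a tractable way to
assign them a mechanism is to ask whether they disrupt a well-defined
transcription-factor binding motif inside an experimentally mapped
binding site.  The RE1 is ideal for this: a 9-bp left half site and a
6-bp right half site, strongly constrained, separated by a weakly
constrained spacer of 0–12 bp (canonically 2).  `re1screen` implements
the full screen as composable R functions:

1. **Motif model** — half-site PWMs with per-spacer variants; a window of
   length 15+s is scored as the log₂-odds sum over its 15 informative
   positions, min–max normalized to [0,1]; a region contains an RE1 when
   its best window (any offset, strand, spacer) reaches S ≥ 0.88.
2. **Genomic screen** — binding regions standardized to 100 bp around the
   summit; single best hit per region; motif half sites intersected with
   a VCF of SNVs; Major allele = reference-genome variant; per-record
   motif-score delta Δ = S(minor) − S(major).
3. **EMSA statistics** — Fraction Bound FB = bound/(bound+unbound) per
   gel lane; triplicate allele comparison by pooled-variance one-sided
   Student's t; classes DOWN/UP/NO_DIFFERENCE at |ΔFB| ≥ 0.1 and
   p < 0.05 (ΔFB = FB_minor − FB_major); positional |ΔFB| profiles;
   dual-luciferase reporter normalization and comparison.
4. **Allele-specific ChIP-seq** — enumeration of all read-length k-mers
   that exactly and uniquely distinguish the two alleles of a SNP;
   exact-match read counting; heterozygosity at ≥ 5 reads per allele;
   exact binomial test of allelic bias; confounder flagging for SNP
   pairs within one read length; Spearman correlation of affinity vs
   enrichment; 2^−ΔΔCt qPCR enrichment.
5. **Synthetic data** — a seeded generator (genome, implanted motifs,
   half-site SNVs, allele-ratio reads, EMSA/reporter replicates) with a
   ground-truth table, so the whole pipeline runs and is tested without
   any downloads.

## Worked example

The `analysis/` directory is a numbered workflow over the package; run it
from the repository root:

```sh
Rscript analysis/01_simulate.R     # synthetic study inputs + truth
Rscript analysis/02_screen.R      # motif screen + SNP overlap
Rscript analysis/03_emsa.R        # affinity comparison + classes
Rscript analysis/04_allelic.R     # allelic read bias + correlations
Rscript analysis/05_calibration.R # decision-rule calibration
```

Output from a complete run (seed 101 bundle: 1-Mb genome, 50 implanted
RE1s, 30 heterozygous half-site SNVs, 200 reads/site at a 0.7 major
fraction):

```
RE1-containing regions: 50 of 50 peaks (33 canonical)
half-site SNP records: 30; truth recovery 30/30
motif-score deltas: -0.077 to 0.030 (negative = minor is a worse motif)

control FB: Ideal 0.058, Mutated 0.895
effect classes: 27 DOWN, 1 UP, 2 no difference; 29 at p<0.05 alone
reporter consistency with EMSA class: 29/30 constructs

30/30 sites heterozygous; 30 with significant allelic bias (binomial p < 0.05)
mean major-read fraction 0.699 (generator truth 0.70)
Spearman rho(enrichment, FB) = -0.809 (p = 6.3e-08); vs 1-FB: 0.809
```

Reading these numbers: every implanted motif is rediscovered at the 0.88
stringency and every injected half-site SNV enters the catalogue; most
minor alleles damage the motif (negative delta) and are classified DOWN
(weaker REST binding, higher Fraction Bound), matching the generator's
truth; the read counts reproduce the simulated 0.7 allelic ratio and the
exact binomial test flags every site; and in vivo enrichment correlates
negatively with Fraction Bound, as it must when FB falls with binding
strength.

The same stages run on real inputs by pointing `screen_config()` at a
genome FASTA, a BED/narrowPeak peak set, a VCF, and optionally a FASTQ
and an EMSA lane TSV:

```r
library(re1screen)
res <- run_screen(screen_config(
  genome = "genome.fa", peaks = "peaks.narrowPeak", vcf = "snps.vcf",
  lanes = "emsa_lanes.tsv", min_maf = 0.01, out_dir = "results/screen"))
res$summary
```

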