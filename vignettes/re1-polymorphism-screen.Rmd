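---
title: "Methods: screening SNVs that alter REST recruitment at RE1 motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening SNVs that alter REST recruitment at RE1 motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(re1screen)
```

## The problem

REST (also called NRSF) is a zinc-finger transcriptional repressor that is
recruited to its target genes through a long, highly recognisable DNA
element, the RE1: a strongly constrained 9-bp left half site and 6-bp
right half site separated by a weakly constrained spacer, canonically 2 bp
but observed from 0 to 12 bp.  A single-nucleotide variant inside a half
site can change the element's affinity for REST, and thereby the degree of
repression of the nearby gene.  `re1screen` implements a multi-stage
screen for such variants: motif discovery inside experimentally determined
binding regions, intersection of motif half sites with a SNV catalogue,
allele-specific motif scoring, replicate competition-EMSA statistics,
reporter-assay comparison, and allele-specific ChIP-seq read-bias testing
-- together with a seeded synthetic-data generator so that every stage is
testable end to end without external downloads.

## Motif model and scoring

The RE1 is modelled as two half-site position-weight matrices plus a
spacer length $s \in \{0, \dots, 12\}$.  Column frequencies $f_{bj}$ (after
adding a pseudocount of 0.01 per cell) are converted to log-odds weights
$w_{bj} = \log_2(f_{bj} / q_b)$ against a background $q$ (uniform 0.25 by
default).  A window of length $15 + s$ receives the raw score
$\sum_{j=1}^{15} w_{x_j j}$ over its 15 informative positions -- spacer
positions carry zero weight by construction, so all spacer variants share
the same attainable score range -- and the raw score is min--max
normalized to $[0,1]$:

$$S = \frac{\mathrm{raw} - \mathrm{raw}_{\min}}{\mathrm{raw}_{\max} - \mathrm{raw}_{\min}}.$$

A region "contains an RE1" when its best window reaches $S \ge 0.88$, a
medium stringency at which hits are rare in random DNA (the package's own
measurement: 2 of 1000 random 100-mers at GC 0.5 under the default
matrix).  The scoring program originally used for this screen is not
published, so the absolute normalized scale here follows the procedure,
not any particular trained matrix; the shipped default matrix is an
explicit stand-in built around the canonical consensus half sites
(`TTCAGCACC` / `GGACAG`) with heterogeneous per-column conservation
(consensus frequencies ~0.85 / ~0.6 / ~0.45 for strongly, moderately and
weakly constrained positions), which mirrors the RE1's uneven information
profile and keeps the score spectrum near the top of the scale
non-degenerate.  Users with a trained matrix supply it via `load_pwm()`
(plain 4 x 15 counts with a `9 6` header, or a minimal JASPAR-style PFM).

Numerical conventions:

* `N` bases score the column minimum rather than aborting, so scanning is
  total over real genomes.
* Ties between candidate windows are broken deterministically -- higher
  score, then smaller spacer, then `+` strand, then leftmost start --
  and two scores within $10^{-12}$ are treated as tied.  This matters in
  practice: windows with identical informative bases under different
  spacer placements are mathematically tied but differ by ~$10^{-16}$ in
  floating-point sums.
* The allele delta `score_allele_delta()` is defined only for windows
  differing at exactly one informative position; a spacer-only difference
  is an error rather than a silent zero, so callers cannot mistake a
  non-informative comparison for a measured one.

## From binding regions to a polymorphic-RE1 catalogue

Binding regions of heterogeneous size are standardized to 100 bp centred
on the peak summit (narrowPeak summit when present, interval midpoint
otherwise).  At contig edges the window is shifted, not truncated, so the
search width is constant; only a contig shorter than 100 bp yields a
flagged, shorter region.  Within each standardized region, every offset x
strand x spacer combination is evaluated and the single best hit is kept
-- one motif explains one binding region.

Half sites occupy motif positions 1--9 and $(10+s)$--$(15+s)$ (12--17 in
the canonical motif).  Only SNVs inside a half site enter the catalogue;
spacer and flank SNVs are excluded.  The allele present in the reference
genome is defined as the **Major** allele even when it is the rarer
variant in populations -- the original screen's convention, preserved here
because the motif search runs on the reference sequence and is therefore
biased toward reference-allele motifs (this also explains why minor
alleles that *increase* affinity are under-represented: a weak reference
motif that improves in the minor allele scores below threshold and never
enters the catalogue).  Records carry the SNP's 1-based position within
the motif, its half site, both allele windows (strand-oriented), and the
normalized-score delta (negative = minor allele is a worse motif).  An
optional minor-allele-frequency filter (`min_maf = 0.01` is the
second-generation preset) drops rare or artifactual variants; records
with unknown MAF are kept and flagged by default.

## EMSA statistics

In the competition assay, an unlabelled competitor sequence competes with
a labelled high-affinity probe for purified REST; **Fraction Bound**
$= \mathrm{bound}/(\mathrm{bound}+\mathrm{unbound})$ of the probe bands
approaches 0 for a strong competitor and 1 for a non-binder.  Alleles are
compared on replicate FB values ($n = 3$ by design) with an unpaired
pooled-variance Student's $t$ test, one-sided in the direction of the
observed difference, uncorrected for multiple testing (an optional BH
column is available).  With equal means the one-sided convention gives
$p = 0.5$.  Effects are classified on
$\Delta FB = FB_{\mathrm{minor}} - FB_{\mathrm{major}}$:

* `DOWN` (minor binds less strongly): $\Delta FB \ge 0.1$ and $p < 0.05$;
* `UP`: $\Delta FB \le -0.1$ and $p < 0.05$;
* `NO_DIFFERENCE` otherwise.

The 0.1 threshold is interpreted as a minimum |change in Fraction Bound|,
consistent with how the quantity is defined in the screen's result
tables.  Because the test direction follows the data, the one-sided
$p$-threshold of 0.05 corresponds to a two-sided size of 0.1; the
combined rule (delta threshold AND $p$) is what controls false calls, and
its measured null rate at the assay's noise level (sd 0.02, $n=3$) is
below 1%.  Reporter-assay readings are normalized firefly/Renilla ratios
relative to the empty backbone, compared two-sided; a minor allele with
increased EMSA affinity is expected to repress the reporter more
strongly.

## Allele-specific ChIP-seq reads

Only reads that directly overlap a SNP reveal their allele of origin.
For each catalogued SNP all possible read-length windows covering it are
enumerated for both alleles, plus reverse complements; matching is exact
full-length string membership (no aligner, no mismatches), mirroring a
"uniquely and exactly mapping" analysis.  The uniqueness filter keeps
major k-mers occurring exactly once in the genome (either strand) and
minor k-mers occurring zero times in the reference; it is on by default
but optional, since genuine mapping uniqueness is genome-dependent.  A
site is **heterozygous** when both alleles have at least 5 matching
reads; heterozygous sites are tested with the exact binomial test
(two-sided, minimum-likelihood-sum convention) against equal sampling.  A
SNP with another catalogued SNP within one read length (distance
$\le L-1$, boundary inclusive) is flagged as confounded and excluded from
testing.  Read length is a data property (the emulated libraries used 25
and 35 nt), never hard-coded.

In vitro affinity and in vivo enrichment are related by a Spearman
correlation of enrichment against Fraction Bound, expected negative since
FB falls as binding strength rises; because the supplementary convention
in the source study plots "relative binding" $(1 - FB)$, both
orientations are reported ($\rho$ and $-\rho$).  Allele-specific ChIP
qPCR enrichment uses the standard $2^{-\Delta\Delta C_t}$ normalization
(target vs control locus, IP vs input).

## The synthetic-data generator

`simulate_bundle()` emulates the statistical structure of the screen's
inputs at desk scale, with one seed fixing every emitted file
byte-for-byte.  Each stage draws from its own sub-stream (seed plus a
fixed stage offset), so changing, say, the number of motifs does not
perturb the read draws.  Defaults are the study conditions used
throughout the tests:

| parameter | default | rationale |
|---|---|---|
| genome | 1 Mb, GC 0.41 | human-like composition, large enough for 50 well-separated sites |
| motifs | 50, spacer weight 0.63 on 2 bp | canonical/noncanonical mix mirroring the screened polymorphic set (52/30) |
| implant score | $\ge 0.95$ | high-quality motifs, comfortably above the 0.88 discovery cut |
| SNVs | 30, half-site placement, het, MAF in [0.01, 0.5] | one per motif; common variants |
| reads | 25 nt, depth 200/site, major fraction 0.7 | short-read ChIP-seq regime with detectable allelic bias |
| EMSA | 3 replicates, FB noise sd 0.02 | triplicate design; noise at which a 0.1 delta is reliably callable |

True per-allele Fraction Bound means are a monotone decreasing map of the
allele's normalized motif score, $FB = \mathrm{clamp}(0.05 + 4(1-S),\,
0.02,\, 0.98)$: consensus-quality motifs compete strongly and each loss
of motif quality raises FB steeply.  The gain of 4 places single-base
deltas in the 0.1--0.3 FB range observed for real half-site variants.
Reporter activity is an increasing affine map of FB (strong binders
repress), with Gaussian noise.

What the generator does **not** emulate -- and what passing tests
therefore do not demonstrate about real data: ChIP fragment-size
distributions, PCR duplicates, mappability structure, base-calling
errors (qualities are constant and unused), genotyping error in the SNP
catalogue, linkage between nearby variants, and any trained motif model.
Recovery rates on synthetic data are upper bounds for real genomes.

## Calibration and problem sizes

The statistical acceptance checks (in `tests/testthat/test-acceptance.R`
and recomputed from scratch by `scripts/acceptance.R`) use these sizes:

* scanner vs brute force: 200 sequences of 80--200 bp, half with
  implants, exhaustive enumeration over offset x strand x spacer;
* exact binomial vs direct pmf summation: all count pairs with
  $n \le 200$, agreement to $10^{-12}$;
* allelic-bias calibration: 1000 simulated sites (2000 for the null in
  the test suite, to keep Monte-Carlo noise well inside the assessment
  band) at 356 overlapping reads.  The depth is chosen because the exact
  binomial test is discrete and conservative -- its true size at
  $\alpha = 0.05$ is 0.035 at $n=100$ and 0.040 at $n=200$ -- and at
  $n = 356$ the size is 0.0497, closest to nominal, so a near-5%
  rejection rate is the correct expectation.  Power at a true major
  fraction of 0.85 is essentially 1 at this depth;
* EMSA classification: 1000 runs each for recovery of a true
  $\Delta FB = 0.4$ (sd 0.02, $n=3$) and for the null false-call rate;
* implant recovery: the default 1-Mb bundle, 50 implants, full screen.

## Known limitations and surfaced inconsistencies

* The default matrix is a consensus-derived stand-in; absolute scores and
  catalogue sizes on real genomes depend on the matrix supplied.
* The one-sided-in-observed-direction t convention doubles the nominal
  one-sided size; it is kept because it is the convention of the original
  assay analysis, and the classification rule adds the $|\Delta FB|$
  guard.
* Binding regions with only a half site, or no identifiable motif, are
  out of scope: recruitment there may not be sequence-directed.
* The source study reports internally inconsistent headline counts
  (942 vs 924 RE1-containing regions; 86 SNPs in 82 RE1s alongside "3
  RE1s with 2 SNPs each", which implies 85; 46 DOWN + 8 UP = 54 against a
  stated 56).  `summarize_classes()` therefore reports the delta-based
  and p-only counts side by side rather than reconciling them, and this
  package makes no attempt to reproduce those catalogue sizes, which
  depend on unavailable inputs (the original genome assembly, SNP builds
  and trained matrix).
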