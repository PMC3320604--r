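## Allele-specific ChIP-seq read analysis.
##
## A read can only reveal its allele of origin if it directly overlaps the
## SNP, so for each pRE1 SNP we enumerate every possible read-length window
## covering the SNP, for both alleles and both strands, and count raw reads
## by exact string membership in those sets (no aligner, no mismatches).
## A site is called heterozygous when at least `min_each` reads match both
## the major and the minor variant; heterozygous sites are then tested for
## allelic bias with the exact binomial test against a 0.5 null.

#' Enumerate allele-distinguishing k-mers over a SNP
#'
#' For every offset that places the SNP inside a `read_length` window (and
#' that keeps the window inside the contig), emits the reference window
#' (major) and the ALT-substituted window (minor), plus reverse
#' complements.  Any sequence appearing in both allele sets (possible only
#' by coincidental collision) is flagged and removed from both.
#'
#' @param genome named list of contig sequences.
#' @param snp one-row data.frame (or list) with `chrom`, `pos` (0-based),
#'   `ref`, `alt`.
#' @param read_length read length L (the screen's source data used 25 and
#'   35 nt).
#' @return List of class `AlleleKmerSet`: `snp`, `read_length`,
#'   `major_kmers`, `minor_kmers` (character vectors incl. reverse
#'   complements), `unique_only = FALSE`, `collision` flag.
#' @export
enumerate_allele_kmers <- function(genome, snp, read_length) {
  genome <- as_genome(genome)
  read_length <- as.integer(read_length)
  if (read_length < 1L) stop("read_length must be >= 1")
  if (snp$alt == snp$ref) stop("ALT equals REF for SNP ", snp$id)
  contig <- genome[[as.character(snp$chrom)]]
  if (is.null(contig)) stop("unknown contig ", snp$chrom)
  n <- nchar(contig)
  pos <- as.integer(snp$pos)
  if (pos < 0L || pos >= n) stop("SNP position outside contig")
  starts <- max(0L, pos - read_length + 1L):min(pos, n - read_length)
  if (!length(starts) || starts[1] > pos)
    stop("contig too short for any read covering the SNP")
  major_f <- substring(contig, starts + 1L, starts + read_length)
  offset_in_window <- pos - starts + 1L
  minor_f <- major_f
  substr_at <- function(s, i, b) { substr(s, i, i) <- b; s }
  for (k in seq_along(minor_f))
    minor_f[k] <- substr_at(minor_f[k], offset_in_window[k], snp$alt)
  major <- unique(c(major_f, revcomp(major_f)))
  minor <- unique(c(minor_f, revcomp(minor_f)))
  shared <- intersect(major, minor)
  if (length(shared)) {
    warning(length(shared), " k-mer(s) collide between alleles and were ",
            "removed from both sets")
    major <- setdiff(major, shared)
    minor <- setdiff(minor, shared)
  }
  structure(list(snp = as.list(snp[c("chrom", "pos", "id", "ref", "alt")]),
                 read_length = read_length,
                 major_kmers = major, minor_kmers = minor,
                 unique_only = FALSE, collision = length(shared) > 0L),
            class = "AlleleKmerSet")
}

#' Keep only uniquely mapping allele k-mers
#'
#' Retains major k-mers that occur exactly once in the reference genome
#' (counting both strands) and minor k-mers that occur zero times in the
#' reference -- i.e. reads that map uniquely and exactly.
#'
#' @param kset an `AlleleKmerSet`.
#' @param genome named list of contig sequences.
#' @return The filtered `AlleleKmerSet` with `unique_only = TRUE`.
#' @export
filter_unique_kmers <- function(kset, genome) {
  genome <- as_genome(genome)
  subject <- Biostrings::DNAStringSet(unlist(genome))
  count_genome <- function(kmers) {
    if (!length(kmers)) return(integer(0))
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
    fwd <- rowSums(Biostrings::vcountPDict(pd, subject))
    rcd <- Biostrings::PDict(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
    rev <- rowSums(Biostrings::vcountPDict(rcd, subject))
    fwd + rev
  }
  kset$major_kmers <- kset$major_kmers[count_genome(kset$major_kmers) == 1L]
  kset$minor_kmers <- kset$minor_kmers[count_genome(kset$minor_kmers) == 0L]
  kset$unique_only <- TRUE
  kset
}

#' Count reads matching each allele's k-mer set
#'
#' Only exact, full-length matches count.  Reads of exactly `read_length`
#' are matched directly; longer reads are compared through every
#' length-L substring and counted at most once per allele set; shorter
#' reads are skipped (their number is reported).
#'
#' @param reads character vector of read sequences.
#' @param kset an `AlleleKmerSet`.
#' @return List of class `AllelicReadCount`: `n_major`, `n_minor`,
#'   `n_skipped` (too-short reads), `heterozygous = NA`, `p_value = NA`
#'   (filled by [test_allelic_bias()]).
#' @export
count_allelic_reads <- function(reads, kset) {
  L <- kset$read_length
  reads <- toupper(reads)
  len <- nchar(reads)
  n_skipped <- sum(len < L)
  if (n_skipped)
    message(n_skipped, " read(s) shorter than ", L, " were skipped")
  exact <- reads[len == L]
  n_major <- sum(exact %in% kset$major_kmers)
  n_minor <- sum(exact %in% kset$minor_kmers)
  for (r in reads[len > L]) {
    subs <- substring(r, seq_len(nchar(r) - L + 1L),
                      seq_len(nchar(r) - L + 1L) + L - 1L)
    if (any(subs %in% kset$major_kmers)) n_major <- n_major + 1L
    if (any(subs %in% kset$minor_kmers)) n_minor <- n_minor + 1L
  }
  structure(list(n_major = n_major, n_minor = n_minor,
                 n_skipped = n_skipped, heterozygous = NA,
                 p_value = NA_real_, confounded = FALSE),
            class = "AllelicReadCount")
}

#' Call heterozygosity and test allelic read bias
#'
#' A site is heterozygous when both alleles have at least `min_each`
#' matching reads.  Heterozygous sites get a two-sided exact binomial
#' p-value against equal allele sampling (success probability 0.5,
#' minimum-likelihood-sum two-sided convention); homozygous sites get no
#' test.
#'
#' @param counts an `AllelicReadCount` (or list with `n_major`,
#'   `n_minor`).
#' @param min_each minimum reads per allele for a heterozygous call
#'   (default 5).
#' @return The completed `AllelicReadCount` with `heterozygous` and
#'   `p_value` filled.
#' @export
test_allelic_bias <- function(counts, min_each = 5L) {
  n_major <- counts$n_major; n_minor <- counts$n_minor
  if (n_major < 0 || n_minor < 0) stop("read counts must be nonnegative")
  counts$heterozygous <- n_major >= min_each && n_minor >= min_each
  counts$p_value <- if (counts$heterozygous)
    binom.test(n_major, n_major + n_minor, p = 0.5)$p.value
  else NA_real_
  counts
}

#' Flag SNPs confounded by a nearby catalogued SNP
#'
#' A second SNP within one read length (i.e. at distance <= read_length -
#' 1) can fall inside the same read windows and distort allele counting;
#' such sites are flagged and excluded from bias testing.
#'
#' @param snp one-row data.frame/list with `chrom`, `pos`, `id`.
#' @param catalogue SNP data.frame to search for neighbours.
#' @param read_length read length in bp.
#' @return TRUE if another catalogued SNP shares a read window with `snp`.
#' @export
flag_confounding_snps <- function(snp, catalogue, read_length) {
  near <- catalogue$chrom == snp$chrom &
    abs(catalogue$pos - snp$pos) <= read_length - 1L &
    !(catalogue$pos == snp$pos & catalogue$id == snp$id)
  any(near)
}

#' Spearman correlation between in vitro affinity and in vivo enrichment
#'
#' ChIP-seq enrichment is expected to correlate negatively with Fraction
#' Bound (low FB = strong competitor = high-affinity RE1).  Both the
#' direct convention (rho vs FB) and the "relative binding" convention
#' (rho vs 1 - FB) are reported.
#'
#' @param fb_values Fraction Bound values.
#' @param enrichments paired ChIP enrichment values.
#' @return List: `rho` (enrichment vs FB), `p_value`,
#'   `rho_relative_binding` (enrichment vs 1 - FB, = -rho), `n`.
#' @export
correlate_affinity_enrichment <- function(fb_values, enrichments) {
  if (length(fb_values) != length(enrichments))
    stop("fb_values and enrichments must be paired")
  if (length(fb_values) < 3L) stop("at least 3 pairs are required")
  if (sd(fb_values) == 0 || sd(enrichments) == 0)
    stop("correlation is undefined for a constant input vector")
  ct <- suppressWarnings(cor.test(enrichments, fb_values,
                                  method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       rho_relative_binding = -unname(ct$estimate),
       n = length(fb_values))
}

#' qPCR fold enrichment by the delta-delta-Ct method
#'
#' Target Ct values are normalized to a non-target control locus within
#' the immunoprecipitate and within input, and the fold enrichment is
#' `2^-(dCt_ip - dCt_input)`.
#'
#' @param ct_target_ip,ct_control_ip Ct values in the ChIP sample.
#' @param ct_target_input,ct_control_input Ct values in input DNA.
#' @return Fold enrichment (1.0 = no enrichment).
#' @export
ddct_enrichment <- function(ct_target_ip, ct_control_ip,
                            ct_target_input, ct_control_input) {
  cts <- c(ct_target_ip, ct_control_ip, ct_target_input, ct_control_input)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  d_ip <- ct_target_ip - ct_control_ip
  d_input <- ct_target_input - ct_control_input
  2^(-(d_ip - d_input))
}
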