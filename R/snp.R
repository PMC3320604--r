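## Intersection of RE1 half sites with SNVs and construction of the
## polymorphic-RE1 (pRE1) catalogue.
##
## Only variants inside the strongly constrained half sites are considered:
## motif positions 1-9 (left) and (10+spacer)-(15+spacer) (right).  The
## allele present in the reference genome is defined as the Major allele
## even when it is the rarer variant in populations; the catalogue keeps
## such "reference-rare" cases as-is.

#' Intersect motif half sites with SNVs
#'
#' One record is produced per (hit, SNP) pair whose genomic position falls
#' inside a half-site interval; SNPs in the spacer or flanks are excluded.
#' A hit carrying two half-site SNPs yields two records with suffixed ids
#' (`X-1`, `X-2`).  SNPs whose REF base disagrees with the genome are
#' rejected with a warning.
#'
#' @param hits motif-hit data.frame from [scan_peaks()].
#' @param snps SNV data.frame from [read_snps()].
#' @param genome named list of contig sequences (used to verify REF).
#' @return data.frame: `pre1_id`, `region_name`, `chrom`, `hit_start`,
#'   `hit_end`, `strand`, `spacer`, `score`, `canonical`, `snp_id`, `pos`,
#'   `ref`, `alt`, `maf`, `motif_position`, `half_site`.
#' @export
intersect_half_sites <- function(hits, snps, genome = NULL) {
  if (!is.null(genome)) genome <- as_genome(genome)
  recs <- list()
  for (i in seq_len(nrow(hits))) {
    hit <- hits[i, , drop = FALSE]
    hs <- half_site_intervals(hit)
    on_chrom <- snps[snps$chrom == hit$chrom, , drop = FALSE]
    if (!nrow(on_chrom)) next
    in_left <- on_chrom$pos >= hs$left[1] & on_chrom$pos < hs$left[2]
    in_right <- on_chrom$pos >= hs$right[1] & on_chrom$pos < hs$right[2]
    sel <- on_chrom[in_left | in_right, , drop = FALSE]
    if (!nrow(sel)) next
    sel$half_site <- ifelse(sel$pos >= hs$left[1] & sel$pos < hs$left[2],
                            "left", "right")
    sel <- sel[order(sel$pos), , drop = FALSE]
    for (k in seq_len(nrow(sel))) {
      snp <- sel[k, , drop = FALSE]
      if (!is.null(genome)) {
        gbase <- substr(genome[[as.character(hit$chrom)]],
                        snp$pos + 1L, snp$pos + 1L)
        if (gbase != snp$ref) {
          warning("SNP ", snp$id, ": REF ", snp$ref,
                  " does not match genome base ", gbase, " at ",
                  hit$chrom, ":", snp$pos, "; record rejected")
          next
        }
      }
      recs[[length(recs) + 1L]] <- data.frame(
        pre1_id = as.character(hit$region_name),
        region_name = as.character(hit$region_name),
        chrom = as.character(hit$chrom),
        hit_start = hit$start, hit_end = hit$end,
        strand = hit$strand, spacer = hit$spacer,
        score = hit$score, canonical = hit$canonical,
        snp_id = snp$id, pos = snp$pos, ref = snp$ref, alt = snp$alt,
        maf = snp$maf,
        motif_position = motif_position_of(hit, snp$pos),
        half_site = snp$half_site,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) return(empty_pre1())
  # suffix ids for hits that carry >1 half-site SNP
  dup <- ave(seq_len(nrow(out)), out$region_name, out$chrom, out$hit_start,
             FUN = length) > 1
  idx <- ave(seq_len(nrow(out)),
             paste(out$region_name, out$chrom, out$hit_start),
             FUN = seq_along)
  out$pre1_id <- ifelse(dup, paste0(out$pre1_id, "-", idx), out$pre1_id)
  rownames(out) <- NULL
  out
}

empty_pre1 <- function() {
  data.frame(pre1_id = character(), region_name = character(),
             chrom = character(), hit_start = integer(), hit_end = integer(),
             strand = character(), spacer = integer(), score = numeric(),
             canonical = logical(), snp_id = character(), pos = integer(),
             ref = character(), alt = character(), maf = numeric(),
             motif_position = integer(), half_site = character(),
             stringsAsFactors = FALSE)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMPLEMENT[strsplit(toupper(s), "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Assign Major/Minor allele sequences and motif-score deltas
#'
#' The Major allele is the reference-genome sequence over the hit interval
#' (strand-oriented, so minus-strand motifs are reverse-complemented); the
#' Minor allele substitutes the ALT base at the SNP's motif position.  The
#' motif-score delta (`normalized(minor) - normalized(major)`) is computed
#' with the spacer variant matching each hit.
#'
#' @param pre1 catalogue data.frame from [intersect_half_sites()].
#' @param genome named list of contig sequences.
#' @param half `HalfSitePWM` used to rebuild the spacer variants.
#' @return The catalogue with `major_seq`, `minor_seq` and `score_delta`
#'   columns filled in.
#' @export
assign_alleles <- function(pre1, genome, half) {
  genome <- as_genome(genome)
  pwms <- lapply(setNames(0:12, 0:12), function(sp) re1_pwm(half, sp))
  pre1$major_seq <- rep(NA_character_, nrow(pre1))
  pre1$minor_seq <- rep(NA_character_, nrow(pre1))
  pre1$score_delta <- rep(NA_real_, nrow(pre1))
  for (i in seq_len(nrow(pre1))) {
    r <- pre1[i, ]
    if (r$alt == r$ref)
      stop("SNP ", r$snp_id, ": ALT equals REF")
    win <- substr(genome[[r$chrom]], r$hit_start + 1L, r$hit_end)
    if (r$strand == "-") win <- revcomp(win)
    sub_base <- if (r$strand == "+") r$alt else unname(COMPLEMENT[r$alt])
    minor <- win
    substr(minor, r$motif_position, r$motif_position) <- sub_base
    pwm <- pwms[[as.character(r$spacer)]]
    pre1$major_seq[i] <- win
    pre1$minor_seq[i] <- minor
    pre1$score_delta[i] <- score_allele_delta(pwm, win, minor)
  }
  pre1
}

#' Filter the catalogue by minor-allele frequency
#'
#' Records with a known MAF below `min_maf` are removed (the
#' second-generation screen kept only common SNPs, MAF >= 1\%).  Records
#' with unknown MAF are kept and flagged by default, or dropped with
#' `keep_unknown = FALSE`.
#'
#' @param records pRE1 catalogue data.frame (with a `maf` column).
#' @param min_maf minimum minor-allele frequency in \[0, 0.5\] (default
#'   0.01).
#' @param keep_unknown keep records with unknown MAF? Default TRUE.
#' @return Filtered catalogue; kept unknown-MAF records carry
#'   `maf_unknown = TRUE`.
#' @export
apply_frequency_filter <- function(records, min_maf = 0.01,
                                   keep_unknown = TRUE) {
  if (min_maf < 0 || min_maf > 0.5)
    stop("min_maf must lie in [0, 0.5]")
  records$maf_unknown <- is.na(records$maf)
  keep <- ifelse(records$maf_unknown, keep_unknown, records$maf >= min_maf)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate catalogue records with distance to the nearest TSS
#'
#' Signed distance from the motif midpoint to the nearest transcription
#' start site; negative values mean the motif lies upstream of the TSS
#' (relative to gene orientation).
#'
#' @param pre1 catalogue data.frame.
#' @param tss data.frame with `chrom`, `pos` (0-based TSS position),
#'   `gene`, `strand` (gene strand).
#' @return Catalogue with `gene` and `tss_dist` columns.
#' @export
annotate_tss_distance <- function(pre1, tss) {
  pre1$gene <- NA_character_
  pre1$tss_dist <- NA_integer_
  for (i in seq_len(nrow(pre1))) {
    cand <- tss[tss$chrom == pre1$chrom[i], , drop = FALSE]
    if (!nrow(cand)) next
    mid <- (pre1$hit_start[i] + pre1$hit_end[i]) %/% 2L
    j <- which.min(abs(cand$pos - mid))
    d <- mid - cand$pos[j]
    if (!is.null(cand$strand) && cand$strand[j] == "-") d <- -d
    pre1$gene[i] <- cand$gene[j]
    pre1$tss_dist[i] <- d
  }
  pre1
}
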