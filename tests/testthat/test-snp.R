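make_hit <- function(fx, name = "pk1") {
  data.frame(region_name = name, chrom = "chrT", start = fx$start,
             end = fx$end, strand = fx$strand, spacer = fx$spacer,
             score = 1, raw = 0, canonical = fx$spacer == 2,
             stringsAsFactors = FALSE)
}

snp_at <- function(fx, motif_position, id = "rsX", alt = NULL) {
  # map a motif position to the genomic position for the fixture's strand
  pos <- if (fx$strand == "+") fx$start + motif_position - 1
    else fx$end - motif_position
  ref <- substr(fx$genome$chrT, pos + 1, pos + 1)
  if (is.null(alt)) alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  data.frame(chrom = "chrT", pos = pos, id = id, ref = ref, alt = alt,
             maf = 0.2, stringsAsFactors = FALSE)
}

test_that("spacer SNPs are excluded and half-site SNPs assigned to sides", {
  fx <- fixture_genome()
  hits <- make_hit(fx)
  spacer_snp <- snp_at(fx, 10)      # canonical spacer = positions 10-11
  expect_equal(nrow(intersect_half_sites(hits, spacer_snp, fx$genome)), 0)
  expect_equal(nrow(intersect_half_sites(hits, snp_at(fx, 11), fx$genome)), 0)

  left <- intersect_half_sites(hits, snp_at(fx, 5), fx$genome)
  expect_equal(left$half_site, "left")
  expect_equal(left$motif_position, 5)
  right <- intersect_half_sites(hits, snp_at(fx, 13), fx$genome)
  expect_equal(right$half_site, "right")
  # flanking SNP outside the motif
  out <- snp_at(fx, 0, id = "flank")
  expect_equal(nrow(intersect_half_sites(hits, out, fx$genome)), 0)
})

test_that("a motif with two half-site SNPs yields two suffixed records", {
  fx <- fixture_genome()
  hits <- make_hit(fx, "pRE1-5")
  snps <- rbind(snp_at(fx, 4, id = "rs1"), snp_at(fx, 13, id = "rs2"))
  recs <- intersect_half_sites(hits, snps, fx$genome)
  expect_equal(nrow(recs), 2)
  expect_setequal(recs$pre1_id, c("pRE1-5-1", "pRE1-5-2"))
  expect_equal(sort(recs$motif_position), c(4, 13))
})

test_that("REF bases disagreeing with the genome are rejected with a warning", {
  fx <- fixture_genome()
  bad <- snp_at(fx, 5)
  bad$ref <- setdiff(c("A", "C", "G", "T"), c(bad$ref, bad$alt))[1]
  expect_warning(recs <- intersect_half_sites(make_hit(fx), bad, fx$genome),
                 "does not match")
  expect_equal(nrow(recs), 0)
})

test_that("record count matches a brute-force interval scan on synthetic data", {
  sim <- simulate_bundle(sim_config(seed = 33, genome_length = 5e4,
                                    n_motifs = 8, n_snps = 8, depth = 10))
  half <- default_re1_pwm()
  pwms <- build_spacer_variants(half)
  std <- standardize_peaks(sim$peaks, 100,
                           vapply(sim$genome, nchar, numeric(1)))
  hits <- scan_peaks(sim$genome, std, pwms)
  recs <- intersect_half_sites(hits, sim$snps, sim$genome)
  # brute force: count (hit, snp) pairs with the snp inside a half site
  n_bf <- 0
  for (i in seq_len(nrow(hits))) {
    hs <- half_site_intervals(hits[i, ])
    for (j in seq_len(nrow(sim$snps))) {
      p <- sim$snps$pos[j]
      if ((p >= hs$left[1] && p < hs$left[2]) ||
          (p >= hs$right[1] && p < hs$right[2])) n_bf <- n_bf + 1
    }
  }
  expect_equal(nrow(recs), n_bf)
  expect_gt(nrow(recs), 0)
})

test_that("major allele is the reference and minor differs at one position", {
  fx <- fixture_genome(strand = "+")
  recs <- intersect_half_sites(make_hit(fx), snp_at(fx, 7, alt = NULL),
                               fx$genome)
  recs <- assign_alleles(recs, fx$genome, default_re1_pwm())
  expect_equal(recs$major_seq, fx$window)       # re-extractable reference
  d <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
              recs$major_seq, recs$minor_seq)
  expect_equal(unname(d), 1)
  expect_equal(substr(recs$minor_seq, 7, 7), recs$alt)
  # consensus major + consensus-breaking alt => worse motif
  expect_lt(recs$score_delta, 0)
})

test_that("minus-strand alleles carry the complemented base at the mapped index", {
  fx <- fixture_genome(strand = "-")
  snp <- snp_at(fx, 7)  # genomic ref is the complement of the motif base
  recs <- intersect_half_sites(make_hit(fx), snp, fx$genome)
  recs <- assign_alleles(recs, fx$genome, default_re1_pwm())
  expect_equal(recs$major_seq, fx$window)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_equal(substr(recs$minor_seq, 7, 7), unname(comp[recs$alt]))
  expect_lt(recs$score_delta, 0)
})

test_that("screening the reverse-complemented genome mirrors the catalogue", {
  sim <- simulate_bundle(sim_config(seed = 44, genome_length = 3e4,
                                    n_motifs = 5, n_snps = 5, depth = 5))
  half <- default_re1_pwm()
  pwms <- build_spacer_variants(half)
  n <- nchar(sim$genome$chrS)
  fwd_hits <- scan_peaks(sim$genome, standardize_peaks(
    sim$peaks, 100, c(chrS = n)), pwms)
  fwd <- assign_alleles(
    intersect_half_sites(fwd_hits, sim$snps, sim$genome),
    sim$genome, half)

  rc_genome <- list(chrS = rc(sim$genome$chrS))
  rc_peaks <- data.frame(chrom = "chrS", start = n - sim$peaks$end,
                         end = n - sim$peaks$start, name = sim$peaks$name,
                         summit = n - 1 - sim$peaks$summit)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_snps <- sim$snps
  rc_snps$pos <- n - 1 - sim$snps$pos
  rc_snps$ref <- unname(comp[sim$snps$ref])
  rc_snps$alt <- unname(comp[sim$snps$alt])
  rc_hits <- scan_peaks(rc_genome, standardize_peaks(
    rc_peaks, 100, c(chrS = n)), pwms)
  rev <- assign_alleles(
    intersect_half_sites(rc_hits, rc_snps, rc_genome), rc_genome, half)

  fwd <- fwd[order(fwd$snp_id), ]; rev <- rev[order(rev$snp_id), ]
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(fwd$motif_position, rev$motif_position)
  expect_equal(fwd$major_seq, rev$major_seq)    # strand-oriented, so equal
  expect_equal(fwd$minor_seq, rev$minor_seq)
  expect_equal(fwd$score_delta, rev$score_delta)
  expect_equal(fwd$hit_start, n - rev$hit_end)  # coordinates mirrored
})

test_that("frequency filter drops rare known MAFs and flags unknown ones", {
  recs <- data.frame(snp_id = c("a", "b", "c", "d"),
                     maf = c(0.30, 0.005, NA, 0.01))
  kept <- apply_frequency_filter(recs, min_maf = 0.01)
  expect_setequal(kept$snp_id, c("a", "c", "d"))
  expect_true(kept$maf_unknown[kept$snp_id == "c"])
  expect_equal(nrow(apply_frequency_filter(recs, min_maf = 0,
                                           keep_unknown = TRUE)), 4)
  expect_equal(nrow(apply_frequency_filter(recs, min_maf = 0.01,
                                           keep_unknown = FALSE)), 2)
  expect_error(apply_frequency_filter(recs, min_maf = 0.7), "0.5")
})

test_that("TSS distances are signed by gene orientation", {
  pre1 <- data.frame(chrom = "chrT", hit_start = 1000, hit_end = 1017)
  tss <- data.frame(chrom = "chrT", pos = c(1500, 5000),
                    gene = c("G1", "G2"), strand = c("+", "+"))
  ann <- annotate_tss_distance(pre1, tss)
  expect_equal(ann$gene, "G1")
  expect_equal(ann$tss_dist, -492)   # motif upstream of the TSS
  tss$strand <- c("-", "-")
  expect_equal(annotate_tss_distance(pre1, tss)$tss_dist, 492)
})
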