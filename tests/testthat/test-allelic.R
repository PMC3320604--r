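test_that("k-mer enumeration covers every window over the SNP, both strands", {
  fx <- allelic_fixture()
  ks <- enumerate_allele_kmers(fx$genome, fx$snp, 25)
  expect_equal(length(ks$major_kmers), 50)   # 25 forward + 25 revcomp
  expect_equal(length(ks$minor_kmers), 50)
  expect_length(intersect(ks$major_kmers, ks$minor_kmers), 0)
  expect_true(all(nchar(ks$major_kmers) == 25))
  # every forward major k-mer is re-extractable at its source locus
  fwd <- ks$major_kmers[vapply(ks$major_kmers, function(k)
    grepl(k, fx$genome$chrT, fixed = TRUE), logical(1))]
  expect_equal(length(fwd), 25)
  # minor k-mers all carry the alt base and never the ref at the SNP
  expect_true(all(vapply(ks$minor_kmers, function(k)
    !grepl(k, fx$genome$chrT, fixed = TRUE), logical(1))))
})

test_that("k-mer enumeration clips at contig edges", {
  fx <- allelic_fixture()
  snp_near_start <- fx$snp
  snp_near_start$pos <- 10
  snp_near_start$ref <- substr(fx$genome$chrT, 11, 11)
  snp_near_start$alt <- setdiff(c("A", "C", "G", "T"),
                                snp_near_start$ref)[1]
  ks <- enumerate_allele_kmers(fx$genome, snp_near_start, 25)
  expect_equal(length(ks$major_kmers), 22)   # 11 forward offsets x 2 strands
  bad <- fx$snp; bad$alt <- bad$ref
  expect_error(enumerate_allele_kmers(fx$genome, bad, 25), "ALT equals REF")
})

test_that("uniqueness filter removes duplicated and pre-existing k-mers", {
  fx <- allelic_fixture(seed = 78, len = 600, pos = 100)
  # duplicate the segment around the SNP elsewhere in the genome
  seg <- substr(fx$genome$chrT, 70, 130)  # covers every SNP window
  dup <- fx$genome
  dup$chrT <- paste0(dup$chrT, seg)
  ks <- enumerate_allele_kmers(dup, fx$snp, 25)
  filt <- filter_unique_kmers(ks, dup)
  expect_true(filt$unique_only)
  expect_equal(length(filt$major_kmers), 0)  # every window now has 2 copies
  # on the original genome everything is retained
  ks1 <- filter_unique_kmers(enumerate_allele_kmers(fx$genome, fx$snp, 25),
                             fx$genome)
  expect_equal(length(ks1$major_kmers), 50)
  expect_equal(length(ks1$minor_kmers), 50)
  # a minor k-mer pre-existing in the reference is removed
  minor_kmer <- substr(fx$genome$chrT, fx$snp$pos - 2, fx$snp$pos + 22)
  substr(minor_kmer, 4, 4) <- fx$snp$alt   # SNP sits at offset 4 here
  planted <- fx$genome
  planted$chrT <- paste0(planted$chrT, minor_kmer)
  ks2 <- enumerate_allele_kmers(planted, fx$snp, 25)
  filt2 <- filter_unique_kmers(ks2, planted)
  expect_lt(length(filt2$minor_kmers), length(ks2$minor_kmers))
  expect_false(minor_kmer %in% filt2$minor_kmers)
})

test_that("read counting is exact full-length string membership", {
  fx <- allelic_fixture()
  ks <- enumerate_allele_kmers(fx$genome, fx$snp, 25)
  one_major <- ks$major_kmers[1]
  counts <- count_allelic_reads(rep(one_major, 7), ks)
  expect_equal(c(counts$n_major, counts$n_minor), c(7, 0))
  empty <- count_allelic_reads(character(0), ks)
  expect_equal(c(empty$n_major, empty$n_minor), c(0, 0))
  # a read one base off matches nothing
  off <- one_major
  substr(off, 13, 13) <- setdiff(c("A", "C", "G", "T"),
                                 substr(off, 13, 13))[1]
  expect_equal(count_allelic_reads(off, ks)$n_major, 0)
  # longer reads are matched through their length-L substrings, once
  long <- paste0("ACGT", one_major, "TTT")
  expect_equal(count_allelic_reads(long, ks)$n_major, 1)
  # short reads are skipped and reported
  expect_message(sh <- count_allelic_reads("ACGTACGT", ks), "skipped")
  expect_equal(sh$n_skipped, 1)
})

test_that("synthetic reads at a 0.7 ratio give counts within binomial noise", {
  sim <- simulate_bundle(sim_config(seed = 91, genome_length = 3e4,
                                    n_motifs = 4, n_snps = 2, depth = 200,
                                    true_allele_ratio = 0.7))
  s <- sim$truth$snps[1, ]
  ks <- filter_unique_kmers(
    enumerate_allele_kmers(sim$genome, s, 25), sim$genome)
  reads <- sim$reads$seq[sim$reads$snp_id == s$id]
  counts <- count_allelic_reads(reads, ks)
  expect_equal(counts$n_major + counts$n_minor, 200)
  ci <- qbinom(c(0.0005, 0.9995), 200, 0.7)
  expect_gte(counts$n_major, ci[1])
  expect_lte(counts$n_major, ci[2])
  # counts must also agree with the generator's per-read truth
  expect_equal(counts$n_major, sum(sim$reads$allele[sim$reads$snp_id ==
                                                      s$id] == "major"))
})

test_that("heterozygosity calls follow the >=5-reads-per-allele rule", {
  res <- test_allelic_bias(list(n_major = 12, n_minor = 0))
  expect_false(res$heterozygous)
  expect_true(is.na(res$p_value))
  res <- test_allelic_bias(list(n_major = 5, n_minor = 5))
  expect_true(res$heterozygous)
  expect_equal(res$p_value, 1)
  res <- test_allelic_bias(list(n_major = 4, n_minor = 5))
  expect_false(res$heterozygous)
  expect_error(test_allelic_bias(list(n_major = -1, n_minor = 3)),
               "nonnegative")
})

test_that("binomial p-values equal direct pmf tail summation", {
  for (pair in list(c(40, 10), c(5, 5), c(100, 80), c(7, 23), c(60, 61))) {
    res <- test_allelic_bias(list(n_major = pair[1], n_minor = pair[2]))
    expect_equal(res$p_value, oracle_binom_p(pair[1], sum(pair)),
                 tolerance = 1e-12)
  }
})

test_that("nearby catalogued SNPs are flagged as confounders, boundary inclusive", {
  cat <- data.frame(chrom = "chrT", pos = c(100, 110, 300),
                    id = c("s1", "s2", "s3"))
  expect_true(flag_confounding_snps(cat[1, ], cat, 25))   # 10 bp away
  expect_false(flag_confounding_snps(cat[3, ], cat, 25))  # 190 bp away
  cat2 <- data.frame(chrom = "chrT", pos = c(100, 124), id = c("s1", "s2"))
  expect_true(flag_confounding_snps(cat2[1, ], cat2, 25)) # exactly L-1
  cat3 <- data.frame(chrom = "chrT", pos = c(100, 125), id = c("s1", "s2"))
  expect_false(flag_confounding_snps(cat3[1, ], cat3, 25))
})

test_that("affinity-enrichment correlation is negative by convention", {
  fb <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  enr <- c(50, 40, 30, 20, 10)        # strictly decreasing in FB
  res <- correlate_affinity_enrichment(fb, enr)
  expect_equal(res$rho, -1)
  expect_equal(res$rho_relative_binding, 1)
  expect_error(correlate_affinity_enrichment(rep(0.5, 5), enr), "constant")
  expect_error(correlate_affinity_enrichment(fb, enr[1:3]), "paired")
  # independent pairs: mean rho near zero
  set.seed(24)
  rhos <- replicate(500,
    correlate_affinity_enrichment(runif(8), runif(8))$rho)
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("delta-delta-Ct enrichment follows the base-2 definition", {
  expect_equal(ddct_enrichment(20, 20, 20, 20), 1)
  expect_equal(ddct_enrichment(19, 20, 20, 20), 2)
  expect_equal(ddct_enrichment(20 - 3.32, 20, 20, 20), 2^3.32)
  expect_equal(round(ddct_enrichment(20 - 3.32, 20, 20, 20), 1), 10)
  expect_error(ddct_enrichment(NA, 20, 20, 20), "finite")
})
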