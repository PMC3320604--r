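## Orchestration of the screen: peaks -> 100-bp standardization -> RE1
## scan -> half-site SNP overlap -> allele assignment -> optional EMSA
## classification and allelic read-bias analysis.  Every effective
## threshold is echoed to the run log so any reported number can be traced
## to its parameters.

#' Screen configuration
#'
#' @param genome path to the genome FASTA (or an in-memory genome list).
#' @param peaks path to a BED/narrowPeak file (or a peak data.frame); may
#'   be a vector/list of several sets, which are merged.
#' @param vcf path to the SNP VCF (or a SNP data.frame).
#' @param reads optional FASTQ path (or named character vector) for
#'   allelic read analysis.
#' @param lanes optional EMSA lane TSV path (or data.frame) for affinity
#'   classification.
#' @param pwm `"default"` or a motif-file path (see [load_pwm()]).
#' @param peak_width standardized region width (default 100).
#' @param score_threshold minimum normalized motif score (default 0.88).
#' @param spacer_min,spacer_max spacer-length range (default 0-12).
#' @param delta_min minimum |Fraction Bound change| for an effect call
#'   (default 0.1).
#' @param alpha significance level (default 0.05, uncorrected).
#' @param min_maf minor-allele-frequency filter (default 0 = keep all;
#'   the second-generation preset is 0.01).
#' @param min_reads_each heterozygosity rule: minimum reads per allele
#'   (default 5).
#' @param read_length read length for k-mer enumeration; default 25.
#' @param unique_kmers apply the genome-uniqueness k-mer filter (default
#'   TRUE).
#' @param out_dir optional directory for TSV/log outputs.
#' @return List of class `ScreenConfig`.
#' @export
screen_config <- function(genome, peaks, vcf, reads = NULL, lanes = NULL,
                          pwm = "default", peak_width = 100L,
                          score_threshold = 0.88, spacer_min = 0L,
                          spacer_max = 12L, delta_min = 0.1, alpha = 0.05,
                          min_maf = 0, min_reads_each = 5L,
                          read_length = 25L, unique_kmers = TRUE,
                          out_dir = NULL) {
  if (score_threshold < 0 || alpha <= 0 || alpha > 1 ||
      delta_min < 0 || min_maf < 0 || min_maf > 0.5)
    stop("threshold out of documented range")
  structure(as.list(environment()), class = "ScreenConfig")
}

#' Run the polymorphic-RE1 screen
#'
#' Executes the stages in order and fails with a stage-named error on any
#' stage failure.  With `out_dir` set, writes `catalogue.tsv`,
#' `class_summary.tsv`, `position_profile.tsv`, `allelic.tsv` (when reads
#' are given) and `run.log`.
#'
#' @param cfg a `ScreenConfig`.
#' @return List: `hits`, `catalogue` (pRE1 records with alleles and score
#'   deltas), `emsa` (comparison table, or NULL), `allelic` (read-bias
#'   table, or NULL), `summary` (class counts), `log` (character vector).
#' @export
run_screen <- function(cfg) {
  log <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  for (p in c("peak_width", "score_threshold", "spacer_min", "spacer_max",
              "delta_min", "alpha", "min_maf", "min_reads_each",
              "read_length", "unique_kmers"))
    say("param ", p, " = ", cfg[[p]])

  genome <- stage("load_genome",
    if (is.character(cfg$genome)) read_genome(cfg$genome)
    else as_genome(cfg$genome))
  contig_lengths <- vapply(genome, nchar, numeric(1))

  peaks <- stage("load_peaks", {
    ps <- cfg$peaks
    if (!is.list(ps) || is.data.frame(ps)) ps <- list(ps)
    sets <- lapply(ps, function(p)
      if (is.character(p)) read_peaks(p) else p)
    if (length(sets) > 1L) merge_peak_sets(sets) else sets[[1]]
  })
  say("loaded ", nrow(peaks), " peak region(s)")

  half <- stage("load_pwm",
    if (identical(cfg$pwm, "default")) default_re1_pwm()
    else load_pwm(cfg$pwm))
  pwms <- build_spacer_variants(half, cfg$spacer_min, cfg$spacer_max)

  std <- stage("standardize_peaks",
    standardize_peaks(peaks, width = cfg$peak_width,
                      contig_lengths = contig_lengths))
  hits <- stage("scan",
    scan_peaks(genome, std, pwms, threshold = cfg$score_threshold))
  say(nrow(hits), " region(s) contain an RE1 at score >= ",
      cfg$score_threshold, " (", sum(hits$canonical), " canonical / ",
      sum(!hits$canonical), " noncanonical)")

  snps <- stage("load_snps",
    if (is.character(cfg$vcf)) read_snps(cfg$vcf) else cfg$vcf)
  catalogue <- stage("overlap", {
    cat <- intersect_half_sites(hits, snps, genome)
    cat <- assign_alleles(cat, genome, half)
    if (cfg$min_maf > 0)
      cat <- apply_frequency_filter(cat, min_maf = cfg$min_maf)
    cat
  })
  say(nrow(catalogue), " half-site SNP record(s) in ",
      length(unique(catalogue$region_name)), " RE1(s)")

  emsa <- NULL
  if (!is.null(cfg$lanes)) {
    emsa <- stage("emsa", {
      lanes <- if (is.character(cfg$lanes)) read_emsa_lanes(cfg$lanes)
        else cfg$lanes
      tab <- emsa_comparison_table(lanes, delta_min = cfg$delta_min,
                                   alpha = cfg$alpha)
      merge(catalogue, tab,
            by.x = "snp_id", by.y = "competitor_label", all.x = TRUE)
    })
    say(sum(emsa$effect_class %in% c("UP", "DOWN"), na.rm = TRUE),
        " record(s) with a significant allelic affinity difference")
  }

  allelic <- NULL
  if (!is.null(cfg$reads)) {
    allelic <- stage("allelic", {
      reads <- if (is.character(cfg$reads)) read_reads(cfg$reads)
        else cfg$reads
      allelic_bias_table(genome, catalogue, reads,
                         read_length = cfg$read_length,
                         min_each = cfg$min_reads_each,
                         unique_kmers = cfg$unique_kmers)
    })
    say(sum(allelic$heterozygous), " heterozygous site(s) tested for ",
        "allelic bias")
  }

  summary <- summarize_classes(if (is.null(emsa)) catalogue else emsa,
                               alpha = cfg$alpha)
  out <- list(hits = hits, catalogue = catalogue, emsa = emsa,
              allelic = allelic, summary = summary, log = log)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(catalogue, file.path(cfg$out_dir, "catalogue.tsv"))
    write_tsv(summary, file.path(cfg$out_dir, "class_summary.tsv"))
    if (!is.null(emsa)) {
      write_tsv(emsa, file.path(cfg$out_dir, "emsa.tsv"))
      prof <- position_effect_profile(emsa[!is.na(emsa$delta_fb), ])
      write_tsv(prof[, setdiff(names(prof), "values")],
                file.path(cfg$out_dir, "position_profile.tsv"))
    }
    if (!is.null(allelic))
      write_tsv(allelic, file.path(cfg$out_dir, "allelic.tsv"))
    writeLines(log, file.path(cfg$out_dir, "run.log"))
  }
  out
}

#' Allelic read-bias table for a pRE1 catalogue
#'
#' Enumerates allele-distinguishing k-mers per SNP, optionally filters
#' them for genome uniqueness, counts matching reads, flags SNPs
#' confounded by another catalogued SNP within one read length, and runs
#' the exact binomial bias test on unconfounded heterozygous sites.
#'
#' @param genome named list of contig sequences.
#' @param catalogue pRE1 catalogue (needs `chrom`, `pos`, `id`/`snp_id`,
#'   `ref`, `alt`).
#' @param reads character vector of read sequences.
#' @param read_length read length L.
#' @param min_each heterozygosity rule (default 5 reads per allele).
#' @param unique_kmers apply [filter_unique_kmers()] (default TRUE).
#' @return data.frame: `snp_id`, `n_major`, `n_minor`, `heterozygous`,
#'   `p_value`, `confounded`.
#' @export
allelic_bias_table <- function(genome, catalogue, reads, read_length = 25L,
                               min_each = 5L, unique_kmers = TRUE) {
  genome <- as_genome(genome)
  snps <- catalogue
  if (!"id" %in% names(snps) && "snp_id" %in% names(snps))
    snps$id <- snps$snp_id
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    snp <- snps[i, ]
    kset <- enumerate_allele_kmers(genome, snp, read_length)
    if (unique_kmers) kset <- filter_unique_kmers(kset, genome)
    counts <- count_allelic_reads(reads, kset)
    counts$confounded <- flag_confounding_snps(snp, snps, read_length)
    if (!counts$confounded)
      counts <- test_allelic_bias(counts, min_each = min_each)
    else counts$heterozygous <- FALSE
    data.frame(snp_id = snp$id, n_major = counts$n_major,
               n_minor = counts$n_minor,
               heterozygous = isTRUE(counts$heterozygous),
               p_value = counts$p_value, confounded = counts$confounded,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize effect classes of a classified catalogue
#'
#' Counts DOWN / UP / NO_DIFFERENCE calls, the number of records reaching
#' p < alpha regardless of the Fraction-Bound-change threshold (the two
#' headline conventions are reported side by side), and the
#' canonical/noncanonical breakdown.
#'
#' @param catalogue data.frame, optionally with `effect_class`,
#'   `p_value`, `canonical` columns.
#' @param alpha significance level for the p-only count.
#' @return One-row data.frame: `n_records`, `n_down`, `n_up`,
#'   `n_no_difference`, `n_p_significant`, `n_canonical`,
#'   `n_noncanonical`.
#' @export
summarize_classes <- function(catalogue, alpha = 0.05) {
  cls <- if ("effect_class" %in% names(catalogue)) catalogue$effect_class
    else character(0)
  pv <- if ("p_value" %in% names(catalogue)) catalogue$p_value
    else numeric(0)
  data.frame(
    n_records = nrow(catalogue),
    n_down = sum(cls == "DOWN", na.rm = TRUE),
    n_up = sum(cls == "UP", na.rm = TRUE),
    n_no_difference = sum(cls == "NO_DIFFERENCE", na.rm = TRUE),
    n_p_significant = sum(pv < alpha, na.rm = TRUE),
    n_canonical = if ("canonical" %in% names(catalogue))
      sum(catalogue$canonical, na.rm = TRUE) else NA_integer_,
    n_noncanonical = if ("canonical" %in% names(catalogue))
      sum(!catalogue$canonical, na.rm = TRUE) else NA_integer_)
}
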