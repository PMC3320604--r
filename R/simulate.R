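## Seeded synthetic-data generator.
##
## Emulates the statistical structure of the screen's inputs at desk
## scale: a random genome, peaks centred on implanted RE1 motifs of mixed
## spacer lengths, heterozygous SNVs inside motif half sites, ChIP-seq
## reads drawn with a configurable major:minor allele ratio, and EMSA
## replicate lanes with Gaussian noise around allele-specific Fraction
## Bound means.  One seed fixes every file byte-for-byte; each stage draws
## from its own sub-stream (seed + a fixed stage offset) so that, e.g.,
## changing the number of motifs does not perturb the read draws.

#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: a 1-Mb
#' genome with human-like GC, 50 implanted RE1s with a canonical-biased
#' spacer mix (the screen's polymorphic motifs were 52 canonical / 30
#' noncanonical), 30 heterozygous half-site SNVs with common-variant
#' frequencies, 25-nt reads at 200x site coverage with a 0.7 major-allele
#' fraction, and EMSA triplicates with 0.02 Fraction-Bound noise.
#'
#' @param seed integer seed fixing every downstream draw.
#' @param genome_length genome size in bp (>= 1000).
#' @param gc_content GC fraction in (0, 1).
#' @param n_motifs number of implanted RE1 motifs.
#' @param spacer_distribution weights over spacer lengths 0-12.
#' @param min_motif_score minimum normalized score of sampled implants.
#' @param n_snps number of injected SNVs (<= n_motifs; one per motif).
#' @param snp_placement where SNVs land: "half_site", "spacer" or "flank".
#' @param alt_mode "random" (any base != ref) or "worst" (the
#'   lowest-weight base in the SNP's motif column).
#' @param genotype "het", "hom_ref" or "hom_alt".
#' @param maf_range minor-allele frequency interval.
#' @param read_length read length in nt (the emulated libraries used 25
#'   and 35).
#' @param depth reads overlapping each SNP site.
#' @param true_allele_ratio major-allele fraction of reads at
#'   heterozygous sites, in (0, 1).
#' @param emsa_noise_sd Gaussian noise sd on replicate Fraction Bound.
#' @param replicates EMSA/reporter replicates per allele (default 3).
#' @param reporter_noise_sd Gaussian noise sd on reporter activity.
#' @param peak_width width of emitted peak intervals around implants.
#' @return List of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1e6,
                       gc_content = 0.41,
                       n_motifs = 50L,
                       spacer_distribution = c(rep(0.37 / 12, 2), 0.63,
                                               rep(0.37 / 12, 10)),
                       min_motif_score = 0.95,
                       n_snps = 30L,
                       snp_placement = c("half_site", "spacer", "flank"),
                       alt_mode = c("random", "worst"),
                       genotype = c("het", "hom_ref", "hom_alt"),
                       maf_range = c(0.01, 0.5),
                       read_length = 25L,
                       depth = 200L,
                       true_allele_ratio = 0.7,
                       emsa_noise_sd = 0.02,
                       replicates = 3L,
                       reporter_noise_sd = 0.08,
                       peak_width = 300L) {
  snp_placement <- match.arg(snp_placement)
  alt_mode <- match.arg(alt_mode)
  genotype <- match.arg(genotype)
  if (gc_content <= 0 || gc_content >= 1)
    stop("gc_content must lie strictly inside (0, 1)")
  if (genome_length < 1000) stop("genome_length must be >= 1000")
  if (true_allele_ratio <= 0 || true_allele_ratio >= 1)
    stop("true_allele_ratio must lie in (0, 1)")
  if (emsa_noise_sd < 0) stop("emsa_noise_sd must be nonnegative")
  if (length(spacer_distribution) != 13L || any(spacer_distribution < 0))
    stop("spacer_distribution must be 13 nonnegative weights (spacers 0-12)")
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 gc_content = gc_content, n_motifs = as.integer(n_motifs),
                 spacer_distribution = spacer_distribution,
                 min_motif_score = min_motif_score,
                 n_snps = as.integer(n_snps),
                 snp_placement = snp_placement, alt_mode = alt_mode,
                 genotype = genotype, maf_range = maf_range,
                 read_length = as.integer(read_length),
                 depth = as.integer(depth),
                 true_allele_ratio = true_allele_ratio,
                 emsa_noise_sd = emsa_noise_sd,
                 replicates = as.integer(replicates),
                 reporter_noise_sd = reporter_noise_sd,
                 peak_width = as.integer(peak_width)),
            class = "SimulationConfig")
}

# Per-stage sub-seeds, all well below 2^31.
stage_seed <- function(cfg, stage) {
  offsets <- c(genome = 101L, motifs = 211L, snps = 307L, reads = 401L,
               emsa = 503L, reporter = 601L)
  (cfg$seed %% 1000000L) * 1000L + offsets[[stage]]
}

#' Simulate an i.i.d. random genome
#'
#' @param cfg a `SimulationConfig`.
#' @return List: `genome` (named list with one contig, "chrS"), `truth`
#'   (skeleton truth table).
#' @export
simulate_genome <- function(cfg) {
  set.seed(stage_seed(cfg, "genome"))
  p <- c((1 - cfg$gc_content) / 2, cfg$gc_content / 2,
         cfg$gc_content / 2, (1 - cfg$gc_content) / 2)
  seq <- paste(sample(DNA_BASES, cfg$genome_length, replace = TRUE,
                      prob = p), collapse = "")
  list(genome = list(chrS = seq),
       truth = list(config = unclass(cfg), motifs = NULL, snps = NULL))
}

# Draw one window from the PWM (per-column categorical draws; spacer bases
# uniform), rejecting until the normalized score reaches min_score.
sample_motif_window <- function(half, spacer, min_score) {
  pwm <- re1_pwm(half, spacer)
  freqs <- cbind(half$left, half$right)
  repeat {
    informative <- vapply(seq_len(15L), function(j)
      sample(DNA_BASES, 1L, prob = freqs[, j]), character(1))
    spacer_bases <- if (spacer > 0L)
      sample(DNA_BASES, spacer, replace = TRUE) else character(0)
    window <- paste(c(informative[1:9], spacer_bases, informative[10:15]),
                    collapse = "")
    sc <- score_window(pwm, window)
    if (sc$normalized >= min_score)
      return(list(window = window, score = sc$normalized))
  }
}

#' Implant RE1 motifs and emit peaks
#'
#' Motifs are sampled from the PWM (per-column categorical draws,
#' rejection-sampled to `min_motif_score`), placed at non-overlapping
#' positions on random strands with spacer lengths drawn from
#' `spacer_distribution`; a peak interval of `peak_width` is emitted
#' centred on each implant.
#'
#' @param sim output of [simulate_genome()].
#' @param half a `HalfSitePWM`.
#' @param cfg a `SimulationConfig`.
#' @return `sim` with the genome modified in place, `peaks` (data.frame)
#'   added and `truth$motifs` filled (implant coordinates, strand, spacer,
#'   sampled score, window).
#' @export
implant_motifs <- function(sim, half, cfg) {
  set.seed(stage_seed(cfg, "motifs"))
  n <- nchar(sim$genome[[1]])
  margin <- cfg$peak_width
  spacing <- max(2L * cfg$peak_width, 250L)
  max_slots <- (n - 2L * margin) %/% spacing
  if (cfg$n_motifs > max_slots)
    stop("genome too small for ", cfg$n_motifs, " non-overlapping implants")
  slots <- sort(sample(max_slots, cfg$n_motifs))
  jitter <- sample(0:(spacing %/% 4L), cfg$n_motifs, replace = TRUE)
  centers <- margin + (slots - 1L) * spacing + jitter

  seq <- sim$genome[[1]]
  motifs <- vector("list", cfg$n_motifs)
  peaks <- vector("list", cfg$n_motifs)
  for (i in seq_len(cfg$n_motifs)) {
    spacer <- sample(0:12, 1L, prob = cfg$spacer_distribution)
    mw <- sample_motif_window(half, spacer, cfg$min_motif_score)
    L <- 15L + spacer
    strand <- sample(c("+", "-"), 1L)
    insert <- if (strand == "+") mw$window else revcomp(mw$window)
    start <- centers[i] - L %/% 2L          # 0-based
    substr(seq, start + 1L, start + L) <- insert
    motifs[[i]] <- data.frame(
      name = sprintf("motif_%02d", i), chrom = names(sim$genome)[1],
      start = start, end = start + L, strand = strand, spacer = spacer,
      score = mw$score, window = mw$window, stringsAsFactors = FALSE)
    p_start <- max(0L, centers[i] - cfg$peak_width %/% 2L)
    peaks[[i]] <- data.frame(
      chrom = names(sim$genome)[1], start = p_start,
      end = p_start + cfg$peak_width,
      name = sprintf("peak_%02d", i), summit = centers[i],
      stringsAsFactors = FALSE)
  }
  sim$genome[[1]] <- seq
  sim$truth$motifs <- do.call(rbind, motifs)
  sim$peaks <- do.call(rbind, peaks)
  sim
}

#' Inject SNVs into implanted motifs
#'
#' Places one SNV per selected motif at a configurable location (half
#' site, spacer, or flank), with REF equal to the implanted genome base,
#' ALT != REF, MAF drawn from `maf_range` and the configured genotype.
#'
#' @param sim output of [implant_motifs()].
#' @param half the `HalfSitePWM` used for implanting (needed for
#'   `alt_mode = "worst"`).
#' @param cfg a `SimulationConfig`.
#' @return `sim` with `snps` (data.frame usable as a VCF table) and
#'   `truth$snps` (adds motif name/position, half site, genotype, true
#'   allele ratio) filled.
#' @export
inject_snps <- function(sim, half, cfg) {
  if (is.null(sim$truth$motifs)) stop("implant motifs before injecting SNPs")
  set.seed(stage_seed(cfg, "snps"))
  if (cfg$n_snps > nrow(sim$truth$motifs))
    stop("n_snps exceeds the number of implanted motifs")
  chosen <- sort(sample(nrow(sim$truth$motifs), cfg$n_snps))
  seq <- sim$genome[[1]]
  weights <- cbind(half$weights)
  rows <- vector("list", cfg$n_snps)
  for (k in seq_along(chosen)) {
    m <- sim$truth$motifs[chosen[k], ]
    half_positions <- c(1:9, (10L + m$spacer):(15L + m$spacer))
    mp <- switch(cfg$snp_placement,
      half_site = sample(half_positions, 1L),
      spacer = if (m$spacer == 0L)
          stop("cannot place a spacer SNP in a spacer-0 motif")
        else sample(9L + seq_len(m$spacer), 1L),
      flank = (15L + m$spacer) + sample(1:10, 1L))
    gpos <- if (m$strand == "+") m$start + mp - 1L else m$end - mp
    ref <- substr(seq, gpos + 1L, gpos + 1L)
    alt <- if (cfg$alt_mode == "worst" && mp %in% half_positions &&
               cfg$snp_placement == "half_site") {
      col <- if (mp <= 9L) mp else mp - m$spacer - 9L + 9L
      worst <- DNA_BASES[which.min(weights[DNA_BASES, col])]
      strand_alt <- if (m$strand == "+") worst else unname(COMPLEMENT[worst])
      if (strand_alt == ref) sample(setdiff(DNA_BASES, ref), 1L)
      else strand_alt
    } else sample(setdiff(DNA_BASES, ref), 1L)
    rows[[k]] <- data.frame(
      chrom = m$chrom, pos = gpos, id = sprintf("snp_%02d", k),
      ref = ref, alt = alt,
      maf = round(runif(1, cfg$maf_range[1], cfg$maf_range[2]), 4),
      motif_name = m$name, motif_position = mp,
      half_site = if (cfg$snp_placement != "half_site") NA_character_
        else if (mp <= 9L) "left" else "right",
      genotype = cfg$genotype,
      true_allele_ratio = cfg$true_allele_ratio,
      stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, rows)
  sim$snps <- snps[, c("chrom", "pos", "id", "ref", "alt", "maf")]
  sim$truth$snps <- snps
  sim
}

#' Simulate SNP-overlapping ChIP-seq reads
#'
#' For each injected SNP, `depth` reads of `read_length` are drawn with
#' start offsets uniform over the windows covering the SNP; at
#' heterozygous sites each read's allele is Bernoulli(`true_allele_ratio`)
#' for the major (reference) variant.  Strands are random and qualities
#' are constant Phred 40 (qualities are never used downstream).
#'
#' @param sim output of [inject_snps()].
#' @param cfg a `SimulationConfig`.
#' @return `sim` with `reads`: data.frame `id`, `seq`, `snp_id`,
#'   `allele` ("major"/"minor").
#' @export
simulate_reads <- function(sim, cfg) {
  if (is.null(sim$truth$snps)) stop("inject SNPs before simulating reads")
  set.seed(stage_seed(cfg, "reads"))
  if (cfg$depth == 0L) {
    warning("depth is 0; no reads simulated")
    sim$reads <- data.frame(id = character(), seq = character(),
                            snp_id = character(), allele = character(),
                            stringsAsFactors = FALSE)
    return(sim)
  }
  seq <- sim$genome[[1]]
  n <- nchar(seq)
  L <- cfg$read_length
  out <- vector("list", nrow(sim$truth$snps))
  for (i in seq_len(nrow(sim$truth$snps))) {
    s <- sim$truth$snps[i, ]
    starts_ok <- max(0L, s$pos - L + 1L):min(s$pos, n - L)
    starts <- sample(starts_ok, cfg$depth, replace = TRUE)
    allele <- switch(s$genotype,
      hom_ref = rep("major", cfg$depth),
      hom_alt = rep("minor", cfg$depth),
      het = ifelse(runif(cfg$depth) < s$true_allele_ratio,
                   "major", "minor"))
    win <- substring(seq, starts + 1L, starts + L)
    is_minor <- allele == "minor"
    if (any(is_minor)) {
      at <- s$pos - starts[is_minor] + 1L
      wm <- win[is_minor]
      for (k in seq_along(wm)) substr(wm[k], at[k], at[k]) <- s$alt
      win[is_minor] <- wm
    }
    flip <- runif(cfg$depth) < 0.5
    win[flip] <- revcomp(win[flip])
    out[[i]] <- data.frame(
      id = sprintf("%s_read_%04d", s$id, seq_len(cfg$depth)),
      seq = win, snp_id = s$id, allele = allele, stringsAsFactors = FALSE)
  }
  sim$reads <- do.call(rbind, out)
  sim
}

# Monotone decreasing map from normalized motif score to true Fraction
# Bound: consensus-quality motifs compete strongly (FB ~ 0.05) and each
# loss of motif quality raises FB steeply (gain 4), clamped to [0.02, 0.98].
fb_from_score <- function(score) {
  pmin(0.98, pmax(0.02, 0.05 + 4 * (1 - score)))
}

#' Simulate EMSA replicate lanes
#'
#' Per-allele true Fraction Bound means are a monotone decreasing
#' function of the allele's normalized motif score (see `fb_from_score`);
#' replicate lanes add Gaussian noise (sd `emsa_noise_sd`), clamp to
#' \[0, 1\] and are converted to bound/unbound intensities at a fixed lane
#' total of 1000 units.  Ideal and Mutated control competitor lanes are
#' included.
#'
#' @param sim output of [inject_snps()] (motif scores and SNP deltas are
#'   taken from the truth table).
#' @param half the `HalfSitePWM` (to score minor-allele windows).
#' @param cfg a `SimulationConfig`.
#' @return `sim` with `lanes` (raw gel-quantification layout) and
#'   `truth$emsa` (true FB means and deltas per pRE1).
#' @export
simulate_emsa <- function(sim, half, cfg) {
  if (is.null(sim$truth$snps)) stop("inject SNPs before simulating EMSA")
  set.seed(stage_seed(cfg, "emsa"))
  total <- 1000
  mk_lanes <- function(label, allele, fb_mean) {
    fb <- pmin(1, pmax(0, fb_mean + rnorm(cfg$replicates, 0,
                                          cfg$emsa_noise_sd)))
    data.frame(competitor_label = label, allele = allele,
               replicate = seq_len(cfg$replicates),
               bound = fb * total, unbound = (1 - fb) * total,
               stringsAsFactors = FALSE)
  }
  truth_rows <- vector("list", nrow(sim$truth$snps))
  lanes <- list(mk_lanes("Ideal", "control", 0.05),
                mk_lanes("Mutated", "control", 0.90))
  for (i in seq_len(nrow(sim$truth$snps))) {
    s <- sim$truth$snps[i, ]
    m <- sim$truth$motifs[sim$truth$motifs$name == s$motif_name, ]
    pwm <- re1_pwm(half, m$spacer)
    major_win <- m$window
    mp <- s$motif_position
    if (mp > nchar(major_win)) next   # flank SNP: no motif window change
    minor_win <- major_win
    strand_alt <- if (m$strand == "+") s$alt else unname(COMPLEMENT[s$alt])
    substr(minor_win, mp, mp) <- strand_alt
    score_major <- score_window(pwm, major_win)$normalized
    score_minor <- score_window(pwm, minor_win)$normalized
    fb_major <- fb_from_score(score_major)
    fb_minor <- fb_from_score(score_minor)
    lanes[[length(lanes) + 1L]] <- mk_lanes(s$id, "major", fb_major)
    lanes[[length(lanes) + 1L]] <- mk_lanes(s$id, "minor", fb_minor)
    truth_rows[[i]] <- data.frame(
      snp_id = s$id, score_major = score_major, score_minor = score_minor,
      fb_major_true = fb_major, fb_minor_true = fb_minor,
      delta_fb_true = fb_minor - fb_major, stringsAsFactors = FALSE)
  }
  sim$lanes <- do.call(rbind, lanes)
  emsa <- do.call(rbind, truth_rows)
  if (is.null(emsa))
    emsa <- data.frame(snp_id = character(), score_major = numeric(),
                       score_minor = numeric(), fb_major_true = numeric(),
                       fb_minor_true = numeric(), delta_fb_true = numeric(),
                       stringsAsFactors = FALSE)
  sim$truth$emsa <- emsa
  sim
}

#' Simulate EMSA lanes for one competitor pair with known truth
#'
#' Standalone lane generator for calibration experiments: replicate
#' Fraction Bound values are Gaussian around the given per-allele true
#' means, clamped to \[0, 1\] and converted to bound/unbound intensities
#' at a fixed lane total of 1000 units.
#'
#' @param fb_major_true,fb_minor_true true Fraction Bound means.
#' @param noise_sd Gaussian noise sd in FB units.
#' @param replicates lanes per allele (default 3).
#' @param label competitor label.
#' @return Lane data.frame (raw gel-quantification layout).
#' @export
simulate_emsa_lanes <- function(fb_major_true, fb_minor_true,
                                noise_sd = 0.02, replicates = 3L,
                                label = "competitor") {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  total <- 1000
  one <- function(allele, mu) {
    fb <- pmin(1, pmax(0, mu + rnorm(replicates, 0, noise_sd)))
    data.frame(competitor_label = label, allele = allele,
               replicate = seq_len(replicates), bound = fb * total,
               unbound = (1 - fb) * total, stringsAsFactors = FALSE)
  }
  rbind(one("major", fb_major_true), one("minor", fb_minor_true))
}

#' Simulate reporter-assay readings
#'
#' Relative activity is a monotone increasing function of true Fraction
#' Bound (strong REST binders repress the reporter), with Gaussian noise.
#'
#' @param sim output of [simulate_emsa()].
#' @param cfg a `SimulationConfig`.
#' @return `sim` with `reporter`: data.frame `construct`, `allele`,
#'   `replicate`, `activity` (relative to the empty backbone).
#' @export
simulate_reporter <- function(sim, cfg) {
  if (is.null(sim$truth$emsa)) stop("simulate EMSA before reporter data")
  set.seed(stage_seed(cfg, "reporter"))
  act <- function(fb) 0.3 + 0.7 * fb
  if (!nrow(sim$truth$emsa)) {
    sim$reporter <- data.frame(construct = character(), allele = character(),
                               replicate = integer(), activity = numeric(),
                               stringsAsFactors = FALSE)
    return(sim)
  }
  rows <- lapply(seq_len(nrow(sim$truth$emsa)), function(i) {
    e <- sim$truth$emsa[i, ]
    rbind(
      data.frame(construct = e$snp_id, allele = "major",
                 replicate = seq_len(cfg$replicates),
                 activity = pmax(0.01, act(e$fb_major_true) +
                   rnorm(cfg$replicates, 0, cfg$reporter_noise_sd))),
      data.frame(construct = e$snp_id, allele = "minor",
                 replicate = seq_len(cfg$replicates),
                 activity = pmax(0.01, act(e$fb_minor_true) +
                   rnorm(cfg$replicates, 0, cfg$reporter_noise_sd))))
  })
  sim$reporter <- do.call(rbind, rows)
  sim
}

#' Generate the full synthetic bundle
#'
#' Runs all generator stages and optionally writes the bundle to disk
#' (genome.fa, peaks.bed, snps.vcf, reads.fastq, emsa_lanes.tsv,
#' reporter.tsv, truth.json), byte-identical for a given seed.
#'
#' @param cfg a `SimulationConfig`.
#' @param half a `HalfSitePWM` (default [default_re1_pwm()]).
#' @param dir optional output directory.
#' @return The simulation list: `genome`, `peaks`, `snps`, `reads`,
#'   `lanes`, `reporter`, `truth`.
#' @export
simulate_bundle <- function(cfg = sim_config(), half = default_re1_pwm(),
                            dir = NULL) {
  sim <- simulate_genome(cfg)
  sim <- implant_motifs(sim, half, cfg)
  sim <- inject_snps(sim, half, cfg)
  sim <- simulate_reads(sim, cfg)
  sim <- simulate_emsa(sim, half, cfg)
  sim <- simulate_reporter(sim, cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_genome(sim$genome, file.path(dir, "genome.fa"))
    write_peaks(sim$peaks, file.path(dir, "peaks.bed"))
    write_snps(sim$snps, file.path(dir, "snps.vcf"))
    write_reads(setNames(sim$reads$seq, sim$reads$id),
                file.path(dir, "reads.fastq"))
    write_tsv(sim$lanes, file.path(dir, "emsa_lanes.tsv"))
    write_tsv(sim$reporter, file.path(dir, "reporter.tsv"))
    jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  sim
}
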