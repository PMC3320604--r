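## Peak standardization and RE1 scanning.
##
## Binding regions from ChIP-seq are heterogeneous in size, so each region
## is standardized to a fixed 100-bp window centred on the peak summit
## before motif search.  Within each window, every offset x strand x spacer
## variant is scored and the single highest-scoring RE1 is taken to account
## for REST binding, provided it reaches the stringency threshold
## (normalized score >= 0.88 by default).

#' Standardize a binding region to a fixed width around its summit
#'
#' The returned interval always has length `width` (centred on the summit,
#' shifted -- not truncated -- when it would overhang a contig edge), unless
#' the contig itself is shorter than `width`, in which case the whole contig
#' is returned and the region is flagged.
#'
#' @param region one-row data.frame (or list) with `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `summit` (0-based; interval
#'   midpoint when absent) and `name`.
#' @param width target width in bp (default 100).
#' @param contig_length length of the contig the region lies on.
#' @return One-row data.frame: `chrom`, `start`, `end`, `summit`, `name`,
#'   `flagged` (TRUE when the contig was shorter than `width`).
#' @export
standardize_peak <- function(region, width = 100L, contig_length) {
  width <- as.integer(width)
  if (width <= 0L) stop("width must be positive")
  start <- as.integer(region$start); end <- as.integer(region$end)
  if (start >= end) stop("invalid region: start >= end")
  summit <- if (!is.null(region$summit) && !is.na(region$summit))
    as.integer(region$summit) else start + (end - start) %/% 2L
  if (summit < 0L || summit >= contig_length)
    stop("summit lies outside the contig")
  name <- if (!is.null(region$name)) as.character(region$name) else NA_character_

  if (contig_length < width) {
    return(data.frame(chrom = region$chrom, start = 0L,
                      end = as.integer(contig_length), summit = summit,
                      name = name, flagged = TRUE,
                      stringsAsFactors = FALSE))
  }
  s <- summit - width %/% 2L
  s <- max(0L, min(s, as.integer(contig_length) - width))
  data.frame(chrom = region$chrom, start = s, end = s + width,
             summit = summit, name = name, flagged = FALSE,
             stringsAsFactors = FALSE)
}

#' Standardize a whole peak table
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end` and
#'   optionally `summit`, `name`.
#' @param width target width in bp.
#' @param contig_lengths named vector of contig lengths.
#' @return data.frame of standardized peaks (one row per input peak).
#' @export
standardize_peaks <- function(peaks, width = 100L, contig_lengths) {
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    cl <- contig_lengths[[as.character(peaks$chrom[i])]]
    if (is.null(cl) || is.na(cl))
      stop("no contig length for ", peaks$chrom[i])
    standardize_peak(peaks[i, , drop = FALSE], width = width,
                     contig_length = cl)
  })
  do.call(rbind, out)
}

#' Merge several peak sets into one
#'
#' Takes the interval union across sets; overlapping intervals are merged
#' and the merged summit is the midpoint of the merged interval.  Used to
#' combine binding regions from multiple cell lines.
#'
#' @param peak_sets list of peak data.frames (`chrom`, `start`, `end`, ...).
#'   Each set may carry an `assembly` attribute; mixing declared assemblies
#'   is an error.
#' @return A single merged peak data.frame with `chrom`, `start`, `end`,
#'   `summit`, `name`.
#' @export
merge_peak_sets <- function(peak_sets) {
  if (!length(peak_sets)) stop("no peak sets supplied")
  assemblies <- unique(unlist(lapply(peak_sets, attr, "assembly")))
  if (length(assemblies) > 1L)
    stop("peak sets declare different assemblies: ",
         paste(assemblies, collapse = ", "))
  all <- do.call(rbind, lapply(peak_sets, function(p)
    p[, c("chrom", "start", "end")]))
  gr <- GenomicRanges::GRanges(all$chrom,
                               IRanges::IRanges(all$start + 1L, all$end))
  merged <- GenomicRanges::reduce(gr)
  start <- GenomicRanges::start(merged) - 1L
  end <- GenomicRanges::end(merged)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                    start = start, end = end,
                    summit = start + (end - start) %/% 2L,
                    name = sprintf("merged_%d", seq_along(merged)),
                    stringsAsFactors = FALSE)
  if (length(assemblies)) attr(out, "assembly") <- assemblies
  out
}

#' Scan a sequence for the best RE1 motif across spacer variants
#'
#' Evaluates every offset on both strands for every spacer variant and
#' returns the single best hit if its normalized score reaches `threshold`.
#' Ties are broken deterministically: higher score, then smaller spacer,
#' then + strand, then leftmost offset.
#'
#' @param seq nucleotide string (the standardized peak sequence).
#' @param pwms list of `RE1PWM` spacer variants (see
#'   [build_spacer_variants()]).
#' @param threshold minimum normalized score for a hit (default 0.88, the
#'   medium-stringency cut at which RE1s are rare in random DNA).
#' @return `NULL` if no window reaches `threshold`; otherwise a one-row
#'   data.frame: `start`, `end` (0-based half-open, relative to `seq`),
#'   `strand`, `spacer`, `score` (normalized), `raw`, `canonical`
#'   (spacer == 2).
#' @export
scan_region <- function(seq, pwms, threshold = 0.88) {
  if (!nchar(seq)) stop("empty sequence")
  n <- nchar(seq)
  codes_f <- encode_dna(seq)
  codes_r <- rev(5L - codes_f)          # reverse complement in code space
  codes_r[codes_r == 0L] <- 5L          # N (code 5) maps to N, not 0
  best <- NULL
  for (pwm in pwms) {
    L <- pwm$total_length
    if (n < L) next
    denom <- pwm$max_raw - pwm$min_raw
    for (str in c("+", "-")) {
      raw <- score_offsets(pwm, if (str == "+") codes_f else codes_r)
      norm <- (raw - pwm$min_raw) / denom
      i <- which.max(norm)
      if (!length(i)) next
      # resolve within-variant ties (scores within 1e-12 are tied): on
      # "-" the leftmost genomic start is the rightmost scanned offset,
      # so pick the leftmost *genomic* start among ties
      ties <- which(norm > norm[i] - 1e-12)
      if (str == "+") {
        off <- min(ties)
        g_start <- off - 1L
      } else {
        off <- max(ties)                # rightmost on revcomp = leftmost genomic
        g_start <- n - (off + L - 1L)
      }
      cand <- list(start = g_start, end = g_start + L, strand = str,
                   spacer = pwm$spacer_length, score = norm[off],
                   raw = raw[off])
      if (is.null(best) || better_hit(cand, best)) best <- cand
    }
  }
  if (is.null(best) || best$score < threshold) return(NULL)
  data.frame(start = best$start, end = best$end, strand = best$strand,
             spacer = best$spacer, score = best$score, raw = best$raw,
             canonical = best$spacer == 2L, stringsAsFactors = FALSE)
}

# Tie rule: higher score, then smaller spacer, then '+' strand, then
# leftmost start.  Scores equal within 1e-12 are treated as tied.
better_hit <- function(a, b) {
  if (abs(a$score - b$score) > 1e-12) return(a$score > b$score)
  if (a$spacer != b$spacer) return(a$spacer < b$spacer)
  if (a$strand != b$strand) return(a$strand == "+")
  a$start < b$start
}

#' Scan standardized peaks against a genome
#'
#' @param genome named character vector (or `DNAStringSet`) of contig
#'   sequences.
#' @param peaks standardized peak data.frame (`chrom`, `start`, `end`,
#'   `name`).
#' @param pwms list of `RE1PWM` variants.
#' @param threshold normalized-score threshold (default 0.88).
#' @return data.frame of motif hits in genomic coordinates: `region_name`,
#'   `chrom`, `start`, `end`, `strand`, `spacer`, `score`, `canonical`.
#'   Peaks without a hit above threshold are dropped.
#' @export
scan_peaks <- function(genome, peaks, pwms, threshold = 0.88) {
  genome <- as_genome(genome)
  hits <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    chrom <- as.character(peaks$chrom[i])
    seq <- substr(genome[[chrom]], peaks$start[i] + 1L, peaks$end[i])
    h <- scan_region(seq, pwms, threshold = threshold)
    if (is.null(h)) next
    h$start <- h$start + peaks$start[i]
    h$end <- h$end + peaks$start[i]
    h$chrom <- chrom
    h$region_name <- if (!is.null(peaks$name)) as.character(peaks$name[i])
      else sprintf("region_%d", i)
    hits[[i]] <- h[, c("region_name", "chrom", "start", "end", "strand",
                       "spacer", "score", "raw", "canonical")]
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(region_name = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), spacer = integer(),
                      score = numeric(), raw = numeric(),
                      canonical = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Half-site genomic intervals of a motif hit
#'
#' The left half site occupies motif positions 1-9 and the right half site
#' positions (10+spacer)-(15+spacer) (1-based motif coordinates; 12-17 for
#' the canonical 2-bp spacer).  On the minus strand the "left" half site
#' maps to the downstream genomic interval.
#'
#' @param hit one-row motif-hit data.frame (`start`, `end`, `strand`,
#'   `spacer`).
#' @return List with `left` and `right`, each `c(start, end)` 0-based
#'   half-open genomic intervals.
#' @export
half_site_intervals <- function(hit) {
  s <- as.integer(hit$start); e <- as.integer(hit$end)
  if (hit$strand == "+") {
    list(left = c(s, s + 9L),
         right = c(s + 9L + as.integer(hit$spacer), e))
  } else {
    list(left = c(e - 9L, e),
         right = c(s, s + 6L))
  }
}

# Genomic position (0-based) -> 1-based motif position for a hit.
motif_position_of <- function(hit, pos) {
  if (hit$strand == "+") pos - as.integer(hit$start) + 1L
  else as.integer(hit$end) - pos
}

# Coerce genome input to a named list of plain character sequences.
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.list(as.character(genome))
  } else if (is.character(genome)) {
    out <- as.list(genome)
  } else if (is.list(genome)) {
    out <- genome
  } else stop("unsupported genome representation")
  if (is.null(names(out)) || any(!nzchar(names(out))))
    stop("genome contigs must be named")
  lapply(out, toupper)
}
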