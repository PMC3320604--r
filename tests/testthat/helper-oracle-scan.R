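# Brute-force scan oracle used by the acceptance checks: enumerates every
# (genomic offset, strand, spacer) candidate and scores each window with
# an explicit per-position summation over precomputed log-odds weights.
# Independent of scan_region's vectorized scanning and of score_offsets.
oracle_scan_fast <- function(seq, half, spacers = 0:12, threshold = 0.88,
                             background = rep(0.25, 4)) {
  freqs <- cbind(half$left, half$right)
  w <- log2(sweep(freqs, 1, background, "/"))
  w <- rbind(w, apply(w, 2, min))          # row 5: N = column minimum
  min_raw <- sum(apply(w[1:4, ], 2, min))
  max_raw <- sum(apply(w[1:4, ], 2, max))
  bases <- c("A", "C", "G", "T", "N")
  n <- nchar(seq)
  ch <- strsplit(toupper(seq), "")[[1]]
  codes <- match(ch, bases); codes[is.na(codes)] <- 5L
  comp <- c(4L, 3L, 2L, 1L, 5L)
  rc_codes <- rev(comp[codes])
  best <- NULL
  better <- function(a, b) {
    if (abs(a$score - b$score) > 1e-12) return(a$score > b$score)
    if (a$spacer != b$spacer) return(a$spacer < b$spacer)
    if (a$strand != b$strand) return(a$strand == "+")
    a$start < b$start
  }
  for (sp in spacers) {
    L <- 15L + sp
    if (L > n) next
    cols <- c(1:9, (9L + sp + 1L):(9L + sp + 6L))
    for (g in 0:(n - L)) {
      for (strand in c("+", "-")) {
        win_codes <- if (strand == "+") codes[(g + 1):(g + L)]
          else rc_codes[(n - g - L + 1):(n - g)]
        raw <- 0
        for (j in 1:15) raw <- raw + w[win_codes[cols[j]], j]
        cand <- list(start = g, end = g + L, strand = strand, spacer = sp,
                     score = (raw - min_raw) / (max_raw - min_raw))
        if (is.null(best) || better(cand, best)) best <- cand
      }
    }
  }
  if (is.null(best) || best$score < threshold) return(NULL)
  best
}
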