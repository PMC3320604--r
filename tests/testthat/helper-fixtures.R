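# Shared fixtures and independent oracles used across the suite.

set.seed(20260921)  # helpers only; each test seeds its own draws

# A toy half-site matrix with distinct per-column counts so every column
# has a unique argmax/argmin and hand computation is easy.
toy_half_pwm <- function(pseudocount = 0.01) {
  perm <- rbind(c(8, 4, 2, 1), c(1, 8, 4, 2), c(2, 1, 8, 4), c(4, 2, 1, 8))
  left <- sapply(1:9, function(j) perm[(j - 1) %% 4 + 1, ])
  right <- sapply(1:6, function(j) perm[j %% 4 + 1, ])
  rownames(left) <- rownames(right) <- c("A", "C", "G", "T")
  half_site_pwm(left, right, pseudocount = pseudocount)
}

# Consensus string (argmax base per column) for a HalfSitePWM + spacer,
# derived independently from the frequency matrices.
consensus_window <- function(half, spacer, spacer_base = "A") {
  freqs <- cbind(half$left, half$right)
  bases <- rownames(freqs)[apply(freqs, 2, which.max)]
  paste(c(bases[1:9], rep(spacer_base, spacer), bases[10:15]),
        collapse = "")
}

anticonsensus_window <- function(half, spacer, spacer_base = "A") {
  freqs <- cbind(half$left, half$right)
  bases <- rownames(freqs)[apply(freqs, 2, which.min)]
  paste(c(bases[1:9], rep(spacer_base, spacer), bases[10:15]),
        collapse = "")
}

rc <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(s, function(x)
    paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Independent per-window, per-position summation score (the oracle for
# score_window / scan_region).  Recomputes log-odds weights from the
# frequency matrices directly.
oracle_score <- function(half, spacer, window, background = rep(0.25, 4)) {
  freqs <- cbind(half$left, half$right)
  w <- log2(sweep(freqs, 1, background, "/"))
  chars <- strsplit(toupper(window), "")[[1]]
  cols <- c(1:9, (9 + spacer + 1):(9 + spacer + 6))
  raw <- 0
  for (j in seq_along(cols)) {
    b <- chars[cols[j]]
    raw <- raw + if (b %in% rownames(w)) w[b, j] else min(w[, j])
  }
  unname((raw - sum(apply(w, 2, min))) /
           (sum(apply(w, 2, max)) - sum(apply(w, 2, min))))
}

# Exhaustive brute-force scan: every genomic start x strand x spacer,
# scored per window with oracle_score; same deterministic tie rule
# (score desc, spacer asc, + strand, leftmost genomic start).
oracle_scan <- function(seq, half, spacers = 0:12, threshold = 0.88) {
  n <- nchar(seq)
  best <- NULL
  better <- function(a, b) {
    if (abs(a$score - b$score) > 1e-12) return(a$score > b$score)
    if (a$spacer != b$spacer) return(a$spacer < b$spacer)
    if (a$strand != b$strand) return(a$strand == "+")
    a$start < b$start
  }
  for (g in 0:(n - 1)) {
    for (sp in spacers) {
      L <- 15 + sp
      if (g + L > n) next
      win_plus <- substr(seq, g + 1, g + L)
      for (strand in c("+", "-")) {
        win <- if (strand == "+") win_plus else rc(win_plus)
        cand <- list(start = g, end = g + L, strand = strand, spacer = sp,
                     score = oracle_score(half, sp, win))
        if (is.null(best) || better(cand, best)) best <- cand
      }
    }
  }
  if (is.null(best) || best$score < threshold) return(NULL)
  best
}

# Exact two-sided binomial p under p0 = 0.5, by direct pmf tail summation
# over the symmetric minimum-likelihood region (independent of
# stats::binom.test).
oracle_binom_p <- function(k, n) {
  lo <- min(k, n - k); hi <- max(k, n - k)
  if (lo == hi) return(1)
  d <- dbinom(0:n, n, 0.5)
  min(1, sum(d[0:n <= lo]) + sum(d[0:n >= hi]))
}

# Small random genome with one SNP in the middle, for k-mer tests.
allelic_fixture <- function(seed = 77, len = 400, pos = 200) {
  set.seed(seed)
  g <- list(chrT = random_dna(len))
  ref <- substr(g$chrT, pos + 1, pos + 1)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  snp <- data.frame(chrom = "chrT", pos = pos, id = "rsF", ref = ref,
                    alt = alt, stringsAsFactors = FALSE)
  list(genome = g, snp = snp)
}

# Tiny deterministic genome with a consensus canonical RE1 implanted.
fixture_genome <- function(half = default_re1_pwm(), at = 200,
                           strand = "+", spacer = 2, len = 600,
                           seed = 42) {
  set.seed(seed)
  g <- random_dna(len)
  win <- consensus_window(half, spacer)
  ins <- if (strand == "+") win else rc(win)
  substr(g, at + 1, at + nchar(ins)) <- ins
  list(genome = list(chrT = g), start = at, end = at + nchar(ins),
       strand = strand, spacer = spacer, window = win)
}
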