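DNA_BASES <- c("A", "C", "G", "T")

## The RE1 motif is modelled as two strongly constrained half sites -- a 9-bp
## left half and a 6-bp right half -- separated by an unconstrained spacer of
## 0-12 bp (2 bp in the canonical configuration).  Scores are log2-odds
## against a background composition, min-max normalized to [0,1] so that a
## single stringency threshold applies across spacer variants.

#' Construct a half-site PWM for the RE1 motif
#'
#' Builds the frequency and log-odds representation of the two RE1 half
#' sites from count (or frequency) matrices.  Columns are normalized to sum
#' to one after adding `pseudocount` to every cell; log-odds weights are
#' `log2(freq / background)`.
#'
#' @param left_counts 4 x 9 numeric matrix (rows A,C,G,T) of counts or
#'   frequencies for the left half site.
#' @param right_counts 4 x 6 numeric matrix for the right half site.
#' @param background length-4 strictly positive vector summing to 1
#'   (nucleotide background frequencies); default uniform.
#' @param pseudocount nonnegative scalar added to every cell before column
#'   normalization.  Default 0.01.
#' @return An object of class `HalfSitePWM`: list with `left`, `right`
#'   (frequency matrices), `weights` (4 x 15 log-odds matrix over the 15
#'   informative positions), `background`, `pseudocount`.
#' @export
half_site_pwm <- function(left_counts, right_counts,
                          background = rep(0.25, 4), pseudocount = 0.01) {
  left_counts <- as.matrix(left_counts)
  right_counts <- as.matrix(right_counts)
  if (nrow(left_counts) != 4L || nrow(right_counts) != 4L)
    stop("half-site matrices must have 4 rows (A, C, G, T)")
  if (ncol(left_counts) != 9L)
    stop("left half-site matrix must have exactly 9 columns, got ",
         ncol(left_counts))
  if (ncol(right_counts) != 6L)
    stop("right half-site matrix must have exactly 6 columns, got ",
         ncol(right_counts))
  if (any(left_counts < 0) || any(right_counts < 0))
    stop("half-site matrices must be nonnegative")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  if (length(background) != 4L || any(background <= 0))
    stop("background must be 4 strictly positive frequencies")
  background <- background / sum(background)

  norm_cols <- function(m) {
    m <- m + pseudocount
    cs <- colSums(m)
    if (any(cs == 0)) stop("half-site matrix has an all-zero column and zero pseudocount")
    sweep(m, 2L, cs, "/")
  }
  left <- norm_cols(left_counts)
  right <- norm_cols(right_counts)
  rownames(left) <- rownames(right) <- DNA_BASES
  weights <- log2(cbind(left, right) / background)
  colnames(weights) <- NULL

  structure(list(left = left, right = right, weights = weights,
                 background = background, pseudocount = pseudocount),
            class = "HalfSitePWM")
}

#' Default RE1 half-site matrix
#'
#' A pseudocount-smoothed stand-in matrix built around the canonical
#' NRSE/RE1 consensus half sites (left `TTCAGCACC`, right `GGACAG`), with
#' heterogeneous per-position conservation (strongly constrained core
#' positions at consensus frequency ~0.85, moderately and weakly
#' constrained positions at ~0.6 and ~0.45) mirroring the uneven
#' information profile of the RE1.  It reproduces the qualitative
#' behaviour of a trained RE1 matrix -- high-scoring motifs are
#' vanishingly rare in random DNA at the 0.88 stringency -- but is not a
#' matrix estimated from binding data; supply your own via [load_pwm()]
#' for real-genome work.
#'
#' @param pseudocount,background passed to [half_site_pwm()].
#' @return A `HalfSitePWM`.
#' @export
default_re1_pwm <- function(pseudocount = 0.01, background = rep(0.25, 4)) {
  profiles <- list(hi = c(17, 1, 1, 1),       # ~0.85 consensus
                   med = c(12, 4, 2, 2),      # ~0.60
                   lo = c(9, 5, 3, 3))        # ~0.45
  consensus_counts <- function(consensus, strength) {
    bases <- strsplit(consensus, "")[[1]]
    m <- matrix(NA_real_, nrow = 4, ncol = length(bases),
                dimnames = list(DNA_BASES, NULL))
    for (j in seq_along(bases)) {
      p <- profiles[[strength[j]]]
      others <- setdiff(DNA_BASES, bases[j])
      m[bases[j], j] <- p[1]
      m[others, j] <- p[2:4]
    }
    m
  }
  half_site_pwm(
    consensus_counts("TTCAGCACC",
                     c("med", "hi", "hi", "hi", "hi", "hi", "lo", "hi",
                       "med")),
    consensus_counts("GGACAG", c("hi", "med", "hi", "hi", "med", "hi")),
    background = background, pseudocount = pseudocount)
}

#' Load a half-site PWM from a motif file
#'
#' Two dialects are accepted: (1) a whitespace-delimited 4 x 15 count or
#' frequency matrix (rows A, C, G, T) preceded by a header line declaring
#' the half-site split, e.g. `>RE1 9 6` or `# halfsites 9 6`; (2) a minimal
#' JASPAR-style PFM with rows `A [ ... ]` .. `T [ ... ]` (the 9|6 split is
#' then taken as the first 9 and last 6 of 15 columns).
#'
#' @param path motif file path.
#' @inheritParams half_site_pwm
#' @return A `HalfSitePWM`.
#' @export
load_pwm <- function(path, background = rep(0.25, 4), pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty motif file: ", path)

  jaspar_rows <- grepl("^[ACGT]\\s*\\[", lines)
  if (sum(jaspar_rows) == 4L) {
    rows <- lines[jaspar_rows]
    base_of <- substr(rows, 1, 1)
    vals <- lapply(rows, function(l) {
      body <- sub("^[ACGT]\\s*\\[", "", sub("\\]\\s*$", "", l))
      as.numeric(strsplit(trimws(body), "\\s+")[[1]])
    })
    widths <- lengths(vals)
    if (length(unique(widths)) != 1L || widths[1] != 15L)
      stop("JASPAR-style motif must have 15 columns per row, got ", widths[1])
    m <- do.call(rbind, vals)
    rownames(m) <- base_of
    m <- m[DNA_BASES, , drop = FALSE]
    if (anyNA(m)) stop("malformed JASPAR-style motif counts in ", path)
    if (any(m < 0)) stop("negative counts in motif file ", path)
    return(half_site_pwm(m[, 1:9], m[, 10:15],
                         background = background, pseudocount = pseudocount))
  }

  header <- lines[1]
  split <- as.integer(regmatches(header, gregexpr("[0-9]+", header))[[1]])
  if (length(split) < 2L || split[1] != 9L || split[2] != 6L)
    stop("motif file header must declare the 9|6 half-site split, got: ",
         header)
  body <- lines[-1]
  body <- body[!grepl("^[#>]", body)]
  if (length(body) != 4L)
    stop("motif matrix must have 4 rows (A, C, G, T), got ", length(body))
  m <- do.call(rbind, lapply(body, function(l)
    as.numeric(strsplit(l, "\\s+")[[1]])))
  if (anyNA(m)) stop("non-numeric entries in motif file ", path)
  if (ncol(m) != 15L)
    stop("motif matrix must have 9 + 6 = 15 columns, got ", ncol(m))
  if (any(m < 0)) stop("negative counts in motif file ", path)
  rownames(m) <- DNA_BASES
  half_site_pwm(m[, 1:9], m[, 10:15],
                background = background, pseudocount = pseudocount)
}

#' Build RE1 PWM spacer variants
#'
#' One scoring model per spacer length.  Spacer positions carry zero weight
#' and never contribute to the raw score, so `min_raw`/`max_raw` (and hence
#' the normalization) are identical across variants.
#'
#' @param half a `HalfSitePWM`.
#' @param spacer_min,spacer_max integer spacer-length bounds, within
#'   \[0, 12\].  Defaults cover the full 0-12 range; the canonical RE1 has a
#'   2-bp spacer.
#' @return List of `RE1PWM` objects, one per spacer length.
#' @export
build_spacer_variants <- function(half, spacer_min = 0L, spacer_max = 12L) {
  if (!inherits(half, "HalfSitePWM")) stop("half must be a HalfSitePWM")
  spacer_min <- as.integer(spacer_min); spacer_max <- as.integer(spacer_max)
  if (is.na(spacer_min) || is.na(spacer_max) ||
      spacer_min < 0L || spacer_max > 12L || spacer_min > spacer_max)
    stop("spacer bounds must satisfy 0 <= spacer_min <= spacer_max <= 12")
  lapply(spacer_min:spacer_max, function(sp) re1_pwm(half, sp))
}

#' Single RE1 PWM spacer variant
#'
#' @param half a `HalfSitePWM`.
#' @param spacer_length integer in \[0, 12\].
#' @return An object of class `RE1PWM`: `weights` (4 x 15 log-odds over the
#'   informative positions, plus a 5th "N" row carrying each column's
#'   minimum), `spacer_length`, `total_length` (= 15 + spacer),
#'   `offsets` (1-based window offsets of the 15 informative positions),
#'   `min_raw`, `max_raw`.
#' @export
re1_pwm <- function(half, spacer_length) {
  spacer_length <- as.integer(spacer_length)
  if (is.na(spacer_length) || spacer_length < 0L || spacer_length > 12L)
    stop("spacer_length must be an integer in [0, 12]")
  w <- half$weights
  w5 <- rbind(w, N = apply(w, 2L, min))   # 'N' scores the column minimum
  structure(list(weights = w5,
                 spacer_length = spacer_length,
                 total_length = 15L + spacer_length,
                 offsets = c(1:9, 9L + spacer_length + 1:6),
                 min_raw = sum(apply(w, 2L, min)),
                 max_raw = sum(apply(w, 2L, max)),
                 half = half),
            class = "RE1PWM")
}

# Encode a nucleotide string as integer codes 1..5 (A,C,G,T,N).
# Any non-ACGT character is treated as N.
encode_dna <- function(x) {
  codes <- match(strsplit(toupper(x), "")[[1]], c(DNA_BASES, "N"))
  codes[is.na(codes)] <- 5L
  codes
}

#' Score a single window against an RE1 PWM variant
#'
#' @param pwm an `RE1PWM`.
#' @param window nucleotide string of length `pwm$total_length`
#'   (alphabet A,C,G,T,N; N scores the column minimum).
#' @return List of class `MotifScore` with `raw` (log-odds sum over the 15
#'   informative positions) and `normalized`
#'   (`(raw - min_raw) / (max_raw - min_raw)`, in \[0, 1\]).
#' @export
score_window <- function(pwm, window) {
  if (nchar(window) != pwm$total_length)
    stop("window length ", nchar(window), " != total_length ",
         pwm$total_length)
  codes <- encode_dna(window)
  raw <- sum(pwm$weights[cbind(codes[pwm$offsets], seq_len(15L))])
  structure(list(raw = raw,
                 normalized = (raw - pwm$min_raw) / (pwm$max_raw - pwm$min_raw)),
            class = "MotifScore")
}

# Raw scores for every start offset of `codes` (integer-encoded sequence)
# under one spacer variant; vectorized over offsets.  Returns numeric vector
# of length n - total_length + 1 (or length 0 if the sequence is too short).
score_offsets <- function(pwm, codes) {
  n <- length(codes)
  L <- pwm$total_length
  if (n < L) return(numeric(0))
  starts <- seq_len(n - L + 1L)
  raw <- numeric(length(starts))
  for (j in seq_len(15L)) {
    raw <- raw + pwm$weights[cbind(codes[starts + pwm$offsets[j] - 1L], j)]
  }
  raw
}

#' Allele-specific motif-score delta
#'
#' Change in normalized RE1 motif score caused by substituting the minor
#' allele for the major allele.  Negative values mean the minor allele is a
#' worse motif (predicted weaker REST binding).
#'
#' @param pwm an `RE1PWM`.
#' @param major_window,minor_window motif-length windows differing at
#'   exactly one informative (non-spacer) position.
#' @return `normalized(minor) - normalized(major)`, a signed scalar.
#' @export
score_allele_delta <- function(pwm, major_window, minor_window) {
  if (nchar(major_window) != pwm$total_length ||
      nchar(minor_window) != pwm$total_length)
    stop("windows must have length total_length = ", pwm$total_length)
  a <- encode_dna(major_window); b <- encode_dna(minor_window)
  diff_pos <- which(a != b)
  if (length(diff_pos) == 0L)
    stop("windows are identical; alleles must differ at one position")
  if (length(diff_pos) > 1L)
    stop("windows differ at ", length(diff_pos),
         " positions; exactly one is required")
  if (!(diff_pos %in% pwm$offsets))
    stop("allele difference falls in the spacer; the motif-score delta is ",
         "exactly 0 there and is not computed")
  score_window(pwm, minor_window)$normalized -
    score_window(pwm, major_window)$normalized
}
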