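## Readers and writers for the standard formats the screen consumes:
## genome FASTA, peak BED/narrowPeak, SNP VCF, read FASTQ, and the lane
## TSVs holding gel-band and reporter quantifications.

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return Named list of uppercase contig sequences (plain characters).
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  as_genome(ss)
}

#' Write a genome FASTA
#' @param genome named character vector or list of contig sequences.
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(as_genome(genome)))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read binding regions from BED3/BED6 or ENCODE narrowPeak
#'
#' The narrowPeak summit (10th column, offset from `start`; -1 when absent)
#' is used when present; otherwise the summit defaults to the interval
#' midpoint.
#'
#' @param path BED or narrowPeak file.
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `summit` (0-based genomic position).
#' @export
read_peaks <- function(path) {
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#", quote = "")
  nc <- ncol(tab)
  if (nc < 3L) stop("peak file must have at least 3 columns: ", path)
  out <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]),
                    end = as.integer(tab[[3]]),
                    name = if (nc >= 4L) as.character(tab[[4]])
                           else sprintf("peak_%d", seq_len(nrow(tab))),
                    stringsAsFactors = FALSE)
  if (nc >= 10L) {
    off <- suppressWarnings(as.integer(tab[[10]]))
    out$summit <- ifelse(!is.na(off) & off >= 0L, out$start + off,
                         out$start + (out$end - out$start) %/% 2L)
  } else {
    out$summit <- out$start + (out$end - out$start) %/% 2L
  }
  out
}

#' Write peaks as BED6
#' @param peaks peak data.frame (`chrom`, `start`, `end`, `name`).
#' @param path output file.
#' @export
write_peaks <- function(peaks, path) {
  bed <- data.frame(peaks$chrom, peaks$start, peaks$end,
                    if (!is.null(peaks$name)) peaks$name else ".",
                    0L, ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read biallelic SNVs from a VCF
#'
#' Multi-allelic records are split into one record per ALT allele;
#' non-SNV alleles (indels, symbolic) are dropped with a message.  Minor
#' allele frequency is taken from the INFO `MAF=` (or `AF=`) key when
#' present, `NA` otherwise.
#'
#' @param path VCF (v4.x) file.
#' @return data.frame: `chrom`, `pos` (0-based), `id`, `ref`, `alt`, `maf`.
#' @export
read_snps <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  n_in <- 0L; n_dropped <- 0L
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ref <- toupper(fix$REF[i])
    info <- fix$INFO[i]
    maf <- NA_real_
    m <- regmatches(info, regexpr("(?:^|;)(?:MAF|AF)=([0-9.eE+-]+)", info,
                                  perl = TRUE))
    if (length(m)) maf <- as.numeric(sub("^.*=", "", m))
    keep <- list()
    for (k in seq_along(alts)) {
      alt <- toupper(alts[k])
      n_in <- n_in + 1L
      if (nchar(ref) != 1L || nchar(alt) != 1L ||
          !(ref %in% DNA_BASES) || !(alt %in% DNA_BASES) || alt == ref) {
        n_dropped <- n_dropped + 1L
        next
      }
      id <- fix$ID[i]
      if (length(alts) > 1L) id <- paste0(id, "_alt", k)
      keep[[length(keep) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]) - 1L,
        id = id, ref = ref, alt = alt, maf = maf,
        stringsAsFactors = FALSE)
    }
    if (length(keep)) rows[[i]] <- do.call(rbind, keep)
  }
  if (n_dropped)
    message(n_dropped, " of ", n_in, " VCF alleles were not biallelic SNVs",
            " and were dropped")
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = integer(), id = character(),
                      ref = character(), alt = character(), maf = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a SNP table as a minimal VCF
#' @param snps data.frame with `chrom`, `pos` (0-based), `id`, `ref`,
#'   `alt` and optionally `maf`.
#' @param path output file.
#' @export
write_snps <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snps)) {
    info <- ifelse(is.na(snps$maf), ".", sprintf("MAF=%g", snps$maf))
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                       snps$chrom, snps$pos + 1L, snps$id, snps$ref,
                       snps$alt, info), con)
  }
  invisible(path)
}

#' Read sequencing reads from FASTQ
#'
#' Only the read sequences are used downstream (allele calls are exact
#' string matches, base qualities are ignored).
#'
#' @param path FASTQ file.
#' @return Character vector of read sequences (uppercase), named by read id.
#' @export
read_reads <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
}

#' Write reads as FASTQ with constant qualities
#' @param reads named character vector of read sequences.
#' @param path output file.
#' @export
write_reads <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))
  qual <- vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), con)
  invisible(path)
}

#' Read EMSA lane quantifications
#'
#' One gel lane per row, in the layout of a raw gel-quantification
#' export: `competitor_label`, `allele`
#' (major/minor/control), `replicate`, `bound`, `unbound` (arbitrary
#' fluorescence units).
#'
#' @param path TSV file.
#' @return data.frame of lanes.
#' @export
read_emsa_lanes <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  need <- c("competitor_label", "allele", "replicate", "bound", "unbound")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("lane table is missing columns: ", paste(miss, collapse = ", "))
  if (any(tab$bound < 0 | tab$unbound < 0))
    stop("band intensities must be nonnegative")
  tab
}

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
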