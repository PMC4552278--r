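#' Read a FASTA file of DNA sequences
#'
#' Sequences are upper-cased on load; the IUPAC ambiguity code \code{N} is
#' retained, any other non-\code{ACGTN} character is an error.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] in file order, named by record id
#'   (first whitespace-delimited token of the header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ", conditionMessage(e))
  )
  chars <- toupper(as.character(raw))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad)) {
    stop("non-ACGTN character in FASTA record(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(chars)
  names(seqs) <- sub("\\s.*$", "", names(raw))
  seqs
}

#' Write DNA sequences to FASTA
#'
#' @param seqs A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, format = "fasta")
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' BED3/BED6 input; coordinates are converted from BED's 0-based half-open
#' convention to the 1-based closed [GenomicRanges::GRanges] convention on
#' load. Score and strand columns are retained when present.
#'
#' @param path Path to a BED file.
#' @return A [GenomicRanges::GRanges].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("malformed BED in ", path, ": ", conditionMessage(e))
  )
  gr
}

#' Write genomic intervals to BED
#' @param gr A [GenomicRanges::GRanges].
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' The track is the package's signal-carrier dialect (in place of bigwig, so
#' that all inputs stay plain text). Intervals within one chromosome must be
#' non-overlapping.
#'
#' @param path Path to a bedGraph file.
#' @return A [GenomicRanges::GRanges] with a numeric \code{score} column.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "bedGraph"),
    error = function(e) stop("malformed bedGraph in ", path, ": ", conditionMessage(e))
  )
  if (any(GenomicRanges::countOverlaps(gr, gr) > 1L)) {
    stop("bedGraph track has overlapping intervals: ", path)
  }
  gr
}

#' Write a signal track as bedGraph
#' @param gr A [GenomicRanges::GRanges] with a \code{score} column.
#' @param path Output path.
#' @export
write_bedgraph <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a per-CpG methylation table
#'
#' Four tab-separated columns without header: chromosome, 0-based position of
#' the cytosine of a CpG, methylation level in \[0, 1\], read coverage.
#'
#' @param path Path to the table.
#' @return A data.frame with columns \code{chrom}, \code{pos}, \code{level},
#'   \code{coverage}; \code{pos} is converted to 1-based.
#' @export
read_methylation <- function(path) {
  if (!file.exists(path)) stop("methylation file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, col.names = c("chrom", "pos", "level", "coverage"),
                          colClasses = c("character", "integer", "numeric", "integer"))
  if (nrow(df)) {
    if (any(df$level < 0 | df$level > 1)) stop("methylation level outside [0,1] in ", path)
    if (any(df$coverage < 0)) stop("negative coverage in ", path)
    df$pos <- df$pos + 1L
  }
  df
}

#' Write a per-CpG methylation table
#' @param df data.frame as returned by [read_methylation()] (1-based \code{pos}).
#' @param path Output path.
#' @export
write_methylation <- function(df, path) {
  out <- data.frame(df$chrom, df$pos - 1L, df$level, df$coverage)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS-distal loop table
#'
#' Seven tab-separated columns without header: TSS-fragment chrom/start/end,
#' distal-fragment chrom/start/end (BED-style 0-based half-open), and a 0/1
#' loop indicator. Each (TSS, distal) pair must be unique.
#'
#' @param path Path to the table.
#' @return A data.frame with \code{tss} and \code{distal} id columns
#'   ("chrom:start-end", 0-based), the component coordinates, and logical
#'   \code{looped}.
#' @export
read_loops <- function(path) {
  if (!file.exists(path)) stop("loop file not found: ", path)
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("tss_chrom", "tss_start", "tss_end",
                                        "distal_chrom", "distal_start", "distal_end", "looped"))
  if (nrow(df)) {
    if (!all(df$looped %in% c(0L, 1L))) stop("loop indicator must be 0/1 in ", path)
    df$tss <- sprintf("%s:%d-%d", df$tss_chrom, df$tss_start, df$tss_end)
    df$distal <- sprintf("%s:%d-%d", df$distal_chrom, df$distal_start, df$distal_end)
    if (anyDuplicated(paste(df$tss, df$distal))) stop("duplicate (tss, distal) pair in ", path)
    df$looped <- df$looped == 1L
  } else {
    df$tss <- character(0); df$distal <- character(0); df$looped <- logical(0)
  }
  df
}

#' Write a TSS-distal loop table
#' @param df data.frame as returned by [read_loops()].
#' @param path Output path.
#' @export
write_loops <- function(df, path) {
  out <- data.frame(df$tss_chrom, df$tss_start, df$tss_end,
                    df$distal_chrom, df$distal_start, df$distal_end,
                    as.integer(df$looped))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract fixed-width windows around interval midpoints
#'
#' Each interval is reduced to its floor midpoint m (0-based arithmetic:
#' \code{floor((start0 + end0) / 2)}) and expanded to the window
#' \code{[m - flank, m + flank)} of length exactly \code{2 * flank}. Sites
#' whose window would run off the chromosome are dropped with a warning so
#' downstream signal matrices stay rectangular.
#'
#' @param centers A [GenomicRanges::GRanges] of sites.
#' @param flank Half-window size in bp (> 0).
#' @param chrom_sizes Named vector of chromosome lengths in bp.
#' @return A [GenomicRanges::GRanges] of accepted windows (names preserved);
#'   attribute \code{n_dropped} counts rejected sites.
#' @export
extract_flank <- function(centers, flank, chrom_sizes) {
  stopifnot(flank > 0)
  m0 <- floor((GenomicRanges::start(centers) - 1L + GenomicRanges::end(centers)) / 2)
  chrom <- as.character(GenomicRanges::seqnames(centers))
  size <- unname(chrom_sizes[chrom])
  if (any(is.na(size))) stop("chromosome(s) missing from chrom_sizes: ",
                             paste(unique(chrom[is.na(size)]), collapse = ", "))
  ok <- (m0 - flank >= 0) & (m0 + flank <= size)
  if (any(!ok)) warning(sum(!ok), " site(s) dropped: window exceeds chromosome bounds")
  out <- GenomicRanges::GRanges(
    seqnames = chrom[ok],
    ranges = IRanges::IRanges(start = m0[ok] - flank + 1L, end = m0[ok] + flank),
    strand = GenomicRanges::strand(centers)[ok]
  )
  names(out) <- names(centers)[ok]
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Pairwise interval overlap (at least one shared nucleotide)
#'
#' Vectorised over pairs: element i reports whether \code{a[i]} and
#' \code{b[i]} share at least one base. Strand is ignored.
#'
#' @param a,b [GenomicRanges::GRanges] of equal length.
#' @return Logical vector.
#' @export
intervals_overlap <- function(a, b) {
  stopifnot(length(a) == length(b))
  same <- as.character(GenomicRanges::seqnames(a)) == as.character(GenomicRanges::seqnames(b))
  same &
    pmax(GenomicRanges::start(a), GenomicRanges::start(b)) <=
    pmin(GenomicRanges::end(a), GenomicRanges::end(b))
}
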