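#' CpG coverage per position around motif sites
#'
#' For every motif occurrence, positions are taken relative to the site's
#' floor midpoint and oriented by the motif strand (so position +r means r bp
#' downstream on the motif strand). Coverage at relative position r is the
#' percentage of sites that have a CpG record mapping there.
#'
#' @param sites Stranded [GenomicRanges::GRanges] of motif occurrences.
#' @param meth Methylation table ([read_methylation()] format, 1-based
#'   \code{pos}).
#' @param flank Half-window (default 50 bp; positions span -flank..+flank).
#' @return Named numeric vector of length \code{2*flank + 1}: percent
#'   coverage per relative position.
#' @export
cpg_position_coverage <- function(sites, meth, flank = 50) {
  if (length(sites) == 0L) stop("empty site set")
  rel_levels <- seq(-flank, flank)
  cov <- stats::setNames(numeric(length(rel_levels)), rel_levels)
  center <- floor((GenomicRanges::start(sites) - 1L + GenomicRanges::end(sites)) / 2) # 0-based
  chrom <- as.character(GenomicRanges::seqnames(sites))
  minus <- as.character(GenomicRanges::strand(sites)) == "-"
  pos0 <- meth$pos - 1L
  for (i in seq_along(sites)) {
    sel <- meth$chrom == chrom[i] & abs(pos0 - center[i]) <= flank
    if (!any(sel)) next
    rel <- pos0[sel] - center[i]
    if (minus[i]) rel <- -rel
    hit <- unique(rel)
    cov[as.character(hit)] <- cov[as.character(hit)] + 1
  }
  100 * cov / length(sites)
}

#' Methylation level at a motif position
#'
#' The CpG interrogated is the dinucleotide starting at the given 1-based
#' motif position on the motif strand; levels reported for the two cytosines
#' of the CpG (either strand) are averaged. Missing record(s) give NA.
#'
#' @param sites Stranded [GenomicRanges::GRanges] of motif occurrences (width
#'   = motif width).
#' @param meth Methylation table (1-based \code{pos}).
#' @param motif_position 1-based position within the motif (default 12).
#' @return Numeric vector of levels in \[0, 1\], NA where no record exists.
#' @export
methylation_at_position <- function(sites, meth, motif_position = 12) {
  W <- unique(GenomicRanges::width(sites))
  if (length(W) != 1L) stop("sites must share the motif width")
  if (motif_position < 1 || motif_position > W) stop("motif_position outside [1, width]")
  chrom <- as.character(GenomicRanges::seqnames(sites))
  minus <- as.character(GenomicRanges::strand(sites)) == "-"
  # 1-based genomic position of the C of the CpG on the motif strand
  cpos <- ifelse(minus,
                 GenomicRanges::end(sites) - motif_position + 1L,
                 GenomicRanges::start(sites) + motif_position - 1L)
  # the opposite-strand C of the same CpG sits one bp 3' on the motif strand
  gpos <- ifelse(minus, cpos - 1L, cpos + 1L)
  key <- paste(meth$chrom, meth$pos)
  lv1 <- meth$level[match(paste(chrom, cpos), key)]
  lv2 <- meth$level[match(paste(chrom, gpos), key)]
  out <- rowMeans(cbind(lv1, lv2), na.rm = TRUE)
  out[is.nan(out)] <- NA_real_ # no record on either strand
  out
}

#' Classify a binding site by its methylation level
#'
#' Strictly greater than 20 percent is "methylated", at most 20 percent is
#' "unmethylated", and a missing level (no CpG record) is "unknown".
#'
#' @param level Methylation level(s) in \[0, 1\] or NA.
#' @param threshold Classification threshold (default 0.20, strict).
#' @return Character vector over \{"methylated", "unmethylated", "unknown"\}.
#' @export
classify_methylation <- function(level, threshold = 0.20) {
  out <- ifelse(is.na(level) | is.nan(level), "unknown",
                ifelse(level > threshold, "methylated", "unmethylated"))
  as.character(out)
}

#' Representative cohesin binding sites
#'
#' Cohesin binding is represented by the overlapping portions (>= 1 nt) of
#' the Rad21 and SMC3 peak sets, merged.
#'
#' @param rad21,smc3 Peak [GenomicRanges::GRanges] of the two subunits.
#' @return [GenomicRanges::GRanges] of intersected regions.
#' @export
cohesin_sites <- function(rad21, smc3) {
  GenomicRanges::intersect(GenomicRanges::reduce(rad21, ignore.strand = TRUE),
                           GenomicRanges::reduce(smc3, ignore.strand = TRUE),
                           ignore.strand = TRUE)
}

#' Cohesin depletion at methylated binding sites
#'
#' Compares cohesin coverage (percent of sites overlapped >= 1 nt) between
#' all sites and the methylated subset; depletion significance is the lower
#' hypergeometric tail of the methylated overlap count.
#'
#' @param all_sites All binding sites ([GenomicRanges::GRanges]).
#' @param methylated_sites The methylated subset (must be a subset).
#' @param cohesin Cohesin regions (e.g. from [cohesin_sites()]).
#' @return List: \code{coverage_all}, \code{coverage_methylated} (percent),
#'   \code{p_value}.
#' @export
cohesin_depletion_test <- function(all_sites, methylated_sites, cohesin) {
  if (length(methylated_sites) == 0L) stop("empty methylated site set")
  allhit <- IRanges::overlapsAny(all_sites, cohesin, ignore.strand = TRUE)
  mhit <- IRanges::overlapsAny(methylated_sites, cohesin, ignore.strand = TRUE)
  p <- hypergeometric_test(N = length(all_sites), K = sum(allhit),
                           n = length(methylated_sites), k = sum(mhit),
                           tail = "lower")
  list(coverage_all = 100 * mean(allhit),
       coverage_methylated = 100 * mean(mhit),
       p_value = p)
}

#' Correlation between methylation level and binding signal
#'
#' Pearson correlation between per-site methylation levels and per-site read
#' counts, with a one-sided bootstrap test of negative correlation: pairs are
#' resampled with replacement and the p-value is the smoothed fraction of
#' resamples whose correlation is >= 0.
#'
#' @param levels Per-site methylation levels (NA pairs dropped).
#' @param read_counts Per-site read counts.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Optional RNG seed.
#' @return List: \code{r}, \code{p_value}, \code{n} (pairs used),
#'   \code{n_boot}.
#' @export
methylation_signal_correlation <- function(levels, read_counts, n_boot = 1000,
                                           seed = NULL) {
  ok <- !is.na(levels) & !is.na(read_counts)
  x <- levels[ok]; y <- read_counts[ok]
  if (length(x) < 3L) stop("fewer than 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector: correlation undefined")
  if (!is.null(seed)) set.seed(seed)
  r <- stats::cor(x, y)
  n <- length(x)
  rb <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) return(NA_real_)
    stats::cor(x[i], y[i])
  }, numeric(1))
  p <- (sum(rb >= 0, na.rm = TRUE) + 1) / (n_boot + 1)
  list(r = r, p_value = p, n = n, n_boot = n_boot)
}

#' Unbound control loci: confident motifs with little binding signal
#'
#' Selects motif hits that pass the motif-confidence threshold but whose
#' binding signal falls strictly below the chosen quantile of the signal
#' across all peaks. With an all-constant signal nothing lies strictly below
#' the quantile and the result is empty.
#'
#' @param hits [GenomicRanges::GRanges] of motif hits with a \code{p_value}
#'   column.
#' @param signal Per-hit binding signal (e.g. ChIP read count).
#' @param peak_signal Signal values across all peaks defining the quantile
#'   (default: \code{signal}).
#' @param quantile Quantile cut (default 0.05, the bottom 5 percent).
#' @param p_threshold Motif-confidence threshold on \code{hits$p_value}.
#' @return Subset of \code{hits}.
#' @export
select_unbound_control_loci <- function(hits, signal, peak_signal = signal,
                                        quantile = 0.05, p_threshold = 1e-4) {
  if (length(hits) == 0L) return(hits)
  stopifnot(length(signal) == length(hits))
  cut <- stats::quantile(peak_signal, quantile, names = FALSE)
  hits[hits$p_value <= p_threshold & signal < cut]
}

#' Binding intensity: reads mapping near a site centre
#'
#' Counts reads whose 5' end (strand-aware) lies within
#' \code{[centre - flank, centre + flank)} of each site's floor midpoint.
#'
#' @param sites [GenomicRanges::GRanges] of sites.
#' @param reads [GenomicRanges::GRanges] of mapped reads.
#' @param flank Half-window (default 100 bp).
#' @return Integer vector of read counts per site.
#' @export
binding_intensity <- function(sites, reads, flank = 100) {
  if (length(reads) == 0L) return(integer(length(sites)))
  five <- ifelse(as.character(GenomicRanges::strand(reads)) == "-",
                 GenomicRanges::end(reads), GenomicRanges::start(reads))
  pts <- GenomicRanges::GRanges(GenomicRanges::seqnames(reads),
                                IRanges::IRanges(five, width = 1L))
  center <- floor((GenomicRanges::start(sites) - 1L + GenomicRanges::end(sites)) / 2)
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(sites),
    IRanges::IRanges(start = center - flank + 1L, end = center + flank) # [c-f, c+f) in 0-based
  )
  GenomicRanges::countOverlaps(win, pts, ignore.strand = TRUE)
}
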