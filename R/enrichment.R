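#' Binned signal matrix around sites
#'
#' Extracts the [-flank, +flank) window around every site midpoint, splits it
#' into bins of \code{bin} bp (left to right in genome coordinates), and
#' records the mean track signal per bin. Bases without track coverage count
#' as signal 0, so sparse tracks are handled without NA holes.
#'
#' @param sites [GenomicRanges::GRanges] of sites.
#' @param track Signal track [GenomicRanges::GRanges] with a \code{score}
#'   column (bedGraph semantics; non-overlapping).
#' @param chrom_sizes Named chromosome lengths (bp).
#' @param flank Half-window (default 1500 bp).
#' @param bin Bin width (default 20 bp); must divide \code{flank}.
#' @return Object of class \code{signal_matrix}: list with \code{S} (sites x
#'   bins matrix), \code{offsets} (bin midpoint offsets from the site centre),
#'   \code{flank}, \code{bin}, \code{windows} (the accepted windows).
#' @export
bin_signal <- function(sites, track, chrom_sizes, flank = 1500, bin = 20) {
  if (flank %% bin != 0) stop("flank must be divisible by bin width")
  win <- extract_flank(sites, flank, chrom_sizes)
  if (length(win) == 0L) stop("no site admits a full window")
  nb <- as.integer(2 * flank / bin)
  n <- length(win)
  bin_start <- rep(GenomicRanges::start(win), each = nb) +
    rep.int(seq_len(nb) - 1L, n) * bin
  bins <- GenomicRanges::GRanges(
    seqnames = rep(GenomicRanges::seqnames(win), each = nb),
    ranges = IRanges::IRanges(start = bin_start, width = bin)
  )
  S <- matrix(0, n, nb)
  ov <- GenomicRanges::findOverlaps(bins, track, ignore.strand = TRUE)
  if (length(ov)) {
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(IRanges::ranges(bins)[qi],
                                            IRanges::ranges(track)[si]))
    contrib <- track$score[si] * w / bin
    agg <- rowsum(contrib, qi)
    flat <- as.integer(rownames(agg)) # bins are laid out site-major
    S[cbind((flat - 1L) %/% nb + 1L, (flat - 1L) %% nb + 1L)] <- agg[, 1L]
  }
  ids <- if (is.null(names(win))) as.character(seq_len(n)) else names(win)
  rownames(S) <- ids
  offsets <- -flank + (seq_len(nb) - 0.5) * bin
  colnames(S) <- offsets
  structure(list(S = S, offsets = offsets, flank = flank, bin = bin,
                 windows = win),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("Signal matrix:", nrow(x$S), "sites x", ncol(x$S), "bins of",
      x$bin, "bp (flank", x$flank, "bp)\n")
  invisible(x)
}

#' Per-bin control profile from an Input track
#'
#' The control strength per bin is the mean Input signal over the same site
#' windows as the signal matrix (site-matched, so the division in
#' [fold_enrichment()] is well-typed per bin offset).
#'
#' @param sites,track,chrom_sizes,flank,bin As in [bin_signal()].
#' @return Numeric vector of per-bin control strengths C_j.
#' @export
control_profile <- function(sites, track, chrom_sizes, flank = 1500, bin = 20) {
  colMeans(bin_signal(sites, track, chrom_sizes, flank, bin)$S)
}

#' Per-bin fold-enrichment of signal over control
#'
#' Element-wise S_ij / C_j of a sites-by-bins signal matrix against a per-bin
#' control profile. Bins with zero control are masked (NA), never infinite.
#'
#' @param sm A \code{signal_matrix} (or bare sites x bins matrix).
#' @param control Per-bin control vector C_j (length = number of bins).
#' @return Sites x bins matrix of fold-enrichments, NA where C_j = 0.
#' @export
fold_enrichment <- function(sm, control) {
  S <- if (inherits(sm, "signal_matrix")) sm$S else sm
  if (length(control) != ncol(S)) stop("control length must equal the number of bins")
  fe <- sweep(S, 2L, control, "/")
  fe[, control == 0] <- NA_real_
  fe
}

#' Colocalization fold-enrichment of a feature at query sites
#'
#' P = percent of query sites overlapped (>= 1 nt) by the feature; C = the
#' same percent over control regions after discarding control regions that
#' overlap any query site; fold = P / C, with a hypergeometric enrichment
#' p-value over the pooled query + control regions.
#'
#' @param query Query site [GenomicRanges::GRanges].
#' @param feature Feature peaks.
#' @param control Control peaks (e.g. Input peaks); query-overlapping ones
#'   are removed before computing C.
#' @return List of class \code{colocalization}: \code{P}, \code{C} (percent),
#'   \code{fold} (NA when C = 0), \code{p_value}, \code{n_control_discarded}.
#' @export
colocalization_fold <- function(query, feature, control) {
  drop <- IRanges::overlapsAny(control, query, ignore.strand = TRUE)
  n_disc <- sum(drop)
  control <- control[!drop]
  if (length(query) == 0L || length(control) == 0L) stop("empty query or control set")
  qhit <- IRanges::overlapsAny(query, feature, ignore.strand = TRUE)
  chit <- IRanges::overlapsAny(control, feature, ignore.strand = TRUE)
  P <- 100 * mean(qhit)
  C <- 100 * mean(chit)
  fold <- if (C == 0) { warning("no control region overlapped; fold undefined"); NA_real_ } else P / C
  p <- hypergeometric_test(N = length(query) + length(control),
                           K = sum(qhit) + sum(chit),
                           n = length(query), k = sum(qhit), tail = "upper")
  structure(list(P = P, C = C, fold = fold, p_value = p,
                 n_control_discarded = n_disc),
            class = "colocalization")
}

#' @export
print.colocalization <- function(x, ...) {
  cat(sprintf("Colocalization: P = %.1f%%, C = %.1f%%, fold = %.2f, p = %.3g\n",
              x$P, x$C, x$fold, x$p_value))
  invisible(x)
}

#' Exact hypergeometric tail test
#'
#' Upper tail P(X >= k) for enrichment, lower tail P(X <= k) for depletion,
#' for X hypergeometric with population \code{N}, \code{K} successes and
#' sample size \code{n}.
#'
#' @param N Population size.
#' @param K Successes in the population.
#' @param n Sample size.
#' @param k Observed successes in the sample.
#' @param tail "upper" (enrichment) or "lower" (depletion).
#' @return Exact tail probability.
#' @export
hypergeometric_test <- function(N, K, n, k, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (K > N || n > N || k > min(n, K) || k < max(0, n + K - N)) {
    stop("inconsistent hypergeometric counts")
  }
  if (tail == "upper") {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  }
}

#' Link genes to their nearest labeled motif site
#'
#' Each TSS is assigned the label of the nearest motif site (by
#' TSS-to-site-midpoint distance) within +/- \code{window} bp, or "other"
#' when no labeled site is that close. Exact distance ties go to the site
#' with the more significant motif p-value, then to the leftmost site.
#'
#' @param tss [GenomicRanges::GRanges] of TSS positions (1 bp, stranded; the
#'   5' position of wider intervals is used).
#' @param motif_sites [GenomicRanges::GRanges] with metadata columns
#'   \code{label} and \code{p_value}.
#' @param window Linking window in bp (default 50000).
#' @return data.frame: gene (names of \code{tss}), label, distance (bp; NA
#'   for "other").
#' @export
link_genes <- function(tss, motif_sites, window = 50000) {
  tpos <- ifelse(as.character(GenomicRanges::strand(tss)) == "-",
                 GenomicRanges::end(tss), GenomicRanges::start(tss))
  tchr <- as.character(GenomicRanges::seqnames(tss))
  mpos <- floor((GenomicRanges::start(motif_sites) - 1L + GenomicRanges::end(motif_sites)) / 2)
  mchr <- as.character(GenomicRanges::seqnames(motif_sites))
  lab <- motif_sites$label
  pv <- motif_sites$p_value
  genes <- if (is.null(names(tss))) paste0("gene", seq_along(tss)) else names(tss)
  out_lab <- rep("other", length(tss))
  out_d <- rep(NA_real_, length(tss))
  for (i in seq_along(tss)) {
    onchr <- which(mchr == tchr[i])
    if (!length(onchr)) next
    d <- abs(mpos[onchr] - tpos[i])
    ok <- onchr[d <= window]
    if (!length(ok)) next
    dd <- abs(mpos[ok] - tpos[i])
    cand <- ok[dd == min(dd)]
    if (length(cand) > 1L) {
      cand <- cand[order(pv[cand], mpos[cand])][1L]
    }
    out_lab[i] <- lab[cand]
    out_d[i] <- min(dd)
  }
  data.frame(gene = genes, label = out_lab, distance = out_d,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Does each site overlap a promoter region?
#'
#' Promoters are the strand-aware windows from \code{upstream} bp upstream to
#' \code{downstream} bp downstream of each TSS. Sites overlapping any
#' promoter by >= 1 nt are flagged.
#'
#' @param sites [GenomicRanges::GRanges] of sites.
#' @param tss Stranded TSS positions; missing strand is treated as "+" with a
#'   warning.
#' @param upstream,downstream Promoter extent in bp (defaults 2500 / 500).
#' @return Logical vector, one per site.
#' @export
classify_promoter_overlap <- function(sites, tss, upstream = 2500, downstream = 500) {
  str <- as.character(GenomicRanges::strand(tss))
  if (any(str == "*")) {
    warning("TSS with missing strand treated as '+'")
    GenomicRanges::strand(tss)[str == "*"] <- "+"
  }
  prom <- GenomicRanges::promoters(tss, upstream = upstream, downstream = downstream)
  prom <- GenomicRanges::trim(prom)
  IRanges::overlapsAny(sites, prom, ignore.strand = TRUE)
}
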