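#' Default planted consensus trio
#'
#' Three dissimilar 19-bp consensus sequences used as the default planted
#' motif classes of the simulators (mirroring a three-variant binding-site
#' pool with mutually exclusive classes).
#'
#' @return Named character vector (class_1, class_2, class_3).
#' @export
default_consensus_trio <- function() {
  c(class_1 = "TGCCACCTAGGTGGCAGAT",
    class_2 = "ATTCGAGCTTACGCAATCG",
    class_3 = "GGACTATGTCGTCCAATGC")
}

# 4 x W probability matrix implied by planting `consensus` with a per-site
# mutation rate (mutated base uniform over the three alternatives)
planted_pfm <- function(consensus, mutation_rate) {
  W <- nchar(consensus)
  p <- matrix(mutation_rate / 3, 4L, W, dimnames = list(DNA_BASES, NULL))
  idx <- match(strsplit(consensus, "")[[1L]], DNA_BASES)
  p[cbind(idx, seq_len(W))] <- 1 - mutation_rate
  p
}

mutate_instance <- function(consensus, mutation_rate) {
  b <- strsplit(consensus, "")[[1L]]
  hit <- stats::runif(length(b)) < mutation_rate
  if (any(hit)) {
    b[hit] <- vapply(b[hit], function(x) sample(setdiff(DNA_BASES, x), 1L), "")
  }
  paste(b, collapse = "")
}

#' Simulate a pooled sequence set with planted exclusive motif classes
#'
#' Every sequence is drawn iid from the background composition; each
#' class-assigned sequence additionally receives exactly one mutated
#' consensus instance at a uniform random offset and strand (zero-or-one
#' occurrence per sequence). The remainder (1 - sum of proportions) stays
#' background-only.
#'
#' @param n_sequences Pool size.
#' @param length Sequence length in bp (default 200).
#' @param consensus Named character vector of class consensus sequences.
#' @param proportions Class proportions (same length as \code{consensus},
#'   each >= 0, sum <= 1).
#' @param mutation_rate Per-position mutation probability of planted
#'   instances (default 0.1).
#' @param background Base composition (default uniform).
#' @param cpg_position Optional 1-based motif position at which a CpG is
#'   forced with probability \code{cpg_prob} (overrides mutation there).
#' @param cpg_prob Probability of forcing the CpG (per planted instance).
#' @param seed RNG seed (same seed, same pool, byte for byte).
#' @return List: \code{sequences} (named DNAStringSet), \code{truth}
#'   data.frame (id, class — "background" for unplanted —, offset 0-based,
#'   strand), \code{true_pfms} list of planted 4 x W probability matrices.
#' @export
simulate_motif_pool <- function(n_sequences = 1000, length = 200,
                                consensus = default_consensus_trio(),
                                proportions = c(0.5, 0.3, 0.15),
                                mutation_rate = 0.1,
                                background = estimate_background(),
                                cpg_position = NULL, cpg_prob = 0,
                                seed = 1) {
  stopifnot(length(consensus) == length(proportions),
            all(proportions >= 0), sum(proportions) <= 1)
  if (any(nchar(consensus) > length)) stop("motif longer than sequence")
  if (is.null(names(consensus))) names(consensus) <- paste0("class_", seq_along(consensus))
  set.seed(seed)
  classes <- sample(c(names(consensus), "background"), n_sequences, replace = TRUE,
                    prob = c(proportions, 1 - sum(proportions)))
  M <- matrix(sample(DNA_BASES, n_sequences * length, replace = TRUE, prob = background),
              nrow = n_sequences)
  offs <- rep(NA_integer_, n_sequences)
  strands <- rep(NA_character_, n_sequences)
  for (i in which(classes != "background")) {
    cons <- consensus[[classes[i]]]
    W <- nchar(cons)
    inst <- mutate_instance(cons, mutation_rate)
    if (!is.null(cpg_position) && stats::runif(1) < cpg_prob) {
      substr(inst, cpg_position, cpg_position + 1L) <- "CG"
    }
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") inst <- revcomp(inst)
    off <- sample.int(length - W + 1L, 1L) - 1L # 0-based
    M[i, (off + 1L):(off + W)] <- strsplit(inst, "")[[1L]]
    offs[i] <- off
    strands[i] <- strand
  }
  seqs <- apply(M, 1L, paste, collapse = "")
  ids <- sprintf("seq%04d", seq_len(n_sequences))
  list(sequences = stats::setNames(Biostrings::DNAStringSet(seqs), ids),
       truth = data.frame(id = ids, class = classes, offset = offs,
                          strand = strands, stringsAsFactors = FALSE),
       true_pfms = lapply(consensus, planted_pfm, mutation_rate = mutation_rate))
}

#' Simulate labeled binding sites along one synthetic chromosome
#'
#' Sites are laid out on a regular grid with jitter so windows up to
#' \code{spacing / 2} never collide, each carrying a class label and a random
#' strand.
#'
#' @param n_sites Number of sites.
#' @param classes Class labels.
#' @param proportions Class proportions (sum 1; recycled to probabilities).
#' @param width Site width (default 19).
#' @param spacing Grid spacing in bp (default 5000).
#' @param chrom Chromosome name.
#' @param seed RNG seed.
#' @return Stranded [GenomicRanges::GRanges] with a \code{class} column;
#'   attribute \code{chrom_sizes} gives the synthetic chromosome length.
#' @export
simulate_binding_sites <- function(n_sites = 300,
                                   classes = names(default_consensus_trio()),
                                   proportions = c(0.5, 0.3, 0.2),
                                   width = 19, spacing = 5000,
                                   chrom = "chrS", seed = 1) {
  set.seed(seed)
  anchor <- spacing * seq_len(n_sites) + spacing
  jitter <- sample.int(spacing %/% 4L, n_sites, replace = TRUE)
  start0 <- anchor + jitter # 0-based
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = start0 + 1L, width = width),
    strand = sample(c("+", "-"), n_sites, replace = TRUE)
  )
  gr$class <- sample(classes, n_sites, replace = TRUE, prob = proportions)
  names(gr) <- sprintf("site%04d", seq_len(n_sites))
  sizes <- stats::setNames(spacing * (n_sites + 2L) + spacing, chrom)
  attr(gr, "chrom_sizes") <- sizes
  gr
}

#' Simulate binned signal tracks with class-specific enrichment
#'
#' The Input track is flat at \code{baseline}; every mark track adds a
#' Gaussian bump (amplitude x exp(-d^2 / 2 sigma^2)) centred at sites of its
#' target class, plus optional Gaussian noise (truncated at 0).
#'
#' @param sites Labeled sites from [simulate_binding_sites()].
#' @param chrom_sizes Named chromosome lengths.
#' @param marks Named list; each element \code{list(class=, amplitude=,
#'   sigma=)}.
#' @param baseline Baseline signal level (default 1).
#' @param bin Track resolution in bp (default 20).
#' @param noise_sd Additive Gaussian noise sd (default 0.1).
#' @param seed RNG seed.
#' @return Named list of [GenomicRanges::GRanges] tracks (one per mark plus
#'   \code{input}).
#' @export
simulate_signal_tracks <- function(sites, chrom_sizes,
                                   marks = list(mark_active = list(class = "class_1",
                                                                   amplitude = 4,
                                                                   sigma = 150)),
                                   baseline = 1, bin = 20, noise_sd = 0.1,
                                   seed = 1) {
  set.seed(seed)
  chrom <- names(chrom_sizes)[1L]
  L <- unname(chrom_sizes[1L])
  nb <- ceiling(L / bin)
  mids <- (seq_len(nb) - 0.5) * bin
  grid <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start = (seq_len(nb) - 1L) * bin + 1L,
                                                  width = bin))
  centers <- floor((GenomicRanges::start(sites) - 1L + GenomicRanges::end(sites)) / 2)
  tracks <- list()
  for (nm in names(marks)) {
    spec <- marks[[nm]]
    v <- rep(baseline, nb)
    tgt <- centers[sites$class == spec$class]
    for (cc in tgt) {
      d <- mids - cc
      near <- abs(d) < 4 * spec$sigma
      v[near] <- v[near] + spec$amplitude * exp(-d[near]^2 / (2 * spec$sigma^2))
    }
    if (noise_sd > 0) v <- pmax(v + stats::rnorm(nb, 0, noise_sd), 0)
    tr <- grid
    tr$score <- v
    tracks[[nm]] <- tr
  }
  inp <- grid
  inp$score <- rep(baseline, nb)
  tracks$input <- inp
  tracks
}

#' Simulate a methylation/cohesin fixture around labeled sites
#'
#' Places a CpG at a designated motif position with class-specific
#' probability, draws its methylation level from a two-component Beta
#' mixture, lays cohesin (Rad21 + SMC3 overlapping peaks) over sites with an
#' occupancy probability that is lower for methylated sites, and draws
#' per-site read counts with a configurable negative correlation with the
#' methylation level; the reads are realised as 5'-end positions near each
#' site centre.
#'
#' @param sites Labeled stranded sites ([simulate_binding_sites()]).
#' @param cpg_prob_by_class Named per-class probability of a CpG at the motif
#'   position.
#' @param motif_position 1-based motif position of the CpG (default 12).
#' @param meth_mix Probability that a present CpG is drawn from the
#'   high-methylation Beta component (default 0.5).
#' @param beta_high,beta_low Shape pairs of the two Beta components.
#' @param cohesin_occupancy Named occupancy probabilities for
#'   \code{methylated} and \code{unmethylated} (used also for CpG-free
#'   sites).
#' @param target_cor Target Pearson correlation between level and read count
#'   (default -0.5).
#' @param mean_reads,sd_reads Read-count scale.
#' @param coverage_reads Reported bisulfite coverage per CpG record.
#' @param seed RNG seed.
#' @return List: \code{meth} (methylation table, [read_methylation()]
#'   format), \code{rad21}, \code{smc3}, \code{reads}
#'   ([GenomicRanges::GRanges]), \code{truth} per-site data.frame (id, class,
#'   has_cpg, level, methyl_class, cohesin_bound, read_count).
#' @export
simulate_methylation_fixture <- function(sites,
                                         cpg_prob_by_class = c(class_1 = 0.5,
                                                               class_2 = 0.25,
                                                               class_3 = 0.1),
                                         motif_position = 12,
                                         meth_mix = 0.5,
                                         beta_high = c(5, 2), beta_low = c(1.5, 8),
                                         cohesin_occupancy = c(methylated = 0.25,
                                                               unmethylated = 0.5),
                                         target_cor = -0.5,
                                         mean_reads = 50, sd_reads = 10,
                                         coverage_reads = 30,
                                         seed = 1) {
  set.seed(seed)
  n <- length(sites)
  chrom <- as.character(GenomicRanges::seqnames(sites))
  minus <- as.character(GenomicRanges::strand(sites)) == "-"
  center <- floor((GenomicRanges::start(sites) - 1L + GenomicRanges::end(sites)) / 2)
  cpos <- ifelse(minus,
                 GenomicRanges::end(sites) - motif_position + 1L,
                 GenomicRanges::start(sites) + motif_position - 1L)
  has_cpg <- stats::runif(n) < cpg_prob_by_class[sites$class]
  level <- rep(NA_real_, n)
  high <- stats::runif(n) < meth_mix
  level[has_cpg & high] <- stats::rbeta(sum(has_cpg & high), beta_high[1], beta_high[2])
  level[has_cpg & !high] <- stats::rbeta(sum(has_cpg & !high), beta_low[1], beta_low[2])
  mclass <- classify_methylation(level)
  occ <- ifelse(mclass == "methylated", cohesin_occupancy["methylated"],
                cohesin_occupancy["unmethylated"])
  bound <- stats::runif(n) < occ
  # read counts: latent Gaussian with the target correlation against level
  z <- rep(NA_real_, n)
  z[has_cpg] <- as.numeric(scale(level[has_cpg]))
  noise <- stats::rnorm(n)
  lat <- ifelse(has_cpg, target_cor * z + sqrt(1 - target_cor^2) * noise, noise)
  counts <- pmax(0L, as.integer(round(mean_reads + sd_reads * lat)))
  # methylation table: both strands of each present CpG share the level
  meth <- data.frame(chrom = rep(chrom[has_cpg], each = 2L),
                     pos = as.integer(rbind(cpos[has_cpg],
                                            cpos[has_cpg] + ifelse(minus[has_cpg], -1L, 1L))),
                     level = rep(level[has_cpg], each = 2L),
                     coverage = coverage_reads,
                     stringsAsFactors = FALSE)
  meth <- meth[order(meth$chrom, meth$pos), , drop = FALSE]
  rownames(meth) <- NULL
  mk_peaks <- function(half_left, half_right) {
    GenomicRanges::GRanges(chrom[bound],
                           IRanges::IRanges(start = center[bound] - half_left + 1L,
                                            end = center[bound] + half_right))
  }
  rad21 <- mk_peaks(75L, 75L)
  smc3 <- mk_peaks(60L, 90L)
  # reads: count_i 5'-ends uniform in [center-100, center+100)
  starts <- unlist(lapply(seq_len(n), function(i) {
    if (counts[i] == 0L) return(integer(0))
    center[i] - 100L + sample.int(200L, counts[i], replace = TRUE)
  }))
  reads <- GenomicRanges::GRanges(rep(chrom, counts),
                                  IRanges::IRanges(start = starts, width = 36L),
                                  strand = "+")
  truth <- data.frame(id = names(sites), class = sites$class, has_cpg = has_cpg,
                      level = level, methyl_class = mclass,
                      cohesin_bound = bound, read_count = counts,
                      stringsAsFactors = FALSE)
  list(meth = meth, rad21 = rad21, smc3 = smc3, reads = reads, truth = truth)
}

#' Simulate a sparse TSS-distal loop fixture
#'
#' Distal fragments receive a motif class (or stay background-only) and a
#' planted consensus instance; every TSS x distal pair carries a loop with
#' probability \code{positive_rate}, multiplied by \code{tag_effect} when the
#' distal fragment belongs to \code{target_class}.
#'
#' @param n_tss,n_distal Fragment counts (pairs = product).
#' @param positive_rate Baseline loop probability (default 0.012, i.e. 1.2
#'   percent of pairs).
#' @param tag_effect Multiplier on the loop probability for the target class
#'   (1 = null).
#' @param target_class Class receiving the effect.
#' @param consensus,proportions,mutation_rate,background As in
#'   [simulate_motif_pool()].
#' @param frag_length Distal fragment length in bp.
#' @param seed RNG seed.
#' @return List: \code{loops} data.frame ([read_loops()] columns plus
#'   \code{tss}, \code{distal}, \code{looped}), \code{sequences} (named
#'   DNAStringSet of distal fragments), \code{truth} per-fragment data.frame
#'   (fragment, class).
#' @export
simulate_loop_fixture <- function(n_tss = 50, n_distal = 1000,
                                  positive_rate = 0.012, tag_effect = 1,
                                  target_class = "class_1",
                                  consensus = default_consensus_trio(),
                                  proportions = c(0.4, 0.25, 0.2),
                                  mutation_rate = 0.1,
                                  background = estimate_background(),
                                  frag_length = 400, seed = 1) {
  stopifnot(positive_rate > 0, positive_rate < 1)
  set.seed(seed)
  frag_pool <- simulate_motif_pool(n_sequences = n_distal, length = frag_length,
                                   consensus = consensus, proportions = proportions,
                                   mutation_rate = mutation_rate,
                                   background = background,
                                   seed = sample.int(.Machine$integer.max, 1L))
  distal_id <- sprintf("chrL:%d-%d", (seq_len(n_distal) - 1L) * frag_length,
                       seq_len(n_distal) * frag_length)
  sequences <- stats::setNames(frag_pool$sequences, distal_id)
  frag_class <- frag_pool$truth$class
  tss_start <- (seq_len(n_tss) - 1L) * 2000L
  tss_id <- sprintf("chrT:%d-%d", tss_start, tss_start + 1000L)
  pairs <- expand.grid(tss = seq_len(n_tss), distal = seq_len(n_distal),
                       KEEP.OUT.ATTRS = FALSE)
  prate <- ifelse(frag_class[pairs$distal] == target_class,
                  pmin(positive_rate * tag_effect, 1), positive_rate)
  looped <- stats::runif(nrow(pairs)) < prate
  loops <- data.frame(
    tss_chrom = "chrT",
    tss_start = tss_start[pairs$tss],
    tss_end = tss_start[pairs$tss] + 1000L,
    distal_chrom = "chrL",
    distal_start = (pairs$distal - 1L) * frag_length,
    distal_end = pairs$distal * frag_length,
    looped = looped,
    tss = tss_id[pairs$tss],
    distal = distal_id[pairs$distal],
    stringsAsFactors = FALSE
  )
  list(loops = loops, sequences = sequences,
       truth = data.frame(fragment = distal_id, class = frag_class,
                          stringsAsFactors = FALSE))
}
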