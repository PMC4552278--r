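# Independent oracles and small fixture builders shared across tests.

# Exhaustive-enumeration oracle for PWM score p-values: scores every one of
# the 4^W words, discretising per column exactly as the DP does.
enum_pvalue_oracle <- function(pfm, bg, granularity = 0.001) {
  lo <- log2(sweep(pfm_probs(pfm), 1L, bg, "/"))
  W <- ncol(lo)
  words <- as.matrix(expand.grid(rep(list(1:4), W), KEEP.OUT.ATTRS = FALSE))
  si <- round(lo / granularity)
  ints <- rowSums(vapply(seq_len(W), function(j) si[words[, j], j],
                         numeric(nrow(words))))
  probs <- apply(words, 1L, function(w) prod(bg[w]))
  function(score) {
    k <- round(score / granularity)
    # same rounding-slack convention as the DP: a summed-then-rounded score
    # within W granules of the max is the max score, not "above range"
    if (k > max(ints) && k <= max(ints) + W) k <- max(ints)
    sum(probs[ints >= k])
  }
}

# random PFM with positive cells
random_pfm <- function(W, nsites = 20, pseudocount = 0.25) {
  sites <- vapply(seq_len(nsites), function(i) {
    paste(sample(c("A", "C", "G", "T"), W, replace = TRUE), collapse = "")
  }, "")
  build_pfm(sites, pseudocount = pseudocount)
}

gri <- function(chrom, start0, end0, strand = "*", ...) {
  # BED-style 0-based half-open constructor for readable tests
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1L, end = end0),
                               strand = strand)
  mc <- list(...)
  for (nm in names(mc)) S4Vectors::mcols(gr)[[nm]] <- mc[[nm]]
  gr
}

# map each discovered motif to its best-matching planted PFM
match_motifs_to_truth <- function(fit, sim) {
  do.call(rbind, lapply(fit$motifs, function(m) {
    pa <- pfm_probs(m$pfm)
    sims <- vapply(sim$true_pfms, function(tp) {
      max(stats::cor(c(pa), c(tp)),
          stats::cor(c(pa), c(tp[4:1, ncol(tp):1, drop = FALSE])))
    }, numeric(1))
    data.frame(motif = m$label, class = names(which.max(sims)),
               correlation = max(sims), stringsAsFactors = FALSE)
  }))
}

# exclusive-assignment accuracy against simulator ground truth
partition_accuracy <- function(fit, sim) {
  map <- match_motifs_to_truth(fit, sim)
  part <- fit$partition[sim$truth$id, ]
  assigned_class <- map$class[match(part$motif, map$motif)]
  correct <- ifelse(sim$truth$class == "background",
                    part$motif == "unassigned",
                    !is.na(assigned_class) & assigned_class == sim$truth$class)
  mean(correct)
}
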