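#' Seed a motif from the most over-represented k-mer
#'
#' Counts every k-mer on both strands of the pool, ranks by the ratio of
#' observed count to the background expectation, and expands the winner to
#' width W: the k consensus columns are centred and padded with background
#' columns. Ties are broken lexicographically.
#'
#' @param pool Sequences (DNAStringSet or character).
#' @param width Target motif width W.
#' @param k Seed k-mer length (<= W).
#' @param bg Background probabilities.
#' @param consensus_prob Probability mass given to the seed base in each
#'   consensus column of the returned matrix (the rest is split evenly).
#' @return A \code{pfm} (probability-scaled) of width W, with attributes
#'   \code{seed_kmer} and \code{n_seeds_tested} (number of distinct k-mers
#'   examined, used for the Bonferroni-style motif E-value).
#' @export
seed_motif <- function(pool, width = 19, k = 8, bg = estimate_background(),
                       consensus_prob = 0.7) {
  stopifnot(width >= k)
  if (!methods::is(pool, "DNAStringSet")) pool <- Biostrings::DNAStringSet(toupper(as.character(pool)))
  if (all(Biostrings::width(pool) < k)) stop("all sequences shorter than the seed k-mer")
  cnt <- colSums(Biostrings::oligonucleotideFrequency(pool, width = k))
  kmers <- names(cnt)
  both <- cnt + cnt[revcomp(kmers)] # occurrences on either strand
  nwin <- 2 * sum(pmax(Biostrings::width(pool) - k + 1L, 0L))
  bgp <- matrix(bg[match(unlist(strsplit(kmers, ""), use.names = FALSE), DNA_BASES)],
                nrow = length(kmers), byrow = TRUE)
  expected <- nwin * apply(bgp, 1L, prod)
  ratio <- both / expected
  best <- kmers[which.max(ratio)] # names are lexicographic: first max wins ties
  p <- matrix(rep(bg, width), nrow = 4L,
              dimnames = list(DNA_BASES, NULL))
  left <- floor((width - k) / 2)
  for (j in seq_len(k)) {
    col <- rep((1 - consensus_prob) / 3, 4L)
    col[match(substr(best, j, j), DNA_BASES)] <- consensus_prob
    p[, left + j] <- col
  }
  out <- pfm_from_probs(p, nsites = 1)
  attr(out, "seed_kmer") <- best
  attr(out, "n_seeds_tested") <- sum(both > 0) # distinct k-mers actually observed
  out
}

# observed-data log-likelihood contribution (variable part) of the ZOOPS model
zoops_loglik <- function(w0, wsum) sum(log(w0 + wsum))

#' Refine a motif by ZOOPS expectation-maximisation
#'
#' Zero-or-one-occurrence-per-sequence EM on both strands: the E-step forms a
#' per-sequence posterior over all site placements (plus "no site"), the
#' M-step re-estimates the position probabilities and the site prior. Stops
#' when the column-wise maximum absolute change in the probability matrix
#' falls below \code{em_tol}, or after \code{em_max_iter} iterations.
#'
#' @param init Initial \code{pfm} (probability or count scale).
#' @param pool Sequences of equal length.
#' @param bg Background probabilities.
#' @param em_max_iter Maximum EM iterations (0 returns \code{init} unchanged).
#' @param em_tol Convergence tolerance on probability entries.
#' @param pseudocount Pseudocount for the M-step re-estimate.
#' @return A \code{pfm} on the count scale (expected counts), with attributes
#'   \code{loglik} (per-iteration penalized observed-data log-likelihood —
#'   the MAP objective the pseudocounted M-step ascends; non-decreasing),
#'   \code{gamma} (site prior), \code{iterations}.
#' @export
em_refine <- function(init, pool, bg = estimate_background(),
                      em_max_iter = 50, em_tol = 1e-3, pseudocount = 0.25) {
  if (em_max_iter == 0) return(init)
  S <- encode_pool(pool)
  if (!is.matrix(S)) stop("EM refinement requires equal-length sequences")
  W <- init$width
  n <- nrow(S)
  no <- ncol(S) - W + 1L
  f <- pfm_probs(init)
  gamma <- 0.5
  ll <- numeric(0)
  it <- 0L
  repeat {
    it <- it + 1L
    lo <- log2(sweep(f, 1L, bg, "/"))
    scf <- scan_scores(S, lo)
    scr <- scan_scores(S, lo[4:1, W:1, drop = FALSE])
    mx <- pmax(apply(scf, 1L, max), apply(scr, 1L, max))
    mx[!is.finite(mx)] <- 0
    ef <- 2^(scf - mx) * (gamma / (2 * no))
    er <- 2^(scr - mx) * (gamma / (2 * no))
    w0 <- (1 - gamma) * 2^(-mx)
    Z <- w0 + rowSums(ef) + rowSums(er)
    # penalized (MAP) objective: the pseudocounted M-step ascends
    # loglik + pseudocount * sum(log f), not the bare likelihood
    ll <- c(ll, sum(log(Z) + mx * log(2)) + pseudocount * sum(log(f)))
    Wf <- ef / Z
    Wr <- er / Z
    counts <- matrix(0, 4L, W, dimnames = list(DNA_BASES, NULL))
    for (j in seq_len(W)) {
      Bf <- S[, j:(j + no - 1L), drop = FALSE]
      Br <- S[, (W - j + 1L):(W - j + no), drop = FALSE] # minus-strand: complement base
      wf <- c(Wf); bf <- c(Bf)
      wr <- c(Wr); br <- c(Br)
      for (b in 1:4) {
        counts[b, j] <- sum(wf[bf == b]) + sum(wr[br == (5L - b)])
      }
    }
    gamma <- min(max(mean(1 - w0 / Z), 1e-6), 1 - 1e-6)
    fnew <- sweep(counts + pseudocount, 2L, colSums(counts + pseudocount), "/")
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < em_tol || it >= em_max_iter) break
  }
  out <- pfm_from_probs(f, nsites = max(round(sum(counts) / W), 1L),
                        pseudocount = pseudocount)
  attr(out, "loglik") <- ll
  attr(out, "gamma") <- gamma
  attr(out, "iterations") <- it
  out
}

#' Evaluate a candidate motif (likelihood-ratio significance)
#'
#' Lambda = 2 * sum over assigned-site base counts n_bj of
#' n_bj * ln(f_bj / b_b); the p-value is the upper chi-squared tail with 3W
#' degrees of freedom. The motif E-value is the p-value Bonferroni-scaled by
#' the number of seed candidates examined and, when \code{n_windows} is
#' supplied, additionally by the number of possible site alignments (the
#' product over assigned sequences of their scanned window count, both
#' strands) — the selection correction that keeps motifs overfit to small
#' background pools from looking significant. Everything is carried in log
#' space so astronomically small p-values survive.
#'
#' @param pfm The candidate \code{pfm} (pseudocounted probabilities are used
#'   for f).
#' @param sites Character vector of assigned site windows (the counts).
#' @param bg Background probabilities.
#' @param n_seeds_tested Number of seed candidates examined.
#' @param n_windows Optional vector of scanned-window counts (both strands)
#'   per assigned sequence, enabling the alignment-count correction.
#' @return List with \code{lambda}, \code{p_value}, \code{e_value},
#'   \code{log10_e}. With no assigned sites, \code{e_value} is +Inf.
#' @export
evaluate_motif <- function(pfm, sites, bg = estimate_background(),
                           n_seeds_tested = 1, n_windows = NULL) {
  if (length(sites) == 0L) {
    return(list(lambda = NA_real_, p_value = 1, e_value = Inf, log10_e = Inf))
  }
  cnt <- build_pfm(sites, pseudocount = 0)$counts
  f <- pfm_probs(pfm)
  lambda <- 2 * sum(cnt * log(sweep(f, 1L, bg, "/")))
  logp <- stats::pchisq(lambda, df = 3 * pfm$width, lower.tail = FALSE, log.p = TRUE)
  loge <- logp + log(n_seeds_tested)
  if (!is.null(n_windows)) loge <- loge + sum(log(n_windows))
  list(lambda = lambda, p_value = exp(logp), e_value = exp(loge),
       log10_e = loge / log(10))
}

#' Split a pool into motif-assigned and remaining sequences
#'
#' A sequence is assigned iff its best-hit p-value passes \code{p_assign};
#' the assigned set and the remainder partition the pool.
#'
#' @param pfm A \code{pfm}.
#' @param pool Named sequences (equal length).
#' @param p_assign Best-hit p-value threshold.
#' @param bg Background probabilities.
#' @return List: \code{assigned} data.frame (id, offset 0-based, strand,
#'   score, p_value, site string), \code{remaining} character vector of ids.
#' @export
eliminate_sequences <- function(pfm, pool, p_assign = 1e-4, bg = estimate_background()) {
  seqs <- as_named_chars(pool)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  S <- encode_pool(seqs)
  if (!is.matrix(S)) stop("pool sequences must have equal length")
  lo <- pwm_log_odds(pfm, bg)
  hits <- scan_best(S, lo, both_strands = TRUE)
  dist <- pwm_score_dist(lo, bg)
  hits$p_value <- score_dist_pvalue(dist, hits$score)
  keep <- hits$p_value <= p_assign
  W <- pfm$width
  site <- substr(seqs, hits$offset + 1L, hits$offset + W)
  site[hits$strand == "-"] <- revcomp(site[hits$strand == "-"])
  assigned <- data.frame(id = names(seqs)[keep], offset = hits$offset[keep],
                         strand = hits$strand[keep], score = hits$score[keep],
                         p_value = hits$p_value[keep], site = site[keep],
                         stringsAsFactors = FALSE)
  list(assigned = assigned, remaining = names(seqs)[!keep])
}

#' Re-estimate a motif from its assigned site windows
#'
#' Replaces the EM estimate by a plain recount over the best-site windows of
#' the assigned sequences; motifs supported by fewer than \code{min_assigned}
#' sites are rejected (NULL).
#'
#' @param sites Character vector of assigned W-mers (motif-strand oriented).
#' @param min_assigned Minimum supporting sites.
#' @param pseudocount Pseudocount for the recount.
#' @return A \code{pfm}, or NULL when rejected.
#' @export
update_motif <- function(sites, min_assigned = 20, pseudocount = 0.25) {
  if (length(sites) < min_assigned) return(NULL)
  build_pfm(sites, pseudocount = pseudocount)
}

# Frame refinement: the seed fixes an arbitrary frame inside the width-W
# window; sliding the frame over the assigned sites and keeping the shift
# with the highest mean per-site log-likelihood ratio re-centres the motif
# on its informative columns. Shift 0 wins ties.
reframe_motif <- function(assigned, seqs, W, shift_max, bg, pseudocount = 0.25) {
  shifts <- order(abs(seq(-shift_max, shift_max)))
  shifts <- seq(-shift_max, shift_max)[shifts] # 0, -1, 1, -2, 2, ...
  best <- NULL
  best_score <- -Inf
  L <- nchar(seqs[1L])
  for (s in shifts) {
    off <- ifelse(assigned$strand == "-", assigned$offset - s, assigned$offset + s)
    ok <- off >= 0L & off + W <= L
    if (sum(ok) < 2L) next
    site <- substr(seqs[assigned$id[ok]], off[ok] + 1L, off[ok] + W)
    neg <- assigned$strand[ok] == "-"
    site[neg] <- revcomp(site[neg])
    pfm <- build_pfm(site, pseudocount = pseudocount)
    cnt <- pfm$counts - pseudocount
    lam <- 2 * sum(cnt * log(sweep(pfm_probs(pfm), 1L, bg, "/")))
    score <- lam / sum(ok) # mean per-site LLR: comparable across shifts
    if (score > best_score + 1e-9) {
      best_score <- score
      best <- pfm
    }
  }
  best
}

# flattened-probability Pearson correlation between two PFMs (same width),
# maximised over forward and reverse-complement orientation
pfm_similarity <- function(a, b) {
  pa <- pfm_probs(a); pb <- pfm_probs(b)
  fw <- stats::cor(c(pa), c(pb))
  rc <- stats::cor(c(pa), c(pb[4:1, ncol(pb):1, drop = FALSE]))
  max(fw, rc)
}

#' Iterative discovery of mutually exclusive motifs
#'
#' The five-step workflow: (1) motif generation (k-mer seeding + ZOOPS EM
#' refinement), (2) motif evaluation (chi-squared likelihood ratio with a
#' Bonferroni-style E-value over seed candidates), (3) sequence elimination
#' (best-hit p-value threshold), (4) motif updating (recount from assigned
#' windows), looped over the shrinking remainder until (5) a stopping
#' criterion fires: the remainder falls below \code{min_remaining} of the
#' initial pool, the candidate's E-value exceeds \code{e_max}, or
#' \code{max_motifs} have been accepted. A candidate whose probability matrix
#' correlates at \code{merge_cor} or more with an earlier motif (forward or
#' reverse complement) is merged into that motif instead of founding a new
#' one. Motif q-values are Benjamini-Hochberg adjusted over all candidates
#' evaluated in the run.
#'
#' @param pool Sequences (DNAStringSet, named character vector, or FASTA
#'   path) of equal length.
#' @param width Motif width W (default 19).
#' @param max_motifs Maximum motifs to report.
#' @param e_max Motif E-value acceptance threshold.
#' @param p_assign Per-sequence best-hit p-value for assignment.
#' @param min_remaining Stop when remaining/initial falls below this fraction.
#' @param min_assigned Minimum sequences supporting an accepted motif.
#' @param seed_k Seed k-mer length.
#' @param em_max_iter,em_tol EM controls.
#' @param pseudocount Pseudocount per base per column.
#' @param background Background probabilities; estimated from the pool when
#'   NULL.
#' @param merge_cor Column-correlation threshold for duplicate merging.
#' @param seed Integer RNG seed (the workflow is deterministic; the seed is
#'   recorded and set for reproducibility of any downstream sampling).
#' @return Object of class \code{motif_discovery}: list with \code{motifs}
#'   (each: label, pfm, bg, e_value, q_value, order, n_assigned, seed_kmer),
#'   \code{partition} data.frame (id, motif, offset, strand, p_value),
#'   \code{log} per-iteration data.frame, \code{params}, \code{background}.
#' @export
discover_motifs <- function(pool, width = 19, max_motifs = 5, e_max = 1e-5,
                            p_assign = 1e-4, min_remaining = 0.05,
                            min_assigned = 20, seed_k = 8,
                            em_max_iter = 50, em_tol = 1e-3,
                            pseudocount = 0.25, background = NULL,
                            merge_cor = 0.9, seed = NULL) {
  if (is.character(pool) && length(pool) == 1L && file.exists(pool)) pool <- read_fasta(pool)
  seqs <- as_named_chars(pool)
  if (length(seqs) == 0L) stop("empty sequence pool")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (!is.null(seed)) set.seed(seed)
  bg <- if (is.null(background)) estimate_background(seqs) else background
  params <- list(width = width, max_motifs = max_motifs, e_max = e_max,
                 p_assign = p_assign, min_remaining = min_remaining,
                 min_assigned = min_assigned, seed_k = seed_k,
                 em_max_iter = em_max_iter, em_tol = em_tol,
                 pseudocount = pseudocount, merge_cor = merge_cor, seed = seed)
  n0 <- length(seqs)
  remaining <- seqs
  motifs <- list()
  assignment <- data.frame(id = names(seqs), motif = "unassigned",
                           offset = NA_integer_, strand = NA_character_,
                           p_value = NA_real_, stringsAsFactors = FALSE)
  rownames(assignment) <- assignment$id
  cand_p <- numeric(0) # q-value family: every candidate evaluated this run
  cand_idx <- integer(0) # index into `motifs` (0 = not accepted)
  log <- list()
  stop_reason <- "max_motifs"
  repeat {
    if (length(remaining) / n0 < min_remaining) { stop_reason <- "min_remaining"; break }
    seed_pfm <- seed_motif(remaining, width = width, k = seed_k, bg = bg)
    ref <- em_refine(seed_pfm, remaining, bg = bg, em_max_iter = em_max_iter,
                     em_tol = em_tol, pseudocount = pseudocount)
    el0 <- eliminate_sequences(ref, remaining, p_assign = p_assign, bg = bg)
    if (nrow(el0$assigned) >= 2L) {
      framed <- reframe_motif(el0$assigned, remaining, width,
                              shift_max = ceiling((width - seed_k) / 2) + 1L,
                              bg = bg, pseudocount = pseudocount)
      if (!is.null(framed)) ref <- framed
    }
    el <- eliminate_sequences(ref, remaining, p_assign = p_assign, bg = bg)
    upd <- update_motif(el$assigned$site, min_assigned = min_assigned,
                        pseudocount = pseudocount)
    if (is.null(upd)) { stop_reason <- "min_assigned"; break }
    nwin <- 2 * (nchar(remaining[el$assigned$id]) - width + 1L)
    ev <- evaluate_motif(upd, el$assigned$site, bg = bg,
                         n_seeds_tested = attr(seed_pfm, "n_seeds_tested"),
                         n_windows = nwin)
    cand_p <- c(cand_p, ev$p_value)
    log[[length(log) + 1L]] <- data.frame(
      iteration = length(log) + 1L, pool_size = length(remaining),
      seed_kmer = attr(seed_pfm, "seed_kmer"), n_assigned = nrow(el$assigned),
      e_value = ev$e_value, log10_e = ev$log10_e, stringsAsFactors = FALSE)
    if (ev$log10_e > log10(e_max)) { cand_idx <- c(cand_idx, 0L); stop_reason <- "e_max"; break }
    merged <- FALSE
    for (m in seq_along(motifs)) {
      if (pfm_similarity(upd, motifs[[m]]$pfm) >= merge_cor) {
        # duplicate (typically reverse-complement) of an earlier motif
        assignment[el$assigned$id, "motif"] <- motifs[[m]]$label
        assignment[el$assigned$id, c("offset", "strand", "p_value")] <-
          el$assigned[, c("offset", "strand", "p_value")]
        motifs[[m]]$n_assigned <- motifs[[m]]$n_assigned + nrow(el$assigned)
        merged <- TRUE
        cand_idx <- c(cand_idx, m)
        break
      }
    }
    if (!merged) {
      ord <- length(motifs) + 1L
      label <- paste0("motif_", LETTERS[min(ord, 26L)])
      motifs[[ord]] <- list(label = label, pfm = upd, bg = bg,
                            e_value = ev$e_value, log10_e = ev$log10_e,
                            q_value = NA_real_,
                            order = ord, n_assigned = nrow(el$assigned),
                            seed_kmer = attr(seed_pfm, "seed_kmer"))
      cand_idx <- c(cand_idx, ord)
      assignment[el$assigned$id, "motif"] <- label
      assignment[el$assigned$id, c("offset", "strand", "p_value")] <-
        el$assigned[, c("offset", "strand", "p_value")]
    }
    remaining <- remaining[el$remaining]
    if (length(motifs) >= max_motifs) { stop_reason <- "max_motifs"; break }
  }
  if (length(cand_p)) {
    q <- stats::p.adjust(cand_p, method = "BH")
    for (i in seq_along(cand_idx)) {
      if (cand_idx[i] > 0L && is.na(motifs[[cand_idx[i]]]$q_value)) {
        motifs[[cand_idx[i]]]$q_value <- q[i]
      }
    }
  }
  structure(list(motifs = motifs, partition = assignment,
                 log = do.call(rbind, log), params = params, background = bg,
                 n_input = n0, stop_reason = stop_reason),
            class = "motif_discovery")
}

#' @export
print.motif_discovery <- function(x, ...) {
  cat("Motif discovery fit:", length(x$motifs), "motif(s) over",
      x$n_input, "sequences\n")
  for (m in x$motifs) {
    cat(sprintf("  %s  width %d  n=%d  log10(E)=%.1f  q=%.3g  consensus %s\n",
                m$label, m$pfm$width, m$n_assigned, m$log10_e, m$q_value,
                pfm_consensus(m$pfm)))
  }
  cat(sprintf("  unassigned: %d (%.1f%%)  [stop: %s]\n",
              sum(x$partition$motif == "unassigned"),
              100 * mean(x$partition$motif == "unassigned"), x$stop_reason))
  invisible(x)
}

#' @export
summary.motif_discovery <- function(object, ...) {
  tab <- table(factor(object$partition$motif,
                      levels = c(vapply(object$motifs, `[[`, "", "label"), "unassigned")))
  out <- list(
    n_motifs = length(object$motifs),
    n_input = object$n_input,
    assignment = tab,
    proportions = as.numeric(tab) / object$n_input,
    motifs = do.call(rbind, lapply(object$motifs, function(m) {
      data.frame(label = m$label, width = m$pfm$width, n_assigned = m$n_assigned,
                 e_value = m$e_value, q_value = m$q_value,
                 consensus = pfm_consensus(m$pfm), stringsAsFactors = FALSE)
    })),
    log = object$log
  )
  class(out) <- "summary.motif_discovery"
  out
}

#' @export
print.summary.motif_discovery <- function(x, ...) {
  cat("Discovered motifs:\n")
  print(x$motifs)
  cat("\nSequence partition:\n")
  print(x$assignment)
  invisible(x)
}

#' Coefficients of a motif discovery fit: the probability matrices
#' @param object A \code{motif_discovery} fit.
#' @param ... Unused.
#' @return Named list of 4 x W probability matrices.
#' @export
coef.motif_discovery <- function(object, ...) {
  stats::setNames(lapply(object$motifs, function(m) pfm_probs(m$pfm)),
                  vapply(object$motifs, `[[`, "", "label"))
}

#' Assign new sequences to discovered motifs
#'
#' @param object A \code{motif_discovery} fit.
#' @param newdata Sequences (DNAStringSet or character).
#' @param p_threshold Assignment p-value threshold (default: the fit's
#'   \code{p_assign}).
#' @param ... Unused.
#' @return data.frame: id, motif ("unassigned" when nothing passes), offset
#'   (0-based), strand, p_value.
#' @export
predict.motif_discovery <- function(object, newdata, p_threshold = NULL, ...) {
  if (is.null(p_threshold)) p_threshold <- object$params$p_assign
  seqs <- as_named_chars(newdata)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  assign_pool(seqs, object$motifs, p_threshold = p_threshold)
}

#' Plot per-column information content of discovered motifs
#'
#' One panel per motif: information content (bits) per position, consensus
#' letters on the axis, stars marking the most informative columns.
#'
#' @param x A \code{motif_discovery} fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.motif_discovery <- function(x, ...) {
  k <- length(x$motifs)
  if (k == 0L) { warning("no motifs to plot"); return(invisible(x)) }
  old <- graphics::par(mfrow = c(k, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in x$motifs) {
    ic <- information_content(m$pfm, m$bg)
    cons <- strsplit(pfm_consensus(m$pfm), "")[[1L]]
    bp <- graphics::barplot(as.numeric(ic), names.arg = cons,
                            ylab = "bits", main = m$label, ylim = c(0, 2.1), ...)
    inf <- attr(ic, "informative")
    graphics::text(bp[inf], as.numeric(ic)[inf] + 0.12, "*", cex = 1.2)
  }
  invisible(x)
}
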