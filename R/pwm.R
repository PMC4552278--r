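DNA_BASES <- c("A", "C", "G", "T")

# integer-encode sequences: A=1 C=2 G=3 T=4 N=5; equal-length input -> matrix
encode_seq <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1]], DNA_BASES)
  v[is.na(v)] <- 5L
  v
}

encode_pool <- function(seqs) {
  seqs <- as.character(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) == 1L) {
    m <- matrix(match(unlist(strsplit(toupper(seqs), ""), use.names = FALSE), DNA_BASES),
                nrow = length(seqs), byrow = TRUE)
    m[is.na(m)] <- 5L
    m
  } else {
    lapply(seqs, encode_seq)
  }
}

revcomp <- function(s) {
  # chartr + reverse: cheap for the short strings this package handles
  vapply(chartr("ACGTN", "TGCAN", s),
         function(x) paste(rev(strsplit(x, "")[[1L]]), collapse = ""),
         "", USE.NAMES = FALSE)
}

# as.character drops names on plain character input; keep them
as_named_chars <- function(x) {
  s <- as.character(x)
  if (!is.null(names(x))) names(s) <- names(x)
  s
}

#' Uniform or estimated mononucleotide background
#'
#' @param seqs Optional sequences (character or DNAStringSet); if omitted, the
#'   uniform background is returned.
#' @return Named probability vector over A, C, G, T (all > 0, summing to 1).
#' @export
estimate_background <- function(seqs = NULL) {
  if (is.null(seqs)) {
    return(stats::setNames(rep(0.25, 4), DNA_BASES))
  }
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  cnt <- colSums(Biostrings::letterFrequency(seqs, DNA_BASES))
  cnt <- cnt + 1 # Laplace: background probabilities must stay positive
  stats::setNames(cnt / sum(cnt), DNA_BASES)
}

#' Build a position frequency matrix from aligned sites
#'
#' Counts base occurrences per column over equal-length site strings, adding a
#' pseudocount to every cell. Sites containing N are dropped with a warning.
#'
#' @param sites Character vector of equal-length DNA strings.
#' @param pseudocount Pseudocount added per base per column (default 0.25).
#' @return An object of class \code{pfm}: list with \code{counts} (4 x W,
#'   rows A/C/G/T), \code{width}, \code{nsites}, \code{pseudocount}.
#' @export
build_pfm <- function(sites, pseudocount = 0.25) {
  sites <- toupper(as.character(sites))
  if (length(sites) == 0L) stop("no sites supplied")
  if (length(unique(nchar(sites))) != 1L) stop("sites must all have the same length")
  hasN <- grepl("[^ACGT]", sites)
  if (any(hasN)) {
    warning(sum(hasN), " site(s) containing N dropped")
    sites <- sites[!hasN]
    if (length(sites) == 0L) stop("all sites contained N")
  }
  W <- nchar(sites[1L])
  m <- matrix(match(unlist(strsplit(sites, ""), use.names = FALSE), DNA_BASES),
              nrow = length(sites), byrow = TRUE)
  counts <- vapply(seq_len(W), function(j) tabulate(m[, j], nbins = 4L), numeric(4))
  counts <- counts + pseudocount
  dimnames(counts) <- list(DNA_BASES, NULL)
  structure(list(counts = counts, width = W, nsites = length(sites),
                 pseudocount = pseudocount),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("Position frequency matrix: width", x$width, "from", x$nsites, "site(s)\n")
  cat("Consensus:", pfm_consensus(x), "\n")
  invisible(x)
}

#' Column probabilities of a PFM
#' @param pfm A \code{pfm} object (or a bare 4 x W probability matrix).
#' @return 4 x W column-stochastic matrix.
#' @export
pfm_probs <- function(pfm) {
  m <- if (inherits(pfm, "pfm")) pfm$counts else pfm
  sweep(m, 2L, colSums(m), "/")
}

#' Consensus string of a PFM (most frequent base per column)
#' @param pfm A \code{pfm} object.
#' @export
pfm_consensus <- function(pfm) {
  paste(DNA_BASES[apply(pfm_probs(pfm), 2L, which.max)], collapse = "")
}

# probability matrix from raw probs (used by simulators / tests)
pfm_from_probs <- function(p, nsites = 1, pseudocount = 0) {
  structure(list(counts = p * nsites, width = ncol(p), nsites = nsites,
                 pseudocount = pseudocount), class = "pfm")
}

#' Per-column information content of a motif
#'
#' IC_j = sum_b f_bj log2(f_bj / b_b), with 0 log 0 = 0. The "most
#' informative" positions are those whose IC exceeds a configurable quantile
#' of the per-column IC values.
#'
#' @param pfm A \code{pfm} object.
#' @param bg Background probabilities (default uniform).
#' @return Numeric vector of length W (bits), with attribute
#'   \code{informative}: logical vector marking columns above the quantile.
#' @param informative_quantile Quantile defining "most informative" columns
#'   (default 0.75, i.e. the top 25 percent).
#' @export
information_content <- function(pfm, bg = estimate_background(),
                                informative_quantile = 0.75) {
  f <- pfm_probs(pfm)
  term <- f * log2(sweep(f, 1L, bg, "/"))
  term[f == 0] <- 0
  ic <- colSums(term)
  attr(ic, "informative") <- ic > stats::quantile(ic, informative_quantile)
  ic
}

# log2-odds score matrix (4 x W), finite because of pseudocounts
pwm_log_odds <- function(pfm, bg = estimate_background()) {
  f <- pfm_probs(pfm)
  if (any(f == 0)) stop("zero cell in PFM; use a positive pseudocount")
  log2(sweep(f, 1L, bg, "/"))
}

# score all windows of an integer-encoded pool (n x L matrix) with a 4 x W
# log-odds matrix; windows containing N score -Inf. Returns n x (L-W+1).
scan_scores <- function(S, lo) {
  W <- ncol(lo)
  L <- ncol(S)
  n <- nrow(S)
  no <- L - W + 1L
  if (no < 1L) stop("sequence shorter than motif width")
  sc <- matrix(0, n, no)
  for (j in seq_len(W)) {
    col <- c(lo[, j], -Inf)
    sc <- sc + matrix(col[S[, j:(j + no - 1L), drop = FALSE]], n, no)
  }
  sc
}

# best hit per sequence over both strands for an n x L pool matrix.
# Tie-break: smaller offset, then + strand.
scan_best <- function(S, lo, both_strands = TRUE) {
  scf <- scan_scores(S, lo)
  no <- ncol(scf)
  if (both_strands) {
    lor <- lo[4:1, ncol(lo):1, drop = FALSE] # reverse-complement PWM
    scr <- scan_scores(S, lor)
  } else {
    scr <- matrix(-Inf, nrow(S), no)
  }
  best <- pmax(apply(scf, 1L, max), apply(scr, 1L, max))
  off <- integer(nrow(S)); strand <- character(nrow(S))
  for (i in seq_len(nrow(S))) {
    bf <- which(scf[i, ] == best[i])
    br <- which(scr[i, ] == best[i])
    of <- if (length(bf)) bf[1L] else Inf
    or <- if (length(br)) br[1L] else Inf
    if (of <= or) { off[i] <- of; strand[i] <- "+" } else { off[i] <- or; strand[i] <- "-" }
  }
  data.frame(offset = off - 1L, strand = strand, score = best) # offset 0-based
}

#' Best motif hit in one sequence
#'
#' Scans every offset (and, optionally, the reverse complement) with the
#' log2-odds matrix of \code{pfm} against \code{bg} and returns the maximal
#' scoring window. Ties are broken by smaller offset, then by the + strand.
#' Windows containing N score -Inf and never win against a finite score.
#'
#' @param pfm A \code{pfm} object.
#' @param bg Background probabilities.
#' @param seq A single DNA string (or length-1 DNAStringSet).
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @return One-row data.frame: \code{offset} (0-based), \code{strand},
#'   \code{score} (bits), \code{p_value} (exact per-window tail probability),
#'   \code{e_value} (p-value times the number of windows scanned).
#' @export
best_hit <- function(pfm, bg, seq, both_strands = TRUE) {
  s <- as.character(seq)[1L]
  if (nchar(s) < pfm$width) stop("sequence shorter than motif width")
  S <- matrix(encode_seq(s), nrow = 1L)
  lo <- pwm_log_odds(pfm, bg)
  hit <- scan_best(S, lo, both_strands)
  dist <- pwm_score_dist(lo, bg)
  hit$p_value <- score_dist_pvalue(dist, hit$score)
  nwin <- (nchar(s) - pfm$width + 1L) * (1L + both_strands)
  hit$e_value <- hit$p_value * nwin
  hit
}

# Exact distribution of the log2-odds score of a random W-mer drawn iid from
# bg, by dynamic programming over scores discretised to `granularity` bits.
pwm_score_dist <- function(lo, bg, granularity = 0.001) {
  si <- round(lo / granularity)
  offs <- apply(si, 2L, min)
  pv <- 1
  for (j in seq_len(ncol(si))) {
    s <- si[, j] - offs[j]
    np <- numeric(length(pv) + max(s))
    for (b in 1:4) {
      idx <- seq_along(pv) + s[b]
      np[idx] <- np[idx] + pv * bg[b]
    }
    pv <- np
  }
  list(min_int = sum(offs), tail = rev(cumsum(rev(pv))),
       granularity = granularity, width = ncol(si))
}

score_dist_pvalue <- function(dist, score) {
  k <- round(score / dist$granularity) - dist$min_int + 1
  # per-column rounding vs rounding the summed score can differ by up to one
  # granule per column: scores within that slack of the maximum are the
  # maximum, not "above range"
  len <- length(dist$tail)
  over <- is.finite(k) & k > len & k <= len + dist$width
  k[over] <- len
  p <- numeric(length(score))
  p[!is.finite(k) & score < 0] <- 1 # -Inf (N windows): below min
  lo <- is.finite(k) & k <= 1
  hi <- is.finite(k) & k > len
  mid <- is.finite(k) & !lo & !hi
  p[lo] <- 1
  p[hi] <- 0
  p[mid] <- dist$tail[k[mid]]
  p
}

#' Exact p-value of a log-odds score
#'
#' P(random W-mer drawn iid from \code{bg} scores >= \code{score}), computed
#' by dynamic programming over scores discretised to \code{granularity} bits
#' (default 1/1000 bit). Scores below the achievable minimum return 1, above
#' the maximum return 0.
#'
#' @param pfm A \code{pfm} object.
#' @param bg Background probabilities.
#' @param score Score(s) in bits.
#' @param granularity Discretisation step in bits.
#' @return p-value(s) in (0, 1], monotone non-increasing in \code{score}.
#' @export
score_pvalue <- function(pfm, bg, score, granularity = 0.001) {
  score_dist_pvalue(pwm_score_dist(pwm_log_odds(pfm, bg), bg, granularity), score)
}

# Batch exclusive assignment: one scorer build per motif, sequences grouped
# by length. Earlier motifs win p-value ties (strict < against the running
# best keeps the first).
assign_pool <- function(seqs, motifs, p_threshold = 1e-4) {
  seqs <- as_named_chars(seqs)
  n <- length(seqs)
  lab <- rep("unassigned", n)
  bestp <- rep(Inf, n)
  off <- rep(NA_integer_, n)
  str <- rep(NA_character_, n)
  lens <- nchar(seqs)
  for (m in motifs) {
    W <- m$pfm$width
    lo <- pwm_log_odds(m$pfm, m$bg)
    dist <- pwm_score_dist(lo, m$bg)
    for (L in unique(lens[lens >= W])) {
      idx <- which(lens == L)
      S <- encode_pool(seqs[idx])
      hits <- scan_best(S, lo, both_strands = TRUE)
      p <- score_dist_pvalue(dist, hits$score)
      upd <- p <= p_threshold & p < bestp[idx]
      j <- idx[upd]
      lab[j] <- m$label
      bestp[j] <- p[upd]
      off[j] <- hits$offset[upd]
      str[j] <- hits$strand[upd]
    }
  }
  bestp[is.infinite(bestp)] <- NA_real_
  data.frame(id = names(seqs), motif = lab, offset = off, strand = str,
             p_value = bestp, stringsAsFactors = FALSE, row.names = NULL)
}

#' Exclusive assignment of a sequence to the most confident motif
#'
#' Scores the sequence with every motif and returns the label of the motif
#' whose best hit has the smallest p-value, provided it passes
#' \code{p_threshold}; ties go to the earlier motif in the list (discovery
#' order). Sequences shorter than a motif's width skip that motif.
#'
#' @param seq A DNA string.
#' @param motifs List of motif models (as in a \code{motif_discovery} fit):
#'   each has \code{pfm}, \code{bg}, \code{label}.
#' @param p_threshold Assignment p-value threshold.
#' @return List with \code{label} ("unassigned" when nothing passes),
#'   \code{p_value}, \code{offset}, \code{strand}.
#' @export
assign_best_motif <- function(seq, motifs, p_threshold = 1e-4) {
  stopifnot(length(motifs) >= 1L)
  s <- as.character(seq)[1L]
  best <- list(label = "unassigned", p_value = NA_real_, offset = NA_integer_, strand = NA_character_)
  bestp <- Inf
  for (m in motifs) {
    if (nchar(s) < m$pfm$width) next
    h <- best_hit(m$pfm, m$bg, s)
    if (h$p_value <= p_threshold && h$p_value < bestp) {
      bestp <- h$p_value
      best <- list(label = m$label, p_value = h$p_value,
                   offset = h$offset, strand = h$strand)
    }
  }
  best
}

#' Write motifs in MEME minimal format
#'
#' @param motifs List of motif models (\code{pfm}, \code{bg}, \code{label},
#'   optionally \code{e_value}).
#' @param path Output path.
#' @export
write_meme <- function(motifs, path) {
  bg <- motifs[[1L]]$bg
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]), ""),
             con)
  for (m in motifs) {
    f <- pfm_probs(m$pfm)
    ev <- if (is.null(m$e_value)) 0 else m$e_value
    writeLines(sprintf("MOTIF %s", m$label), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= %g",
                       m$pfm$width, m$pfm$nsites, ev), con)
    writeLines(apply(f, 2L, function(col) sprintf(" %.6f %.6f %.6f %.6f",
                                                  col[1], col[2], col[3], col[4])), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from MEME minimal format
#'
#' @param path Path to a MEME-format motif file.
#' @return List of motif models (\code{pfm}, \code{bg}, \code{label},
#'   \code{e_value}).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- estimate_background()
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi)) {
    tok <- strsplit(trimws(lines[bgi[1L] + 1L]), "\\s+")[[1L]]
    bg <- stats::setNames(as.numeric(tok[c(2, 4, 6, 8)]), DNA_BASES)
  }
  starts <- grep("^MOTIF ", lines)
  motifs <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    label <- strsplit(lines[starts[i]], "\\s+")[[1L]][2L]
    hdr <- lines[starts[i] + 1L]
    w <- as.integer(sub(".* w= *(\\d+).*", "\\1", hdr))
    nsites <- as.integer(sub(".* nsites= *(\\d+).*", "\\1", hdr))
    ev <- as.numeric(sub(".* E= *([-0-9.eE+]+).*", "\\1", hdr))
    rows <- lines[(starts[i] + 2L):(starts[i] + 1L + w)]
    p <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1L]]),
                  numeric(4), USE.NAMES = FALSE))
    pfm <- pfm_from_probs(t(p), nsites = nsites)
    dimnames(pfm$counts) <- list(DNA_BASES, NULL)
    motifs[[i]] <- list(label = label, pfm = pfm, bg = bg, e_value = ev)
  }
  motifs
}
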