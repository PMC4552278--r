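#' Tag fragments by their most confident motif
#'
#' Scans each fragment sequence with every discovered motif and tags it with
#' the label of the smallest best-hit p-value passing the threshold
#' ("untagged" otherwise). Fragments shorter than every motif width are
#' untagged with a warning.
#'
#' @param sequences Named fragment sequences (DNAStringSet or character);
#'   names are the fragment ids.
#' @param motifs List of motif models (or a \code{motif_discovery} fit).
#' @param p_threshold Assignment p-value threshold.
#' @return data.frame: fragment, tag, p_value.
#' @export
tag_fragments <- function(sequences, motifs, p_threshold = 1e-4) {
  if (inherits(motifs, "motif_discovery")) motifs <- motifs$motifs
  seqs <- as_named_chars(sequences)
  if (is.null(names(seqs))) names(seqs) <- paste0("frag", seq_along(seqs))
  minW <- min(vapply(motifs, function(m) m$pfm$width, 1L))
  short <- nchar(seqs) < minW
  if (any(short)) warning(sum(short), " fragment(s) shorter than every motif width: untagged")
  res <- assign_pool(seqs, motifs, p_threshold = p_threshold)
  data.frame(fragment = res$id,
             tag = ifelse(res$motif == "unassigned", "untagged", res$motif),
             p_value = res$p_value,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Loop fold-enrichment for one fragment tag
#'
#' fold = (loop rate among fragments carrying the tag) / (loop rate among all
#' fragments); significance is the upper hypergeometric tail of the looped
#' count among tagged fragments.
#'
#' @param tagged data.frame from [tag_fragments()] (columns fragment, tag).
#' @param loops data.frame with columns \code{distal} (fragment id) and
#'   logical \code{looped}; every distal fragment must appear in
#'   \code{tagged}. A fragment is "looped" when any of its pairs loops.
#' @param tag The tag to test.
#' @return List: \code{fold}, \code{p_value}, \code{n_tag},
#'   \code{n_looped_tag}.
#' @export
loop_fold_enrichment <- function(tagged, loops, tag) {
  if (!all(loops$distal %in% tagged$fragment)) {
    stop("loop table references fragments missing from the tagged set")
  }
  looped_frag <- unique(loops$distal[loops$looped])
  if (length(looped_frag) == 0L) stop("no looped fragments")
  is_tag <- tagged$tag == tag
  if (!any(is_tag)) stop("no fragment carries tag '", tag, "'")
  is_looped <- tagged$fragment %in% looped_frag
  k <- sum(is_tag & is_looped)
  fold <- (k / sum(is_tag)) / (sum(is_looped) / nrow(tagged))
  p <- hypergeometric_test(N = nrow(tagged), K = sum(is_looped),
                           n = sum(is_tag), k = k, tail = "upper")
  list(fold = fold, p_value = p, n_tag = sum(is_tag), n_looped_tag = k)
}

#' Bagged Pearson correlation against sparse loop calls
#'
#' Down-samples the dominant negative class: each bag combines all positive
#' (looped) pairs with an equal-sized sample of negative pairs drawn without
#' replacement, and records the Pearson correlation of the feature against
#' the 0/1 loop indicator over the combined set. Bags in which the feature is
#' constant are recorded as missing.
#'
#' @param feature Per-pair numeric feature vector.
#' @param looped Per-pair logical loop indicator.
#' @param n_bags Number of bags (default 1000).
#' @param seed Optional RNG seed.
#' @return Object of class \code{pcc_distribution}: \code{values} (length
#'   \code{n_bags}, NA for degenerate bags), \code{mean}, \code{ci} (central
#'   95 percent interval), \code{n_positive}, \code{n_missing}.
#' @export
bagged_pcc <- function(feature, looped, n_bags = 1000, seed = NULL) {
  stopifnot(length(feature) == length(looped))
  pos <- which(looped)
  neg <- which(!looped)
  if (length(pos) < 2L) stop("need at least 2 positive (looped) pairs")
  if (length(neg) < length(pos)) stop("fewer negatives than positives")
  if (!is.null(seed)) set.seed(seed)
  np <- length(pos)
  ind <- c(rep(1, np), rep(0, np))
  vals <- vapply(seq_len(n_bags), function(b) {
    bag <- c(pos, sample(neg, np, replace = FALSE))
    x <- feature[bag]
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(x, ind)
  }, numeric(1))
  structure(list(values = vals,
                 mean = mean(vals, na.rm = TRUE),
                 ci = stats::quantile(vals, c(0.025, 0.975), na.rm = TRUE, names = FALSE),
                 n_positive = np,
                 n_missing = sum(is.na(vals)),
                 n_bags = n_bags),
            class = "pcc_distribution")
}

#' @export
print.pcc_distribution <- function(x, ...) {
  cat(sprintf("Bagged PCC over %d bags (%d positives): mean r = %.3f, 95%% interval [%.3f, %.3f]",
              x$n_bags, x$n_positive, x$mean, x$ci[1], x$ci[2]))
  if (x$n_missing) cat(sprintf("  (%d degenerate bag(s))", x$n_missing))
  cat("\n")
  invisible(x)
}
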