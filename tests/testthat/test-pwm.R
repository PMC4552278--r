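test_that("PFM construction counts bases, applies pseudocounts, and rejects bad input", {
  pfm <- build_pfm(c("AC", "AC", "AT"), pseudocount = 0)
  expect_equal(unname(pfm$counts[, 1]), c(3, 0, 0, 0))
  expect_equal(unname(pfm$counts[, 2]), c(0, 2, 0, 1))

  pfm2 <- build_pfm("AAAA", pseudocount = 0.25)
  expect_equal(unname(colSums(pfm2$counts)), rep(2, 4))

  expect_error(build_pfm(c("AC", "ACG")), "same length")
  expect_error(build_pfm(character(0)), "no sites")
  expect_warning(pfm3 <- build_pfm(c("ACGT", "ACNT", "ACGT")), "dropped")
  expect_equal(pfm3$nsites, 2L)
  expect_error(suppressWarnings(build_pfm("NNNN")), "all sites")
})

test_that("information content matches closed-form column values", {
  bg <- estimate_background()
  p1 <- pfm_from_probs(matrix(c(1, 0, 0, 0), 4, 1))
  expect_equal(as.numeric(information_content(p1, bg)), 2.0)
  p2 <- pfm_from_probs(matrix(0.25, 4, 1))
  expect_equal(as.numeric(information_content(p2, bg)), 0.0)
  p3 <- pfm_from_probs(matrix(c(0.5, 0.5, 0, 0), 4, 1))
  expect_equal(as.numeric(information_content(p3, bg)), 1.0)

  # informative flag marks the high-IC columns
  p4 <- pfm_from_probs(cbind(c(1, 0, 0, 0), c(1, 0, 0, 0),
                             matrix(0.25, 4, 6)))
  inf <- attr(information_content(p4, bg), "informative")
  expect_true(all(inf[1:2]))
  expect_false(any(inf[3:8]))
})

test_that("best_hit finds the maximal window on either strand with tie rules", {
  bg <- estimate_background()
  pfm <- build_pfm(c("AC"), pseudocount = 1e-6)
  h <- best_hit(pfm, bg, "GGAC")
  expect_equal(h$offset, 2L)
  expect_equal(h$strand, "+")
  expect_equal(h$score, 4.0, tolerance = 1e-4) # 2 * log2(1/0.25)

  h2 <- best_hit(pfm, bg, "GTGG") # revcomp contains AC
  expect_equal(h2$strand, "-")
  expect_equal(h2$score, 4.0, tolerance = 1e-4)

  # N windows score -Inf and never beat a finite window
  h3 <- best_hit(pfm, bg, "NNAC")
  expect_equal(h3$offset, 2L)
  expect_true(is.finite(h3$score))

  expect_error(best_hit(pfm, bg, "A"), "shorter")

  # strand symmetry of the best score
  set.seed(7)
  pfm4 <- random_pfm(6)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(best_hit(pfm4, bg, s)$score, best_hit(pfm4, bg, rc)$score,
                 tolerance = 1e-10)
  }
})

test_that("DP score p-values equal exhaustive enumeration and are monotone", {
  bg <- estimate_background()
  # the AC-consensus dinucleotide case: top score has mass 1/16
  pfm <- build_pfm("AC", pseudocount = 1e-6)
  expect_equal(score_pvalue(pfm, bg, 4.0), 1 / 16, tolerance = 1e-6)

  skew <- c(A = 0.4, C = 0.1, G = 0.2, T = 0.3)
  set.seed(11)
  for (W in 4:6) {
    for (bgi in list(bg, skew)) {
      pfm <- random_pfm(W, nsites = 12)
      oracle <- enum_pvalue_oracle(pfm, bgi)
      lo <- log2(sweep(pfm_probs(pfm), 1, bgi, "/"))
      scores <- sort(unique(c(sum(apply(lo, 2, min)), sum(apply(lo, 2, max)),
                              replicate(20, sum(lo[cbind(sample(4, W, TRUE), 1:W)])))))
      for (s in scores) {
        expect_equal(score_pvalue(pfm, bgi, s), oracle(s), tolerance = 1e-9)
      }
      # monotone non-increasing in score
      ps <- score_pvalue(pfm, bgi, scores)
      expect_true(all(diff(ps) <= 1e-12))
    }
  }

  # clamping below/above the achievable range
  pfm <- random_pfm(4)
  expect_equal(score_pvalue(pfm, bg, -1e6), 1)
  expect_equal(score_pvalue(pfm, bg, 1e6), 0)
})

test_that("exclusive assignment picks the smallest p-value with discovery-order ties", {
  bg <- estimate_background()
  mA <- list(label = "A", pfm = build_pfm(rep("ACGTACGTAC", 5), pseudocount = 0.25), bg = bg)
  mB <- list(label = "B", pfm = build_pfm(rep("GGGGGCCCCC", 5), pseudocount = 0.25), bg = bg)
  seq_a <- paste0("TTTT", "ACGTACGTAC", "TTTT")
  res <- assign_best_motif(seq_a, list(mA, mB), p_threshold = 1e-2)
  expect_equal(res$label, "A")

  res2 <- assign_best_motif("TTTTTTTTTTTTTTTTTT", list(mA, mB), p_threshold = 1e-6)
  expect_equal(res2$label, "unassigned")

  # identical motifs: earlier in the list wins the tie
  res3 <- assign_best_motif(seq_a, list(mA, modifyList(mA, list(label = "A2"))),
                            p_threshold = 1e-2)
  expect_equal(res3$label, "A")
})

test_that("MEME minimal format round-trips motifs", {
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  motifs <- list(
    list(label = "motif_A", pfm = build_pfm(rep("ACGTACGT", 10)), bg = bg, e_value = 1e-20),
    list(label = "motif_B", pfm = build_pfm(rep("GGGGCCCC", 8)), bg = bg, e_value = 1e-5)
  )
  f <- withr::local_tempfile(fileext = ".meme.txt")
  write_meme(motifs, f)
  back <- read_meme(f)
  expect_length(back, 2L)
  expect_equal(back[[1]]$label, "motif_A")
  expect_equal(back[[2]]$e_value, 1e-5)
  expect_equal(unname(back[[1]]$bg), unname(bg), tolerance = 1e-4)
  expect_equal(pfm_probs(back[[1]]$pfm), pfm_probs(motifs[[1]]$pfm), tolerance = 1e-5)
  expect_equal(pfm_consensus(back[[2]]$pfm), pfm_consensus(motifs[[2]]$pfm))
})
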