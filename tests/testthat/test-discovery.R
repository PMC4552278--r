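# small single-motif pool used by several blocks
small_pool <- function(n = 150, len = 100, consensus = c(class_1 = "ACGTTAGCACG"),
                       prop = 0.7, mut = 0.05, seed = 5) {
  simulate_motif_pool(n_sequences = n, length = len, consensus = consensus,
                      proportions = prop, mutation_rate = mut, seed = seed)
}

test_that("seeding finds the planted k-mer and breaks ties lexicographically", {
  set.seed(3)
  sim <- small_pool(n = 100, consensus = c(x = "ACGTACGA"), prop = 1, mut = 0)
  sp <- seed_motif(sim$sequences, width = 11, k = 8)
  expect_equal(attr(sp, "seed_kmer"), "ACGTACGA")
  expect_true(grepl("ACGTACGA", pfm_consensus(sp)))
  expect_true(attr(sp, "n_seeds_tested") > 0)

  # determinism on a pure iid pool: same pool, same seed k-mer
  set.seed(9)
  iid <- simulate_motif_pool(50, 60, proportions = 0, consensus = c(x = "ACGTACGA"),
                             seed = 2)
  s1 <- seed_motif(iid$sequences, width = 11, k = 6)
  s2 <- seed_motif(iid$sequences, width = 11, k = 6)
  expect_identical(attr(s1, "seed_kmer"), attr(s2, "seed_kmer"))
  expect_error(seed_motif(Biostrings::DNAStringSet("ACG"), width = 11, k = 8),
               "shorter")
})

test_that("EM refinement is a near fixed point at the truth and its log-likelihood never decreases", {
  sim <- small_pool(n = 120, prop = 1, mut = 0.05, seed = 7)
  truth <- pfm_from_probs(sim$true_pfms[[1]])
  bg <- estimate_background()
  ref <- em_refine(truth, sim$sequences, bg = bg, em_max_iter = 30)
  # converges to the sample realisation of the planted matrix
  expect_lt(max(abs(pfm_probs(ref) - pfm_probs(truth))), 0.08)
  ll <- attr(ref, "loglik")
  expect_true(all(diff(ll) > -1e-6))

  # em_max_iter = 0 is the identity
  expect_identical(em_refine(truth, sim$sequences, em_max_iter = 0), truth)

  # monotone log-likelihood from a cold start too
  seed0 <- seed_motif(sim$sequences, width = 11, k = 6, bg = bg)
  ref2 <- em_refine(seed0, sim$sequences, bg = bg, em_max_iter = 25)
  expect_true(all(diff(attr(ref2, "loglik")) > -1e-6))
})

test_that("sequence elimination partitions the pool and recovers planted membership", {
  sim <- simulate_motif_pool(100, 100, consensus = c(x = "ACGTTAGCACG"),
                             proportions = 0.6, mutation_rate = 0.02, seed = 13)
  truth <- pfm_from_probs(sim$true_pfms[[1]], nsites = 60)
  el <- eliminate_sequences(truth, sim$sequences, p_assign = 1e-4)
  expect_setequal(c(el$assigned$id, el$remaining), names(sim$sequences))
  expect_length(intersect(el$assigned$id, el$remaining), 0L)

  planted <- sim$truth$id[sim$truth$class != "background"]
  recall <- mean(planted %in% el$assigned$id)
  fp <- mean(setdiff(names(sim$sequences), planted) %in% el$assigned$id)
  expect_gte(recall, 0.95)
  expect_lte(fp, 0.05)

  # threshold extremes
  expect_length(eliminate_sequences(truth, sim$sequences, p_assign = 1)$remaining, 0L)
  expect_equal(nrow(eliminate_sequences(truth, sim$sequences, p_assign = 0)$assigned), 0L)
})

test_that("motif updating recounts sites, is idempotent, and enforces the support minimum", {
  sites <- rep("ACGTACGTACG", 25)
  upd <- update_motif(sites, min_assigned = 20)
  expect_equal(pfm_consensus(upd), "ACGTACGTACG")
  expect_gt(min(pfm_probs(upd)[cbind(match(strsplit(sites[1], "")[[1]], c("A","C","G","T")), 1:11)]), 0.95)
  expect_null(update_motif(sites[1:10], min_assigned = 20))
  # idempotence: recounting the same sites gives the same matrix
  expect_equal(update_motif(sites, min_assigned = 20), upd)
})

test_that("motif evaluation: background motif scores E = n_seeds, significance grows with lambda", {
  bg <- estimate_background()
  # f == b: lambda 0, p 1, e = n_seeds_tested
  unif <- pfm_from_probs(matrix(0.25, 4, 8))
  sites <- vapply(1:30, function(i) paste(sample(c("A","C","G","T"), 8, TRUE), collapse = ""), "")
  ev <- evaluate_motif(unif, sites, bg, n_seeds_tested = 100)
  expect_equal(ev$lambda, 0, tolerance = 1e-9)
  expect_equal(ev$p_value, 1)
  expect_equal(ev$e_value, 100)

  strong <- evaluate_motif(build_pfm(rep("ACGTACGT", 30)), rep("ACGTACGT", 30),
                           bg, n_seeds_tested = 100)
  expect_lt(strong$log10_e, ev$log10_e)
  expect_equal(evaluate_motif(unif, character(0), bg)$e_value, Inf)
})

test_that("discovery on a single planted motif returns one motif and a clean partition", {
  sim <- small_pool(n = 200, prop = 1, mut = 0.05, seed = 21)
  fit <- discover_motifs(sim$sequences, width = 11, seed_k = 6, seed = 21)
  expect_s3_class(fit, "motif_discovery")
  expect_length(fit$motifs, 1L)
  expect_gte(mean(fit$partition$motif == "motif_A"), 0.95)
  expect_lt(mean(fit$partition$motif == "unassigned"), 0.05)
  expect_gte(match_motifs_to_truth(fit, sim)$correlation, 0.9)

  # partition property: every sequence exactly once
  expect_setequal(fit$partition$id, names(sim$sequences))
  expect_equal(anyDuplicated(fit$partition$id), 0L)
})

test_that("discovery is deterministic and controls false positives on iid pools", {
  sim <- small_pool(n = 150, seed = 31)
  f1 <- discover_motifs(sim$sequences, width = 11, seed_k = 6, seed = 4)
  f2 <- discover_motifs(sim$sequences, width = 11, seed_k = 6, seed = 4)
  expect_equal(coef(f1), coef(f2))
  expect_identical(f1$partition, f2$partition)

  iid <- simulate_motif_pool(120, 100, proportions = c(0, 0, 0), seed = 8)
  f0 <- discover_motifs(iid$sequences, width = 11, seed_k = 6, e_max = 1e-10, seed = 8)
  expect_length(f0$motifs, 0L)
  expect_true(all(f0$partition$motif == "unassigned"))
  expect_error(discover_motifs(character(0)), "empty")
})

test_that("S3 methods expose the fit: print, summary, coef, predict, plot", {
  sim <- small_pool(n = 150, prop = 0.8, seed = 41)
  fit <- discover_motifs(sim$sequences, width = 11, seed_k = 6, seed = 41)
  expect_output(print(fit), "Motif discovery fit")
  s <- summary(fit)
  expect_s3_class(s, "summary.motif_discovery")
  expect_output(print(s), "Discovered motifs")
  expect_equal(sum(s$assignment), 150)

  cf <- coef(fit)
  expect_true(all(vapply(cf, function(m) all(abs(colSums(m) - 1) < 1e-9), TRUE)))

  pred <- predict(fit, sim$sequences[1:20])
  expect_equal(nrow(pred), 20L)
  expect_true(all(pred$motif %in% c("motif_A", "unassigned")))
  # predictions agree with the fit's own partition on its training pool
  expect_gte(mean(pred$motif == fit$partition$motif[1:20]), 0.9)

  pf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(pf)
  expect_silent(plot(fit))
  grDevices::dev.off()
  expect_true(file.exists(pf))
})
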