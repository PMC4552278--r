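test_that("the planted pool respects proportions, determinism, and exact planting at zero mutation", {
  sim <- simulate_motif_pool(n_sequences = 1000, seed = 3)
  counts <- table(sim$truth$class)
  # class counts within 3 binomial sd of expectation
  for (cl in c("class_1", "class_2", "class_3")) {
    p <- c(class_1 = 0.5, class_2 = 0.3, class_3 = 0.15)[[cl]]
    expect_lt(abs(counts[[cl]] - 1000 * p), 3 * sqrt(1000 * p * (1 - p)) + 1)
  }
  expect_true(all(Biostrings::width(sim$sequences) == 200))

  # byte-identical reproduction under the same seed
  sim2 <- simulate_motif_pool(n_sequences = 50, seed = 9)
  sim3 <- simulate_motif_pool(n_sequences = 50, seed = 9)
  expect_identical(as.character(sim2$sequences), as.character(sim3$sequences))
  expect_identical(sim2$truth, sim3$truth)

  # zero mutation: every planted window equals its consensus (given strand)
  sim0 <- simulate_motif_pool(n_sequences = 60, mutation_rate = 0, seed = 5)
  cons <- default_consensus_trio()
  planted <- sim0$truth[sim0$truth$class != "background", ]
  for (i in seq_len(nrow(planted))) {
    s <- as.character(sim0$sequences[[planted$id[i]]])
    w <- substr(s, planted$offset[i] + 1, planted$offset[i] + 19)
    expected <- cons[[planted$class[i]]]
    if (planted$strand[i] == "-") {
      expected <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(expected)))
    }
    expect_equal(w, expected)
  }

  expect_error(simulate_motif_pool(10, length = 10), "longer")
})

test_that("simulated pools round-trip through FASTA without warnings", {
  sim <- simulate_motif_pool(n_sequences = 20, seed = 2)
  f <- withr::local_tempfile(fileext = ".fa")
  expect_no_warning(write_fasta(sim$sequences, f))
  expect_no_warning(back <- read_fasta(f))
  expect_identical(as.character(back), as.character(sim$sequences))
})

test_that("signal fixture: flat input, class-specific bumps, determinism", {
  sites <- simulate_binding_sites(n_sites = 60, seed = 4)
  sizes <- attr(sites, "chrom_sizes")
  tracks <- simulate_signal_tracks(sites, sizes, baseline = 1, noise_sd = 0, seed = 4)
  expect_named(tracks, c("mark_active", "input"))
  expect_true(all(tracks$input$score == 1))

  sm_a <- bin_signal(sites[sites$class == "class_1"], tracks$mark_active, sizes)
  sm_c <- bin_signal(sites[sites$class == "class_3"], tracks$mark_active, sizes)
  ctrl <- control_profile(sites, tracks$input, sizes)
  central <- abs(sm_a$offsets) <= 100
  fe_a <- fold_enrichment(sm_a, ctrl)
  fe_c <- fold_enrichment(sm_c, ctrl)
  expect_gt(mean(fe_a[, central]), mean(fe_c[, central]) + 1)
  # far flanks are near baseline for everyone
  far <- abs(sm_a$offsets) > 1200
  expect_lt(abs(mean(fe_a[, far]) - 1), 0.2)

  # amplitude 0 gives fold 1 everywhere
  flat <- simulate_signal_tracks(sites, sizes, noise_sd = 0, seed = 4,
                                 marks = list(m = list(class = "class_1",
                                                       amplitude = 0, sigma = 150)))
  fe0 <- fold_enrichment(bin_signal(sites, flat$m, sizes), control_profile(sites, flat$input, sizes))
  expect_true(all(abs(fe0 - 1) < 1e-9))

  t1 <- simulate_signal_tracks(sites, sizes, seed = 6)
  t2 <- simulate_signal_tracks(sites, sizes, seed = 6)
  expect_identical(t1$mark_active$score, t2$mark_active$score)

  # emitted tracks survive a bedGraph round trip
  f <- withr::local_tempfile(fileext = ".bedGraph")
  expect_no_warning(write_bedgraph(tracks$mark_active, f))
  expect_no_warning(back <- read_bedgraph(f))
  expect_equal(back$score, tracks$mark_active$score, tolerance = 1e-6)
})

test_that("methylation fixture carries the designed class contrasts and correlations", {
  sites <- simulate_binding_sites(n_sites = 1000, seed = 8)
  fx <- simulate_methylation_fixture(sites, seed = 8)

  # CpG coverage ratio class_1 vs class_3 approximately 5
  t1 <- mean(fx$truth$has_cpg[fx$truth$class == "class_1"])
  t3 <- mean(fx$truth$has_cpg[fx$truth$class == "class_3"])
  expect_gt(t1 / t3, 2.5)

  # correlation between level and read count near the -0.5 target
  ok <- fx$truth$has_cpg
  r <- cor(fx$truth$level[ok], fx$truth$read_count[ok])
  expect_lt(abs(r - (-0.5)), 0.12)

  # methylated sites get cohesin at about half the rate
  occ_m <- mean(fx$truth$cohesin_bound[fx$truth$methyl_class == "methylated"])
  occ_u <- mean(fx$truth$cohesin_bound[fx$truth$methyl_class == "unmethylated"])
  expect_lt(occ_m, occ_u)

  # fixture files parse cleanly through the package readers
  mf <- withr::local_tempfile(fileext = ".tsv")
  expect_no_warning(write_methylation(fx$meth, mf))
  expect_no_warning(m <- read_methylation(mf))
  expect_equal(nrow(m), nrow(fx$meth))

  # pipeline recovers the planted level at the 12th position
  lv <- methylation_at_position(sites, fx$meth, 12)
  expect_equal(!is.na(lv), fx$truth$has_cpg)
  expect_equal(lv[fx$truth$has_cpg], fx$truth$level[fx$truth$has_cpg], tolerance = 1e-9)

  # read counts recovered by binding_intensity match the truth
  counts <- binding_intensity(sites, fx$reads, flank = 100)
  expect_equal(counts, fx$truth$read_count)

  # determinism
  fx2 <- simulate_methylation_fixture(sites, seed = 8)
  expect_identical(fx$truth, fx2$truth)
})

test_that("loop fixture hits the sparsity target and tags modulate loop rates", {
  fx <- simulate_loop_fixture(n_tss = 50, n_distal = 1000, tag_effect = 1, seed = 3)
  n_pairs <- nrow(fx$loops)
  expect_equal(n_pairs, 50000L)
  # 1.2% positive rate within 3 binomial sd
  expect_lt(abs(sum(fx$loops$looped) - 600), 3 * sqrt(50000 * 0.012 * 0.988))

  # null: loop rate independent of fragment class
  rate_by_class <- tapply(fx$loops$looped, fx$truth$class[match(fx$loops$distal, fx$truth$fragment)], mean)
  expect_lt(max(rate_by_class) / min(rate_by_class), 2)

  # effect: target class rate multiplied
  fx2 <- simulate_loop_fixture(n_tss = 50, n_distal = 1000, tag_effect = 3, seed = 3)
  rate2 <- tapply(fx2$loops$looped, fx2$truth$class[match(fx2$loops$distal, fx2$truth$fragment)], mean)
  expect_gt(rate2[["class_1"]] / rate2[["class_3"]], 1.8)

  # determinism and file round trip
  fx3 <- simulate_loop_fixture(n_tss = 50, n_distal = 1000, tag_effect = 1, seed = 3)
  expect_identical(fx$loops, fx3$loops)
  lf <- withr::local_tempfile(fileext = ".tsv")
  expect_no_warning(write_loops(fx$loops, lf))
  expect_no_warning(back <- read_loops(lf))
  expect_equal(sum(back$looped), sum(fx$loops$looped))
})
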