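test_that("CpG position coverage counts strand-oriented relative positions", {
  # three + strand sites of width 19 centred at 0-based 1009 (start0 1000)
  sites <- gri("chrS", c(1000, 2000, 3000), c(1019, 2019, 3019), strand = "+")
  # CpG at motif position 12 for all three sites: C at 0-based start0 + 11
  meth <- data.frame(chrom = "chrS", pos = c(1012, 2012, 3012), # 1-based
                     level = 0.5, coverage = 10)
  cov <- cpg_position_coverage(sites, meth, flank = 50)
  expect_length(cov, 101L)
  # relative position of the C: (start0+11) - center0 = 11 - 9 = 2
  expect_equal(unname(cov["2"]), 100)
  expect_equal(sum(cov > 0), 1L)

  # half the sites -> 50%
  cov2 <- cpg_position_coverage(sites, meth[1:2, ], flank = 50)
  expect_equal(unname(cov2["2"]), 100 * 2 / 3, tolerance = 1e-9)

  # minus-strand site: orientation flips
  sm <- gri("chrS", 1000, 1019, strand = "-")
  covm <- cpg_position_coverage(sm, meth[1, , drop = FALSE], flank = 50)
  expect_equal(unname(covm["-2"]), 100)

  expect_equal(sum(cpg_position_coverage(sites, meth[0, ], flank = 50)), 0)
  expect_error(cpg_position_coverage(sites[0], meth), "empty")
})

test_that("12th-position methylation averages the two strands and handles missing records", {
  site <- gri("chrS", 1000, 1019, strand = "+") # width 19
  # motif-strand C at 1-based 1001+11 = 1012; opposite-strand C at 1013
  both <- data.frame(chrom = "chrS", pos = c(1012, 1013), level = c(0.6, 0.8),
                     coverage = 10)
  expect_equal(methylation_at_position(site, both, 12), 0.7)
  expect_equal(methylation_at_position(site, both[1, ], 12), 0.6)
  expect_true(is.na(methylation_at_position(site, both[0, ], 12)))

  # minus strand: C at end - 11 = 1008, pair at 1007
  sitem <- gri("chrS", 1000, 1019, strand = "-")
  minus <- data.frame(chrom = "chrS", pos = c(1008, 1007), level = c(0.2, 0.4),
                      coverage = 10)
  expect_equal(methylation_at_position(sitem, minus, 12), 0.3)
  expect_error(methylation_at_position(site, both, 25), "outside")
})

test_that("methylation classification uses the strict 20% threshold", {
  expect_equal(classify_methylation(c(0.25, 0.20, 0.0, NA)),
               c("methylated", "unmethylated", "unmethylated", "unknown"))
  # monotone threshold function
  lv <- seq(0, 1, 0.01)
  cl <- classify_methylation(lv)
  expect_true(all(diff(cl == "methylated") >= 0))
})

test_that("cohesin sites are the symmetric subunit intersection", {
  r <- gri("chr1", 10, 30)
  s <- gri("chr1", 20, 40)
  cs <- cohesin_sites(r, s)
  expect_equal(GenomicRanges::start(cs), 21L) # [20,30) 0-based
  expect_equal(GenomicRanges::end(cs), 30L)
  expect_equal(cohesin_sites(r, s), cohesin_sites(s, r))
  expect_length(cohesin_sites(gri("chr1", 0, 10), gri("chr1", 50, 60)), 0L)
  # nested peaks give the inner interval
  inner <- cohesin_sites(gri("chr1", 0, 100), gri("chr1", 40, 60))
  expect_equal(GenomicRanges::start(inner), 41L)
  expect_equal(GenomicRanges::end(inner), 60L)
})

test_that("cohesin depletion test reproduces exact lower-tail pmf sums", {
  # N=100 sites, K=50 cohesin-overlapped, n=20 methylated, k=2 overlapped
  all_sites <- gri("chr1", s <- seq(0, 99000, 1000), s + 100)
  cohesin <- gri("chr1", s[1:50] + 10, s[1:50] + 50) # first 50 overlapped
  meth_sites <- all_sites[c(1, 2, 51:68)] # 2 overlapped among 20
  res <- cohesin_depletion_test(all_sites, meth_sites, cohesin)
  expect_equal(res$coverage_all, 50)
  expect_equal(res$coverage_methylated, 10)
  expect_equal(res$p_value, sum(dhyper(0:2, 50, 50, 20))) # exact oracle
  expect_lt(res$p_value, 0.05)

  # null behaviour: methylated coverage equal to overall is not depleted
  null_meth <- all_sites[c(1:10, 51:60)]
  res0 <- cohesin_depletion_test(all_sites, null_meth, cohesin)
  expect_gte(res0$p_value, 0.5)
  expect_error(cohesin_depletion_test(all_sites, all_sites[0], cohesin), "empty")
})

test_that("methylation-signal correlation recovers the sign with a calibrated bootstrap", {
  # perfect anti-correlation: r = -1, p at its smoothed floor
  lv <- seq(0.1, 0.9, length.out = 50)
  res <- methylation_signal_correlation(lv, -lv, n_boot = 200, seed = 1)
  expect_equal(res$r, -1)
  expect_equal(res$p_value, 1 / 201)

  # independent pairs: |r| small, p not extreme
  set.seed(4)
  a <- rnorm(200); b <- rnorm(200)
  res2 <- methylation_signal_correlation(a, b, n_boot = 200, seed = 2)
  expect_lt(abs(res2$r), 0.2)

  expect_error(methylation_signal_correlation(rep(0.5, 10), rnorm(10)), "constant")
  expect_error(methylation_signal_correlation(c(0.1, 0.2), c(1, 2)), "fewer than 3")
})

test_that("unbound-control selection takes confident motifs below the signal quantile", {
  hits <- gri("chr1", s <- seq(0, 99000, 1000), s + 19, p_value = 1e-6)
  signal <- 1:100
  sel <- select_unbound_control_loci(hits, signal, quantile = 0.05)
  expect_true(all(signal[seq_along(hits) %in% match(GenomicRanges::start(sel), GenomicRanges::start(hits))] <
                    quantile(signal, 0.05)))
  expect_equal(length(sel), sum(signal < quantile(signal, 0.05)))

  # all-equal signal: nothing strictly below the quantile
  expect_length(select_unbound_control_loci(hits, rep(5, 100)), 0L)
  # unconfident hits are excluded even at low signal
  hits2 <- hits; hits2$p_value <- 1e-2
  expect_length(select_unbound_control_loci(hits2, signal), 0L)
  expect_length(select_unbound_control_loci(hits[0], numeric(0)), 0L)
})

test_that("binding intensity counts 5' read ends in the half-open window", {
  site <- gri("chrS", 5000, 5019) # center0 = 5009
  # + strand reads: 5' end = start
  inside <- gri("chrS", c(4909, 5000, 5108), c(4909, 5000, 5108) + 36, strand = "+")
  at_edge <- gri("chrS", 5109, 5150, strand = "+") # 5' at center+100: excluded
  below <- gri("chrS", 4908, 4950, strand = "+") # 5' at center-101: excluded
  reads <- c(inside, at_edge, below)
  expect_equal(binding_intensity(site, reads, flank = 100), 3L)
  # minus-strand read: 5' end is the right edge
  minus_in <- gri("chrS", 5050, 5100, strand = "-") # 5' at 5100 - inside
  expect_equal(binding_intensity(site, minus_in, flank = 100), 1L)
  expect_equal(binding_intensity(site, reads[0], flank = 100), 0L)
})
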