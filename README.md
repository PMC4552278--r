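# motifdiv

Discovery and functional profiling of divergent DNA binding motifs.

Proteins such as CTCF bind a family of related sequence variants with
different regulatory roles. Fitting one position weight matrix to all
ChIP-seq peak sequences blurs those variants together. `motifdiv` discovers
**multiple motifs over mutually exclusive subsets** of a pooled sequence
set: the most over-represented k-mer seeds a width-19 matrix, ZOOPS
expectation–maximisation refines it, sequences whose best hit passes an
exact p-value threshold are assigned to the motif and removed, the motif is
recounted from its sites, and the loop repeats on the remainder until the
pool is exhausted or a candidate fails its E-value test. Scan p-values are
exact: the null score distribution of a background W-mer is computed by
dynamic programming at 1/1000-bit granularity. Motif significance combines
a chi-squared likelihood-ratio statistic (Lambda = 2 Σ n<sub>bj</sub>
ln(f<sub>bj</sub>/b<sub>b</sub>), 3W df) with Bonferroni-style corrections
for the seeds examined and the possible site alignments.

Around the discovery engine sit the quantification tools used to
characterise motif classes:

* binned signal fold-enrichment S<sub>ij</sub>/C<sub>j</sub> around sites
  (±1500 bp in 150 bins of 20 bp, Input-controlled);
* colocalization fold P<sub>i</sub>/C<sub>i</sub> against filtered control
  peaks, with exact hypergeometric tests;
* gene linking to the nearest labeled site within ±50 kb, strand-aware
  promoter classification;
* CpG coverage and methylation level at motif positions (the 12th position
  in particular), methylated/unmethylated classification at the strict 20%
  threshold, cohesin (Rad21 ∩ SMC3) depletion tests, and read-count
  correlations with bootstrap significance;
* a bagged Pearson-correlation procedure for sparse chromatin-loop calls
  (all positives + equal-sized negative subsamples, 1000 bags);
* seeded synthetic-data generators with ground truth for every input class,
  so the whole pipeline runs and is tested fully offline.

## Worked example

```r
library(motifdiv)

sim <- simulate_motif_pool(n_sequences = 1000, seed = 7) # 3 planted classes + background
fit <- discover_motifs(sim$sequences, width = 19, seed = 7)
fit
#> Motif discovery fit: 3 motif(s) over 1000 sequences
#>   motif_A  width 19  n=515  log10(E)=-2639.6  q=0  consensus TGCCACCTAGGTGGCAGAT
#>   motif_B  width 19  n=289  log10(E)=-1470.6  q=0  consensus CGATTGCGTAAGCTCGAAT
#>   motif_C  width 19  n=149  log10(E)=-758.5   q=0  consensus GGACTATGTCGTCCAATGC
#>   unassigned: 47 (4.7%)  [stop: min_remaining]

predict(fit, sim$sequences[1:3])
#>        id      motif offset strand      p_value
#> 1 seq0001 unassigned     NA   <NA>           NA
#> 2 seq0002    motif_A    167      - 3.693770e-12
#> 3 seq0003    motif_A     96      + 8.923952e-08
```

The three planted classes (50/30/15% of the pool, per-position mutation
rate 0.1) are recovered in abundance order with their consensus sequences
intact (motif_B is the reverse complement of its planted consensus — both
strands are scanned throughout); the background remainder stays unassigned
and stops the loop. `coef(fit)` returns the probability matrices,
`plot(fit)` the per-column information content, `summary(fit)` the
partition table, and `write_meme()` serialises the motifs for use with
external scanners. A thin command-line wrapper (`inst/cli/motifdiv.R`)
exposes `discover`, `scan`, `simulate`, and `run` (the composed pipeline
driven by a YAML config).

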