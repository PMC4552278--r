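---
title: "Divergent motif discovery and downstream quantification: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergent motif discovery and downstream quantification: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Many DNA-binding proteins — CTCF is the motivating example — recognise a
family of related but functionally distinct sequence variants. A single
position weight matrix fit to all ChIP-seq peak sequences averages those
variants away. `motifdiv` instead discovers several motifs, each describing a
*mutually exclusive* subset of the pooled sequences: once a motif claims a
sequence, that sequence leaves the pool, and the next motif is sought in the
remainder. The package couples this discovery engine to the quantification
steps used to characterise motif classes: binned signal fold-enrichment
around sites, colocalization enrichment against control peaks, CpG coverage
and methylation at motif positions (the 12th position being the
biologically loaded one for CTCF), cohesin depletion tests, and a bagged
Pearson-correlation procedure for very sparse chromatin-loop calls.

## The discovery model

`discover_motifs()` iterates five steps on a shrinking pool:

1. **Motif generation.** The most over-represented k-mer (k = 8 by default,
   counted on both strands and ranked against its background expectation;
   lexicographic tie-break) seeds a width-W matrix (W = 19 by default,
   matching the CTCF core logo span) which is refined by
   zero-or-one-occurrence-per-sequence (ZOOPS) expectation–maximisation on
   both strands. The EM M-step uses a Dirichlet pseudocount (0.25 per base
   per column), so the quantity that ascends monotonically — and that the
   package records — is the penalized log-likelihood, not the bare one.
2. **Frame refinement.** The seed fixes an arbitrary frame inside the W
   window; the motif is slid over its assigned sites and the shift with the
   highest mean per-site log-likelihood ratio wins (shift 0 on ties). Without
   this step a recovered motif is typically a few columns out of register
   with the planted/biological one, wasting informative columns.
3. **Sequence elimination.** A sequence is assigned if its best-hit p-value
   passes `p_assign` (default 1e-4). Best-hit p-values are *exact*: the
   log2-odds score distribution of a background W-mer is computed by dynamic
   programming at 1/1000-bit granularity, so the discretisation error is far
   below any threshold in use.
4. **Motif updating.** The accepted motif is recounted from the best-site
   windows of its assigned sequences, replacing the EM estimate. Motifs with
   fewer than `min_assigned` (20) supporting sequences are rejected.
5. **Stopping.** The loop ends when the remainder falls below `min_remaining`
   (5%) of the initial pool, when the candidate's E-value exceeds `e_max`
   (1e-5), or at `max_motifs`.

**Motif significance.** The evaluation statistic is the likelihood ratio
Lambda = 2 Σ n~bj~ ln(f~bj~ / b~b~) over assigned-site counts, referred to an
upper chi-squared tail with 3W degrees of freedom. A Bonferroni factor over
the seed candidates examined is not sufficient: the EM stage can overfit a
small background remainder and produce a motif whose Lambda looks
astronomically significant (we observed E ≈ 1e-52 for a motif assembled from
~20 random sequences). The E-value therefore also carries an alignment-count
correction — the product over assigned sequences of their scanned window
counts (both strands), the number of ways the site configuration could have
been chosen. All of this is carried in log space; with it, planted motifs
score log10(E) in the hundreds of negative orders while background-derived
candidates land far above any acceptance threshold. Motif q-values are
Benjamini–Hochberg adjusted over all candidates evaluated within one run;
that family choice is the package's own, since per-run candidates are the
only family available without a genome-wide null.

A candidate whose probability matrix correlates at 0.9 or more with an
earlier motif (forward or reverse-complement orientation) is merged into
that motif rather than reported twice; with both-strand scanning this mainly
catches reverse-complement rediscoveries.

Assignment of new sequences or fragments (`predict()`, `tag_fragments()`,
`assign_best_motif()`) is by smallest best-hit p-value passing the
threshold, ties to the earlier motif in discovery order.

## Coordinates and containers

Externally everything speaks BED conventions (0-based half-open); internally
the package uses `GRanges` (1-based closed), the Bioconductor idiom, with the
conversion confined to the I/O layer. Motif positions reported to users are
1-based ("the 12th position"). Window centring uses the floor midpoint of an
interval, and out-of-bounds flanking windows drop the site (with a warning)
rather than truncate, so signal matrices stay rectangular. Signal input is
bedGraph rather than bigwig so that all inputs remain plain text.

## Downstream statistics

* **Signal fold-enrichment** S~ij~/C~j~: sites × bins matrix of mean track
  signal over ±1500 bp windows in 150 bins of 20 bp, divided by the per-bin
  Input strength. Bin signal is a mean, not a sum, so changing the bin width
  does not rescale the enrichment. C~j~ is *site-matched* (the Input binned
  over the same windows): the formula indexes the control by bin only, and
  the site-matched reading is the one that makes the division well-typed;
  bins with zero control are masked, never infinite.
* **Colocalization** P~i~/C~i~: percent of query sites overlapped (≥ 1 nt,
  half-open) by a feature over the percent of control regions overlapped,
  after discarding control regions that touch the query; significance by the
  exact hypergeometric tail (upper for enrichment, lower for depletion).
* **Gene linking**: each TSS takes the label of the nearest site midpoint
  within ±50 kb, ties to the smaller motif p-value then leftmost, otherwise
  "other". Promoters are strand-aware [−2500, +500] windows around the TSS
  (a [−2000, +500] variant used for chromatin-state refinement is available
  through the parameters).
* **Methylation**: the CpG at motif position p is the dinucleotide starting
  there on the motif strand; levels reported for its two cytosines are
  averaged. A site is "methylated" when the level is strictly greater than
  20%. Binding intensity counts read 5′ ends (strand-aware, avoiding
  double-counting across window edges) in ±100 bp. Cohesin is represented by
  the intersection of Rad21 and SMC3 peaks; depletion at methylated sites is
  a lower hypergeometric tail. The level/read-count association is a Pearson
  correlation with a one-sided bootstrap (resampling pairs; smoothed
  p-value).
* **Loops**: with ~1% of TSS-distal pairs looped, a single Pearson
  correlation against the 0/1 loop indicator is dominated by negatives.
  `bagged_pcc()` draws, per bag, all positives plus an equal number of
  negatives sampled without replacement (independently across bags) and
  records the per-bag point-biserial correlation — the literal reading of
  correlating a genomic element with looping. One distributional fact
  matters for calibration checks: all bags share the same positive set, so
  the mean of the bag distribution has a sampling standard deviation equal
  to the bag-to-bag standard deviation itself, *not* sd/√n_bags; treating
  bags as independent makes any null band roughly √n_bags too narrow.

## The synthetic-data generators

All tests run on generated data with recorded ground truth; nothing is
downloaded. `simulate_motif_pool()` plants exactly one mutated consensus
instance (ZOOPS-compatible) per class-assigned sequence at a uniform offset
and strand; defaults are 1000 sequences of 200 bp, class proportions
50/30/15% with a 5% background remainder, and a per-position mutation rate
of 0.1. The default consensus trio consists of three dissimilar 19-mers:
the generator emulates the *exclusive class structure* of a pooled peak set,
not the substantial mutual similarity of real CTCF variants — recovery
results on it therefore say nothing about separating highly similar motifs.
`simulate_signal_tracks()` lays Gaussian bumps (amplitude 4 × baseline,
σ = 150 bp) over one class's sites on a flat Input. The methylation fixture
places a CpG at motif position 12 with class-specific probability (0.5 /
0.25 / 0.1 — a ~5-fold first-vs-third class contrast), draws levels from a
two-component Beta mixture, halves cohesin occupancy at methylated sites
(0.25 vs 0.5), and draws read counts with a −0.5 target correlation against
the level. The loop fixture uses a 1.2% positive rate over 50 × 1000
TSS-distal pairs, optionally multiplying the rate for one class. Every
generator is deterministic given its seed.

## Problem sizes and numerical choices

The shipped test-suite sizes are the package's own choices: five seeded
replicates of the full 1000 × 200 bp three-motif benchmark, fifty seeded
methylation/cohesin fixtures of 1000 sites (200 bootstrap resamples each),
and the full 50,000-pair / 1000-bag loop calibration. The scanner's DP
p-values are validated against exhaustive enumeration of all 4^W words for
W ≤ 6, and the hypergeometric tails against a 10^6-draw urn simulation.
EM stops at a column-wise max probability change below 1e-3 or 50
iterations; degenerate inputs (N-containing windows score −∞ and never win;
constant features make a bag's correlation undefined and are reported as
missing) are handled explicitly rather than propagating NaN.

## Known limitations

Only fixed-width, zero-or-one-occurrence motifs are modelled; the background
is 0-order; scan E-values follow the per-hit p-value × windows convention.
The generators do not emulate read-level artefacts (fragment-size
distributions, PCR duplicates) or genuinely similar motif families, and the
bagged correlation treats pre-called loops as truth — loop calling itself is
out of scope.
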