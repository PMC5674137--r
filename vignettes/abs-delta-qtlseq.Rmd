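---
title: "QTL-seq with |Delta(SNP-index)| windows for heterozygous crosses"
author: "absQTLseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QTL-seq with |Delta(SNP-index)| windows for heterozygous crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(absQTLseq)
```

## The model

QTL-seq compares two DNA bulks pooled from offspring with extreme opposite
phenotypes. At a biallelic site covered by `ref` and `alt` reads in a pool,
the SNP-index is `alt/(ref + alt)`: 1 when every read differs from the
reference genome, 0 when every read matches it, missing at zero depth. The
per-site contrast between bulks is `Delta = index(A) − index(B)`, and the
genome is scanned with sliding windows (200 kb wide, 20-kb steps) holding
the arithmetic means of the per-pool indices, of Delta and of |Delta| over
the SNPs each window contains. Candidate regions are windows whose
statistic exceeds an empirical quantile of the genome-wide window
distribution — the top 0.5% for |Delta|, or the top and lowermost 0.25%
for signed Delta — merged into intervals and pruned of intervals supported
by few, widely separated SNPs.

The sign of Delta carries information only when the reference genome is one
parental haplotype. When both parents are highly heterozygous and the
reference is an unrelated cultivar, the reference's haplotype state drifts
along each chromosome relative to the parents. Wherever it switches, the
allele that counts as "alt" flips, so the per-site Delta changes sign while
|Delta| is unchanged. We follow the usage of calling this the
*pseudoexchange effect*: it mimics a recombination breakpoint that never
happened in the cross. Averaged over a window that spans one or more
switches, signed Delta cancels toward zero and true candidate windows drop
below threshold; |Delta| windows do not cancel. That asymmetry is the
entire case for the sign-free statistic, and the simulator exists to make
it measurable.

## Filters and their defaults

Three exclusion rules run before windowing, all in `FilterPolicy()`:

* `minIndex = 0.3` — sites whose SNP-index is below 0.3 are treated as
  sequencing/alignment noise. The rule is applied when **both** pools are
  below the cutoff (`indexRule = "both_pools_below"`): a site informative
  in one bulk is kept. The published description of this filter does not
  state whether it applied per pool or jointly; both-pools is the
  classical bulked-segregant reading (a site uninformative in both bulks),
  and `"either_pool_below"` is available.
* `minDepth = 7` — a site is dropped when **either** pool has total depth
  below 7 reads; again the per-pool reading is a choice we expose rather
  than hide.
* `dropIfMissingInOnePool = TRUE` — sites with no coverage in one bulk
  have no usable contrast.

Segregation-distortion screening is sometimes mentioned alongside these
filters in the literature without an operational definition; we do not
invent one, and expose only the generic depth/index rules above.

## Windows, thresholds, intervals

Window starts are `1, 1+step, 1+2·step, …` on every scaffold; windows
overhanging a scaffold end are truncated, never discarded, so short
scaffolds still contribute. Missing per-site values never enter a mean;
windows with fewer than `minSnpsPerWindow` (default 1) SNPs carry missing
statistics, and missing window statistics never enter quantiles.

Thresholds use the empirical quantile with linear interpolation
(`stats::quantile`, type 7) over windows, matching threshold lines drawn on
window plots; flagging is strict (`>` above, `<` below), so a degenerate
constant statistic flags nothing. Raising the tail mass can only lower the
upper threshold (monotonicity), which the tests assert. Realized threshold
values are data-dependent outputs, never constants: on one 10-Mb simulated
dataset the top-0.5% |Delta| threshold lands near 0.3, but it moves with
depth, pool sizes and heterozygosity.

Flagged windows merge when they overlap or abut, so interval bounds land on
the step grid (starts …0001, ends …0000 with the defaults). Two length
conventions coexist in candidate-region reporting and both are implemented
explicitly: grid-aligned regions are measured inclusively
(`end − start + 1`), marker-bounded spans as coordinate differences
(`end − start`). Every call and report states its mode, because published
tables mix the two and both arithmetics must be reproducible.

The sparse-interval filter (`SparsityPolicy()`: fewer than 10 SNPs, or a
median inter-SNP gap above 20 kb, one window step) is this package's
concrete rendering of the qualitative practice of discarding intervals
supported "by only a few, widely separated SNPs"; no numeric criteria are
published, so the defaults are ours, config-exposed, and echoed in every
report.

## The simulator and what it emulates

`CrossSimConfig()` describes a biparental F1 cross of two heterozygous
parents with a single dominant trait locus, pooled and sequenced:

| parameter | default | meaning |
|---|---|---|
| `nScaffolds`, `scaffoldLength` | 5 × 2 Mb | toy genome |
| `snpDensity` | 0.002 /bp | segregating sites (2 per kb) |
| `parentHeterozygosity` | 0.4 | P(site heterozygous) per parent |
| `recombinationRate` | 50 cM/Mb | ~100 cM genetic length per scaffold |
| `nOffspring`, `nOffspringPerPool` | 100; 28+27 | phenotyped F1s; bulk sizes |
| `meanDepth` | 20 | Poisson reads/site/pool |
| `sequencingError` | 0.005 | per-read allele error |
| `referenceMode`, `mosaicSwitchRate` | mosaic; 5 /Mb | pseudoexchange model |
| `penetrance`, `crossType` | 1; Rr × rr | dominant single-locus phenotype |

Parents are phased: each site is heterozygous with the stated probability,
otherwise homozygous for a random allele; the dominant allele is placed
heterozygously in parent A (and in parent B for `RrXRr`). Gametes follow a
Poisson crossover process at the scaffold's genetic length in Morgans.
Bulks take the first 28 carrier and 27 non-carrier offspring; read depth is
Poisson and alt counts binomial with the pool allele frequency shrunk
toward 0.5 by the sequencing error. The mosaic reference is a Markov
switching process along each scaffold between parent A's two haplotypes,
with Poisson breakpoints at `mosaicSwitchRate` per Mb — the minimal model
that flips the sign of Delta at random boundaries, which is all the
pseudoexchange argument needs.

Scale choices. The bulk sizes (28 + 27) and ~20× pooled depth mirror the
motivating pear experiment; the genome is a deliberate desk-scale stand-in.
Two of its parameters deserve justification:

* **Recombination, 50 cM/Mb.** Each 2-Mb scaffold is a scaled-down
  chromosome: its *genetic* length (~100 cM) is kept realistic while the
  physical axis is compressed. Preserving genetic length preserves the
  number of independently segregating blocks per chromosome, which is what
  controls both the background noise of window statistics and the decay of
  linkage around the locus. Using a physically realistic 3–4 cM/Mb on a
  2-Mb toy scaffold instead would make each scaffold a single 8-cM linkage
  block: the expected |Delta| would be flat along the entire scaffold and
  "localization" within it would be undefined. A toy genome must be scaled
  in map units, not base pairs.
* **SNP density, 2/kb; heterozygosity, 0.4.** Outcrossing tree genomes are
  SNP-dense and parental lines of the kind motivating this method are
  highly heterozygous; these values give windows of ~400 raw sites, enough
  that window noise is dominated by offspring sampling and read sampling
  rather than site count.

What the simulator does **not** model: alignment artifacts, mapping-quality
variation, indel realism, copy-number variation, segregation distortion
beyond the penetrance knob, overdispersed coverage, and linked selection.
Passing tests therefore show the statistics behave as designed under clean
Mendelian sampling with a mosaic reference — not that the pipeline is
robust to alignment pathology in real data.

## The power comparison

`powerExperiment()` draws replicate datasets and runs both pipelines on
each, so replicates are paired. Both methods flag the same total tail mass
(0.5%: one-tailed for |Delta|, split 0.25% + 0.25% for signed Delta),
isolating the statistic from the flagged-window budget. Detection means
some called interval covers the true locus. `pairedDetectionTest()` uses
the exact one-sided sign test on discordant pairs. Under the default
mosaic conditions the |Delta| pipeline detects the locus in nearly all
replicates while signed Delta misses a substantial fraction; under a
parental reference the two are indistinguishable — both facts are asserted
by seeded tests, not quoted from elsewhere.

## Numerical and degenerate-input choices

* SNP-index at zero depth is missing (`NA`), never 0: "no reads" and "all
  reads match the reference" are different observations.
* Multi-allelic VCF sites keep the alternate allele with the largest
  summed depth across both pools (with a message); the statistics are
  defined for biallelic contrasts. InDel records flow through the same
  index arithmetic.
* Dropped records carry exactly one reason, with precedence
  `missing_index` > `low_depth` > `low_index`.
* Exact interval lengths are returned unrounded; report writers format kb
  to one decimal. Empty inputs — no records, all records filtered, an
  all-missing window statistic — raise errors rather than returning empty
  silence.
* All randomness flows from one seed per simulated dataset;
  `simulateCross()` with equal seeds is bit-identical, and the analysis
  pipeline itself is deterministic.

## Known limitations

* Thresholding by quantile fixes the *number* of flagged windows, so the
  called candidate width is governed by the flagged mass and the merging
  geometry, not by estimation noise: increasing depth mainly buys coverage
  probability and replicate-to-replicate stability of the candidate set,
  not a narrower mean interval. In our depth sweeps (6–24×, 50 replicates
  per depth) the dispersion of candidate width shrinks strongly with depth
  while its mean stays within ~10 kb of 260 kb.
* With 28 + 27 offspring per bulk, offspring sampling noise bounds the
  precision of window statistics beyond ~30× depth; deeper sequencing
  cannot substitute for larger bulks.
* The sparse-interval defaults are heuristics; on real data they should be
  revisited against the local SNP density.
* Scaffold-to-linkage-group assignment is a join against a user-supplied
  lookup; genetic-map construction is out of scope.

## Problem sizes used by the test suite

Unit tests run on 30–400-kb toy scaffolds; the window oracle uses 1000
random SNPs over five scaffolds; the power comparisons use the default
5 × 2-Mb genome with 50 paired mosaic replicates and 25 parental
replicates; the depth sweep uses 50 replicates at each of 6×, 12× and
24×. These sizes were chosen so the full suite completes in minutes on a
single core while leaving the binomial comparisons adequately powered.
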