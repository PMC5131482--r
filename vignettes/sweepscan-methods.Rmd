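---
title: "Methods: windowed pool-seq sweep scanning with sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed pool-seq sweep scanning with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The problem

Pooled resequencing (pool-seq) sequences DNA pooled from many individuals
and yields, at each variant site, allele *read counts* per pool rather than
individual genotypes. When two pools are built from phenotypically extreme
groups of the same population — here the motivating design is two pools of
dairy goats, 20 low-fecundity and 14 high-fecundity does — regions under
recent selection in one group show a characteristic signature: loss of
heterozygosity in the selected pool together with elevated allele-frequency
differentiation between pools. `sweepscan` implements a windowed scan for
that signature and a forward simulator to validate it end to end.

## Statistics

**Pooled heterozygosity (Hp).** For each genome window and pool, every
site contributes its major and minor allele read counts
$n_{MAJ} = \max(r, a)$ and $n_{MIN} = \min(r, a)$. With
$S_{MAJ} = \sum n_{MAJ}$ and $S_{MIN} = \sum n_{MIN}$ over the window,

$$ Hp = \frac{2\, S_{MAJ}\, S_{MIN}}{(S_{MAJ} + S_{MIN})^2} . $$

Hp lies in $[0, 0.5]$, reaching 0.5 when major and minor read mass balance
and 0 when the pool is fixed at every site. Major/minor status is decided
per site *within* each pool, on read counts: counts are what pool-seq
provides, and converting to frequencies first would discard depth
information.

**Pool-Fst.** Per site, with alt-read frequencies $f_1, f_2$, within-pool
heterozygosities $h_i = 2 f_i (1 - f_i)$, $H_S = (h_1 + h_2)/2$, and
$H_T = 2 \bar f (1 - \bar f)$ at the mean frequency
$\bar f = (f_1 + f_2)/2$, the classical estimator is
$F_{ST} = (H_T - H_S) / H_T$. Windows aggregate by ratio of sums,
$\sum (H_T - H_S) / \sum H_T$, which weights sites by their information
content instead of averaging noisy per-site ratios. No pool-size or depth
bias correction is applied; the statistic is used descriptively, for
ranking windows, not for unbiased parameter estimation. Sampling noise can
push the raw window ratio slightly negative; values are clipped to
$[0, 1]$ before the Z-transform.

**Z-transforms and D-ZHp.** Hp (per pool) and Fst are Z-transformed
genome-wide — $z = (x - \bar x)/s$ with the $n-1$ sample standard
deviation — over the windows passing the minimum-SNP filter. The
differential statistic is $D\text{-}ZHp = ZHp_{pool2} - ZHp_{pool1}$
(high-fecundity minus low-fecundity in the motivating design): strongly
negative values mark windows homozygous specifically in pool 2.

**Candidate selection.** A window is a candidate for a pool when its ZHp
falls at or below the empirical lower `zhp_quantile` (default 5%: the
high-homozygosity tail) *and* its ZFst at or above the upper
`zfst_quantile` (default 5%: the high-differentiation tail). Quantiles use
linear interpolation of order statistics (`stats::quantile` type 7) and
are computed over eligible windows only. One Fst exists per window, so the
ZFst cutoff is shared between pools while the ZHp cutoff is per pool.
Candidate windows of each pool are merged into maximal intervals;
intervals overlapping (≥ 1 bp) a merged interval of the other pool are
*shared*, the remainder *unique* — merging makes a sweep spanning several
sliding windows count once. A description in terms of "top ZHp" sometimes
appears for this kind of selection; since low Hp means high homozygosity,
the lower ZHp tail is what selects swept windows, and that is the
implemented direction (configurable through the quantile arguments).

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `window_size` | 150,000 | bp | smallest size whose per-window SNP count stays comfortably above the Z-transform floor at mammalian SNP densities; `window_size_scan()` reproduces this trade-off survey |
| `step_size` | 75,000 | bp | 50% overlap localises sweep edges without doubling the multiple-testing burden |
| `min_snps` | 20 | SNPs | windows with fewer SNPs give unstable Hp/Fst and are excluded from Z-transformation and selection |
| `min_depth` | 4 | reads | site kept when depth **> 4 in every pool** (strict); per-pool, since each pool is an independent library |
| `min_qual` | 20 | phred | standard call-quality floor |
| `zhp_quantile`, `zfst_quantile` | 0.05 | — | conventional empirical-outlier tail mass |
| `flank` | 1,000 | bp | upstream/downstream annotation window, the common variant-annotator default; splicing = 2 bp into the intron |

Read-level QC (`filter_reads`) mirrors standard pre-alignment filtering:
drop a read when more than 50% of its bases have phred ≤ 5, when ≥ 10% are
N, or when its longest exact adapter match exceeds 10 nt; for paired input
the pair is dropped together. The three rules deliberately mix strict and
inclusive inequalities — they are encoded exactly as conventionally
printed, and each edge is pinned by a test. Adapter matching is
longest-exact-substring: deterministic and testable, where a banded
alignment would add parameters the scan does not need.

## Coordinates and file formats

Internally windows, genes and transcript models are 0-based half-open;
site positions are 1-based (as in sync and VCF) and converted at the
boundary: a site at 1-based `pos` is in `[start, end)` iff
`start <= pos - 1 < end`. Windows anchor at 0 on each chromosome and a
window is emitted for every start below the chromosome length, with the
terminal window truncated and flagged; truncated windows fall to the
min-SNP filter rather than being special-cased. Sync input (per-pool
`A:T:C:G:N:del` counts) keeps only biallelic SNP lines — exactly two
alleles with positive combined count, one of them the stated reference;
multiallelic, deletion-bearing, monomorphic and reference-mismatched lines
are tallied and skipped, because the Hp and Fst forms used here are
biallelic. VCF ingestion reads per-sample `FORMAT/AD` fields through
`vcfR`. Interval arithmetic (window assignment, merging, gene overlap)
uses `GenomicRanges`/`IRanges`; sequence handling and translation use
`Biostrings`.

## The simulator

`simulate_pools()` is a phenomenological forward model of the data the
scan consumes, not a population-genetic simulator:

* sites placed uniformly at 5 SNPs/kb (default) on a 30 Mb genome of
  three 10 Mb chromosomes;
* ancestral frequency $p \sim \mathrm{Beta}(0.2, 0.2)$, a U-shaped
  spectrum dominated by near-fixed sites as in real SNP catalogues;
* pool frequencies by binomial resampling of $2N$ chromosomes
  ($N = 20$ and $14$ diploids);
* inside a planted sweep interval the pool frequency moves toward the
  nearer of 0/1 by strength $s$: $f' = f(1-s)$ below 0.5, else
  $f' = f + s(1-f)$;
* read counts binomial at a Poisson per-site depth (mean 25×, matching a
  typical pool at ~25× coverage), with fixed depth available for exact
  tests;
* ref/alt pairs drawn with transition probability $2.3/(1+2.3)$ so the
  simulated ts/tv matches the ~2.3 of mammalian resequencing catalogues;
* sites with no alternate read in either pool are not emitted — they
  would not appear in a SNP call set.

Everything is a pure function of the config seed, and the caller's RNG
state is restored. What the simulator deliberately does **not** emulate:
linkage disequilibrium and recombination (sites are independent), demography,
sequencing error, mapping artefacts, or callable-genome gaps. Passing
recovery tests therefore show that the statistics and selection logic
behave as designed on data with the assumed structure — not that the scan
is robust to real-data artefacts such as repeat-driven coverage spikes.

## Recovery behaviour and a tail-mass ceiling

`recovery_experiment()` scores the full pipeline against the planted
truth: sensitivity is the fraction of planted intervals overlapped by at
least one candidate window of the swept pool; the false-positive rate is
the fraction of candidate windows overlapping no planted interval. The
validation configuration used by `scripts/acceptance.R` and the test
suite plants twenty 300 kb sweeps at $s = 0.95$ on the 30 Mb genome and
averages over 10 seeds; the same script also runs the null ($s$ absent)
calibration. These problem sizes keep a full multi-seed validation in the
order of seconds per run while leaving ~400 sliding windows, enough for
meaningful 5% tails.

Two findings from that harness are worth understanding before using the
default quantiles on data where sweeps are plentiful:

* **False positives are essentially absent** at strong $s$: every
  candidate window the intersection rule nominates overlaps a planted
  sweep (measured FPR 0), and under the null the candidate fraction stays
  well below the 5% single-tail mass (~0.3–0.7%, against 0.25% expected
  if the two tails were independent — ZHp and ZFst are mildly positively
  associated at swept-free windows).
* **Sensitivity is capped by tail mass, not by signal.** Twenty 300 kb
  intervals intersect ~120 of the ~400 sliding windows (~30%), but a
  5% × 5% quantile intersection can nominate at most ~20 windows — about
  10–12 in practice. Those nominations land almost randomly among the
  many near-tied swept windows, so the expected fraction of *intervals*
  touched plateaus around 0.4–0.5 (the harness measures ≈ 0.42) even
  though every swept window separates cleanly from the neutral
  background. This is an intrinsic property of fixed-quantile outlier
  selection whenever the truly swept fraction of the genome exceeds the
  nominal tail mass; widening the quantiles (or selecting on a fixed
  Z threshold instead) removes the ceiling at the cost of admitting
  neutral windows. The package keeps the conventional 5% default and
  exposes both quantiles.

## Numerical and degenerate-input choices

* Hp of a window with zero pool depth is `NA` (undefined), never 0 — a
  fixed pool and an unobserved pool must not be conflated.
* `z_transform` refuses fewer than two defined values or zero dispersion
  rather than returning `NaN`s.
* A selection quantile of exactly 0 selects nothing (the natural limit,
  although `quantile(x, 0)` is the minimum and `zhp <= min` would select
  one window).
* Fewer than 20 eligible windows make empirical 5% quantiles meaningless;
  `select_candidates` errors instead of guessing.
* Phenotype SD of a single-observation group is reported as 0.00 with a
  `sd_degenerate` flag.
* ts/tv with zero transversions is `NA` with a warning.
* The window report writer prints doubles with 17 significant digits so
  the writer–reader round trip is lossless.

## Effect classification

`classify_site` applies the precedence *exonic > splicing > intronic >
upstream/downstream > intergenic* across transcripts, with splicing
defined as ≤ 2 bp into the intron and flanks of 1 kb respecting strand; a
site upstream of one transcript and downstream of another reports the
combined category. `coding_effect` rebuilds the reference codon from the
spliced CDS (reverse-complemented on the minus strand), substitutes the
alternate base and translates with the standard nuclear code
({TAA, TAG, TGA} stops); it is checked against an independent oracle that
translates the whole mutant CDS and diffs the protein. Exonic sites
outside any CDS (UTR exons) are tallied as `exonic_noncoding` so the
annotation table remains a partition of its input. The heterozygosity
rate denominator is the total genome length by default — the natural
choice when no callability mask exists — and is an explicit argument for
users who track callable length.

## Known limitations

* The Fst estimator ranks windows well but is biased at low depth and
  small pool size; Karlsson- or Weir–Cockerham-style pool corrections are
  out of scope.
* Sites are treated as independent both in the simulator and in the
  Z-transforms; with strong LD the effective number of windows is smaller
  than the nominal one.
* Multiallelic sites are dropped, not decomposed.
* Haplotype-based statistics (iHS, XP-EHH) and per-window significance
  testing are out of scope: selection is by empirical quantile, so *some*
  windows are always nominated — interpret candidates comparatively, not
  as hypothesis tests.
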