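---
title: "Composite selection signals: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite selection signals: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csscan)
```

## The problem and the model

A recent selective sweep in one population leaves three correlated traces
at and around the favoured locus: allele frequencies diverge from related
populations (high Fst), the derived allele rises toward fixation relative
to an outgroup-polarized ancestral state (large positive ΔDAF), and one
haplotype becomes long and common, so haplotype homozygosity extends much
further than elsewhere in the genome (positive XP-EHH). Each statistic on
its own is noisy and scale-incompatible with the others; `csscan`
implements the composite selection signals approach, which combines them
*through ranks only*:

1. each component statistic is ranked ascending across SNPs and the rank
   scaled to a fraction strictly inside (0, 1);
2. fractional ranks are mapped to z-scores by the inverse normal CDF;
3. the per-SNP mean z̄ of the m components is referred to its exchangeable
   null, z̄ ~ N(0, 1/m);
4. CSS = −log10 of the upper-tail p-value of z̄;
5. the raw track is smoothed by averaging over a ±0.5 Mb window;
6. the top `top_fraction` of smoothed values defines significant SNPs,
   merged into regions.

The construction assumes only that, absent selection, each component's
ranks are exchangeable across SNPs and the three components are
approximately independent — then z̄ is approximately N(0, 1/m) and the
implied p-values are uniform, which the test suite verifies empirically
(Kolmogorov–Smirnov on 10,000-SNP null tracks, and the empirical variance
of z̄ against 1/3).

### Orientation and one-sidedness

All three components are oriented so that selection in the *target*
population pushes the statistic up: Fst is non-directional but grows with
differentiation, ΔDAF is target minus reference, XP-EHH is
ln(iHH_target/iHH_reference). The p-value is therefore taken one-sided in
the upper tail; a two-sided choice would reward haplotype structure in the
*reference* equally, which is not the question a breed scan asks, and
would make "the top fraction of smoothed scores" incoherent. This is a
committed design choice of the package.

## Component details and numerical choices

**Weir–Cockerham Fst.** The two-population (r = 2) moment estimator is
computed per SNP from observed sample sizes, allele2 frequencies and
heterozygote frequencies; no multi-locus averaging is done, because the
scan consumes per-SNP ranks. Negative estimates (common when true
differentiation is near zero) are kept as computed: clamping at zero would
create a huge tie group at the bottom of the ranking and distort the null.
Sites monomorphic across both populations, or with fewer than two called
samples in either, are invalid. The implementation is pinned to ≤1e-12
against an independent oracle that reconstructs individual dosages and
computes the gametic analysis-of-variance mean squares.

**Ancestral polarization and ΔDAF.** The ancestral allele is the *strictly*
major allele of the outgroup panel; an exact 50/50 tie or an uncalled site
leaves the SNP unresolved rather than guessing — unresolved SNPs are
invalid for ΔDAF. ΔDAF is z-scored for display comparability; because
z-scoring is strictly monotone it provably never changes the fractional
ranks, which the tests assert directly.

**XP-EHH.** EHH at extension x is the pooled-sample probability that two
random haplotypes are identical over every SNP from the core to x
*inclusive of the core*; no partition by core allele is made (the
cross-population convention). Both populations' EHH decay curves are
integrated by the trapezoid rule over physical distance with *shared
stopping*: extension ends where the EHH of the combined two-population
sample first drops below `cutoff`, and that crossing step is included in
both integrals. Truncated curves — chromosome edge or `max_extend_bp`
reached first — are integrated as-is rather than discarded, so cores near
chromosome ends keep their partial information; `max_extend_bp` is applied
as "the first SNP beyond the cap ends the walk", so the curve stops at the
last SNP within range. Single inter-SNP gaps wider than `gap_cap_bp`
contribute at most `gap_cap_bp` of width, preventing one sparse stretch
from dominating an integral. Cores where either integral is zero are
invalid rather than ±∞. Raw scores are normalized genome-wide to mean 0,
sd 1 over valid SNPs. The compiled scan is pinned against an exhaustive
pair-enumeration oracle on toy panels.

Defaults — `cutoff = 0.05`, `max_extend_bp = 1e6` (1 Mb),
`gap_cap_bp = 2e5` (200 kb) — are the long-standing conventions of the
haplotype-scan tools this field uses; all three are arguments of
`xpehh_scan()` and `run_scan()`.

**Ranking.** Fractional ranks are r/(n_valid + 1) with average ranks for
ties, so ranks can never hit 0 or 1 and the normal quantile stays finite.
A SNP whose component value is invalid receives, for that component, the
midrank the value 0 would take against the valid pool — null-neutral —
so the three component vectors stay aligned on a single SNP vector. The
alternative (`invalid_policy = "drop"` in `css_config()`) removes any SNP
with an invalid component from the track entirely.

**Tail computation.** CSS is computed from the normal log-tail
(`pnorm(..., log.p = TRUE)`), so extreme mean z-scores give large finite
CSS values instead of underflowing to p = 0.

**Smoothing and calling.** The window is inclusive on both endpoints,
always contains the focal SNP, and never crosses a chromosome boundary.
Exactly ceiling(`top_fraction` · n) SNPs are flagged; ties at the
threshold are broken by genome order (lowest chromosome, then position),
which keeps the count exact and the output deterministic. The stricter
`secondary_fraction` (0.1%) mask is reported alongside but never used for
region calling.

**Regions.** Successive significant SNPs at most `merge_gap_bp` apart on
one chromosome merge into a region; the span runs from the first to the
last significant SNP (1-based inclusive — not window edges), the region's
average CSS is the mean smoothed score over its *significant* SNPs, and
`n_snps` counts every panel SNP in the span. The merge gap is the one knob
that changes region counts; its default of 1 Mb matches the effective
1 Mb scale of the smoothing window. Gene annotation is normalized to
1-based inclusive coordinates internally (BED read as 0-based half-open,
GFF3 as 1-based); a gene attaches to a region when the intervals
intersect after widening the region by `flank_bp` (default 0, exposed
because "immediately flanking" has no canonical distance).

## Quality control and harmonization

`filter_qc()` fixes an explicit order: chromosome subset → samples with
missing fraction > 10% → SNPs with call-rate failures (> 10% missing) →
SNPs with MAF < 1% on the remaining samples. Sample-before-variant
filtering matches how the standard tooling behaves and makes the result
reproducible; the thresholds are arguments.

`harmonize_alleles()` reconciles two panels by shared SNP id: pure strand
flips are complemented, allele swaps recoded g → 2 − g, combinations
handled. Strand-ambiguous sites (A/T, C/G) are *always* dropped, even when
the alleles nominally match: without array-manifest strand information a
flip and a swap are indistinguishable there, and a silent frequency
inversion is worse than losing the site. Every decision is returned in the
flip report.

## What the simulator emulates — and what it does not

`simulate_panel()` generates, per SNP, a pool frequency
p ~ Uniform(0.05, 0.95) and population frequencies from the
Balding–Nichols model Beta(p(1−F)/F, (1−p)(1−F)/F) with drift parameter
`divergence_f`, so expected between-population variance — and hence mean
Fst — increases in F. The ancestral panel samples at the pool frequency,
making its major allele a consistent estimate of the ancestral state. A
sweep copies the interval segment of one randomly chosen target haplotype
over `carrier_fraction` of all target haplotypes, creating jointly
elevated Fst, ΔDAF and XP-EHH with a recorded truth interval. Genotypes
are haplotype-pair sums, optionally masked at `missing_rate` (haplotypes
are never masked — phased input is complete by contract).

Deliberate simplifications: sites are independent outside sweeps (no
background LD), there is no recombination map, no demographic history, no
genotyping-error model, and the uniform pool frequency avoids the rare
tail. This keeps the null exchangeable — exactly the assumption the CSS
calibration tests need — and means a passing suite demonstrates
correctness of the *computation*, not the field performance of the method
on real LD structure. On real data the effective number of independent
tests is smaller and smoothed-score autocorrelation larger, so region
counts and widths will differ from the simulated behaviour.

Validation problem sizes, chosen to keep the suite quick while leaving
sampling noise well below the assertion margins: 5,000 SNPs on one 50 Mb
chromosome with 50 + 50 + 30 diploids for the end-to-end scenarios (10
sweep seeds, 20 null seeds), 10,000 SNPs for null calibration, 1,000
random count configurations for the Fst oracle, 8-haplotype × 15-SNP
panels for the exhaustive XP-EHH oracle.

## Known limitations

* Two populations per Fst/ΔDAF/XP-EHH comparison; scanning a target
  against several references means looping `run_scan()` over references.
* Physical distance only; no genetic-map smoothing or integration.
* PLINK *binary* (bed/bim/fam) input is out of scope — convert to text or
  VCF first; likewise phasing itself is upstream of this package.
* The outgroup tie rule discards exactly-50/50 sites; with small outgroup
  panels this can remove an appreciable fraction of SNPs from the ΔDAF
  component (they remain in the scan under the null-neutral policy).
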