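---
title: "Methods: temporal cistrome dynamics and regulatory integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal cistrome dynamics and regulatory integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models and decision rules, the tunable parameters and why their defaults
are what they are, what the synthetic-data generators do and do not
emulate, and the numerical conventions that make runs reproducible.

## The analysis in one paragraph

Two nuclear-receptor signaling programs are compared across a treatment
time course. Binding is quantified as library-normalized read depth (RPM)
in fixed windows centered on peak summits; temporal change per site is
ranked by a linear model of RPM on time; dynamic site classes are
interrogated for cofactor motifs against a scrambled-sequence null;
responsive genes from differential-expression tables are tested for
concordance between agonists and for physical proximity of binding to
their promoters via distance CDFs; and for genes repressed late despite
rising promoter RNAP2 occupancy, a gene-body elongation mark (H3K36me3)
separates promoter-proximal pausing from reduced initiation.

## Coordinates and containers

Internally every interval lives in a `GRanges` with the Bioconductor
1-based, closed convention, because that buys the whole GenomicRanges
interval algebra (overlaps, nearest, coverage views) instead of a private
re-implementation. BED and narrowPeak files are 0-based half-open on disk;
`read_peaks()`/`write_peaks()` convert at the boundary, and round-trips
are byte-exact (tested). All user-facing definitions (summit windows,
promoter flanks, distances) are stated in the half-open convention of the
file formats and produce identical genomic intervals either way.

Error handling at the boundary is deliberately strict: a malformed line
fails with its line number; an interval beyond its chromosome, or a summit
outside its peak, is a validation error. A summit-less BED record gets the
interval midpoint as summit; a narrowPeak summit of −1 means the same.

## Occupancy quantification

* **Summit windows** (`summit_window()`): width 100 bp (even, clipped at
  chromosome edges). Peak widths vary by caller and condition; a fixed
  window centred on the point of maximal signal makes read depth
  comparable across sites and time points.
* **Normalization** (`normalize_depth()`): RPM = count / total aligned
  reads × 10⁶. Invariant under joint rescaling of counts and library
  size; no input subtraction or fragment modeling (out of scope).
* **Counting** (`count_reads()`): from a coverage track, the per-base
  signal summed over the region (a 1× track over 100 bp counts 100).
* **Ratios** (`depth_ratio()`): log2 with an additive RPM pseudocount of
  1.0. The log scale makes gains and losses symmetric around 0 and the
  pseudocount keeps ratios finite at empty regions; 1 RPM is small
  relative to any site worth interpreting. Histogram-style summaries
  (`majority_direction()`) report the up/down/zero fractions.
* **Multi-promoter genes** (`strongest_region_for_gene()`): the promoter
  or gene-body region with the strongest RPM in the reference sample
  (earliest timepoint unless configured) represents the gene; exact ties
  resolve to the 5′-most region so the choice is deterministic.

## Temporal dynamics

`fit_site_trend()` regresses RPM on time in hours, pooling replicate
observations as independent points, and reports the two-sided *t* test on
the slope with df = n<sub>obs</sub> − 2. With two timepoints this is
equivalent to an equal-variance two-sample *t* test. Classification
(`classify_dynamics()`) is *gained*/*lost* when the slope is
positive/negative with p < α = 0.05, else *stable*; a slope of exactly 0
is always stable. No multiple-testing correction is applied by default —
the analysis *ranks* sites (the top 50 % of p-ranked sites per class feed
motif work, `select_top_fraction()`, ceiling rounding, ties broken by
|slope| then site id) — but a Benjamini–Hochberg column is available in
`fit_trends(adjust = TRUE)`.

**Power of the per-site test.** With two replicates at two timepoints the
slope test has df = 2 (critical |t| = 4.30). For negative-binomial counts
with variance μ + φμ², the coefficient of variation is bounded below by
√φ no matter how deep the site is sequenced, which caps the attainable
noncentrality. At φ = 0.05 and a 4-fold shift, the per-site test recovers
roughly two-thirds of planted dynamic sites at α = 0.05 (the acceptance
script reports the exact recovery under the default generator), while the
false-dynamic rate stays at the nominal ~5 %. Recovering ≳90 % of 4-fold
shifts at this dispersion requires a third replicate or a
variance-pooling (moderated) estimator, both outside the per-site model
this package implements deliberately — the ranking, not the thresholded
call set, is the downstream interface.

`gained_lost_counts()` compares two peak sets by presence/absence under a
≥1 bp overlap criterion, and `percent_excess(a, b)` summarizes two site
tallies as 100 × (a − b)/a rounded half away from zero — the denominator
is the larger count, the only convention consistent with both published
comparisons it mirrors (6500 vs 3162 → 51 %; 7179 vs 6273 → 13 %).

## Motif fold enrichment

PWMs are per-position base probabilities (counts are converted with a
+0.25 pseudocount; probabilities are floored at 10⁻⁴ so log-odds stay
finite). Scanning (`scan_pwm()`) scores every window on both strands with
Σ log2(p/q) against a uniform background, counts a window once however
many strands hit, and treats any window containing N as unscorable. The
default hit threshold is 60 % of the motif's maximum achievable score — a
conventional permissive setting; it is configurable in bits because
calibrated thresholds are motif-specific.

The null (`motif_fold_enrichment()`) scrambles every site sequence
(seeded mononucleotide permutation by default — exact base-composition
preservation; an Altschul–Erickson dinucleotide shuffle is available for
GC/CpG-sensitive motifs) and averages total hits over 10 scrambles;
`fold = observed / max(null mean, 0.5)`. The 0.5 floor guards the ratio
when the null finds no hits; it also means the fold is only a
well-measured quantity for motifs with a non-negligible background hit
rate — calibration checks in the test suite therefore use a short (7-bp)
motif, for which the null fold is stable near 1, rather than a 16-bp
direct repeat whose background expectation in 20 kb of sequence is
essentially zero.

## Responsive genes and concordance

Fold changes are stored signed and linear (−2 = 2-fold down);
log2 input converts via `signed_linear_fc()`. Filtering uses a strict
inequality on adjusted p (< 0.01) and an inclusive bound on |fold|
(≥ 2, companion cutoff 1.5). The high-confidence set of an agonist pair
is the plain intersection of identically-filtered sets.

`overlap_concordance()` tallies genes responsive under both treatments,
splits them by fold-change sign into concordant/discordant, and reports
the percent concordant rounded half away from zero to one decimal — this
rounding reproduces published overlap tables digit for digit, which
banker's rounding does not. Overlap significance is the upper-tail
hypergeometric probability; the universe defaults to the genes tested in
both tables because the true tested universe of any external analysis is
rarely published — the p-value is therefore reported *for a declared
universe* rather than matched to any published bound.

## Regulatory integration

* **Distances**: from the TSS to the nearest edge base of the nearest
  site, 0 inside a site, ∞ when the chromosome has none (such genes stay
  in CDF denominators). Measuring from the TSS rather than promoter edge
  or midpoint is the declared reading of "distance of binding to
  promoters"; at the 1 kb–1 Mb scales of the CDF grid the three differ
  negligibly.
* **CDF grid**: log-spaced, 1 kb–1 Mb, 25 points — covering proximal
  regulation through long-range enhancers; curves are compared by the
  signed maximum vertical gap and mean difference (`cdf_enrichment()`).
* **Strata**: near < 10 kb, far > 100 kb, both bounds exclusive,
  intermediate genes excluded, compared by a two-sided rank-sum test —
  exact enumeration of all group assignments when the smaller group has
  ≤ 8 observations (ties handled by average ranks), otherwise the normal
  approximation with tie-corrected variance and continuity correction
  (within 0.01 of exact at the crossover, tested).
* **Pausing calls** (`classify_repression_mechanism()`): defined for
  RNA-down genes only. Promoter ratio > 0 with body ratio < 0 ⇒
  pausing-consistent; both < 0 ⇒ reduced initiation; anything else
  indeterminate. Boundary zeros are deliberately indeterminate rather
  than forced into a mechanism.

## What the generators emulate — and what they do not

`sim_config()` freezes the study conditions: occupancy at 2 h and 48 h
with 2 replicates; negative-binomial counts (mean 100, dispersion 0.05 —
a typical ChIP-seq biological CV of ~22 %); log-normal site strengths
(sdlog 1.2, a realistic ~10-fold interquartile spread); planted
gained/lost fractions of 0.2 each with 4-fold shifts; responsive genes at
|fc| ≥ 4 against cutoffs of p < 0.01, |fc| ≥ 2; 80 % of repressed genes
given a site within 10 kb of a TSS; pausing effects of ±1 log2 at
promoters and −1 log2 in bodies with noise sd 0.2 over 200 genes; default
scale 2 chromosomes × 5 Mb, 500 genes, 2000 sites (the whole pipeline
runs in minutes on one CPU; tests use smaller instances of the same
structure). Generators are pure functions of (config, seed): identical
inputs give byte-identical outputs, and every planted label is emitted as
a truth table so downstream recovery is scored without re-derivation.

Deliberately not emulated: read-level artifacts (duplicates, fragment
size, mappability), peak-caller behaviour, covariance between sites,
GC/CpG sequence structure (site sequences are uniform random), and
between-gene expression correlation. Passing the planted-recovery tests
therefore demonstrates that the statistics behave as designed under their
own model assumptions — not that those assumptions hold in any particular
real dataset.

## Numerical conventions

* p-values are floored at 10⁻³⁰⁰ (zero residual variance yields the floor,
  or exactly 1 for a flat fit).
* Percent rounding is half away from zero everywhere a percentage is
  reported.
* All stochastic functions take explicit seeds; child seeds derive from a
  master seed by a fixed affine map within the 32-bit range.
* Pipeline outputs carry no timestamps; TSV outputs carry the seed in a
  comment header and each run writes a manifest with config MD5 hashes,
  so reruns are byte-comparable. (BED/FASTA outputs are emitted without
  comment headers for format portability; their provenance lives in the
  manifest.)
* Tie-breaks are always defined (coordinate order for score ties, 5′-most
  for RPM ties, |slope| then site id for p ties) so no result depends on
  input order.

## Known limitations

The per-site df = 2 trend test is honest but weak, as quantified above;
analyses needing high recall of dynamic sites should add replicates or a
moderated variance estimator upstream and feed the resulting classes into
the same downstream machinery. The hypergeometric universe is a declared
choice, not an inferred one. The motif null preserves composition but not
higher-order sequence structure unless the dinucleotide shuffle is
selected. The pausing classifier is a sign-based decision table; it
labels direction, not magnitude, and genes with pseudocount-dominated
ratios near zero land in *indeterminate*.
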