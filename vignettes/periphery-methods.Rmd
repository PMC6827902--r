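---
title: "Methods: quantifying gene-locus positioning at the nuclear periphery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying gene-locus positioning at the nuclear periphery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perimir)
```

This vignette documents the statistical models behind `perimir`, the
parameters that matter, the numerical choices made where conventions
diverge, and what the synthetic-data generators do and do not emulate.

## 1. Overlap enrichment with a size-preserving permutation null

**Model.** Given a feature set $F$ (e.g. pre-miRNA loci) and a merged
domain set $D$ (cLADs, ciLADs, nucleoporin peaks) on a genome of size $G$,
the observed overlap is either the intersected base pairs of the two
unions (`bp` mode) or the number of features sharing at least 1 bp with a
domain (`feature_count` mode). The expectation under random placement uses
coverage fractions only:

$$E_{bp} = G \cdot \frac{|F|_{bp}}{G} \cdot \frac{|D|_{bp}}{G},
\qquad E_{count} = n_F \cdot \frac{|D|_{bp}}{G}.$$

Enrichment is observed/expected: values above 1 indicate colocalization
preference, below 1 avoidance. The count-mode expectation treats features
as points; their finite width is not corrected analytically because the
permutation null reproduces it exactly.

**Null.** Each of `n_perm` permutations (default 1000) relocates every
feature uniformly over all genomic positions where it fits within a single
chromosome, preserving the feature count and the multiset of lengths.
Shuffling is genome-wide because domain avoidance is a genome-scale
question; a per-chromosome option exists for karyotype-confounded inputs.
Shuffled features may overlap one another — rejection would bias the size
distribution. One-sided p-values are the fraction of permutations with an
overlap at least (`p_enriched`) or at most (`p_depleted`) as extreme as
observed, with ties counted in both tails, so
$p_{enriched} + p_{depleted} \ge 1$ and the p-values are conservative.
When no permutation reaches the observed value the p-value is reported as
the bound `<1/n_perm` (and its numeric slot floored at $1/n_{perm}$, so it
stays in $(0, 1]$). The tie rule matters in count mode, where the
statistic is a small integer: under a true null the p-value distribution
sits slightly above uniform, which is visible in the calibration checks
and is the accepted price of never anti-conservative calls.

**Implementation note.** The permutation loop runs on linearized
coordinates with a prefix-coverage index (covered bp before any position),
so each permutation costs a handful of vectorized operations; the test
suite asserts that this path agrees with the public
GenomicRanges-based `overlap_bp()`/`features_overlapping()` surface and
with per-bp brute-force masks.

## 2. Scaled distance to domain boundaries

Raw bp distances to cLAD/ciLAD boundaries are not comparable across
domains whose sizes span orders of magnitude. The scaled statistic divides
each feature's distance to the nearest boundary by the size of that
closest domain. A feature midpoint inside a domain is at most half a
domain from a boundary, so inside values lie in $[0, 0.5]$ with 0.5 the
domain center; outside values are negated and features farther than one
domain length from the boundary are discarded (a feature exactly one
length away is retained at $-1$). The result lives on $[-1, 0.5]$ and is
invariant under translation and rescaling of the whole genome — the point
of the construction.

Conventions that the statistic's definition leaves open, fixed here:

* **Reference point** is the feature midpoint. Pre-miRNA loci (~0.1 kb)
  are tiny relative to domains (~100-1000 kb), so edge-vs-midpoint choices
  are immaterial in practice; midpoint is the only symmetric option.
* **Straddling features** are classified by where the midpoint falls.
* **Equidistant outside ties** go to the upstream (left) domain.
* A feature on a chromosome with no domains is discarded with a tagged
  reason, never an error.

**Analytic null.** Under uniform midpoint placement the inside part of the
distribution has CDF $2t$ per domain; each gap splits at its midpoint
between the flanking domains and contributes piecewise-linear outside
mass. `scaled_distance_null_cdf()` evaluates this closed form (including
chromosome-end gaps) and is used as an independent oracle: 5000 uniform
features must match it within KS distance 0.05.

Group comparisons (cLAD-proximal vs ciLAD-proximal features) use the
two-sided Wilcoxon rank-sum test: exact enumeration when the combined
sample is at most 12 without ties, tie-corrected normal approximation
otherwise.

## 3. Radial FISH statistics

The nucleus is modeled as a sphere (center + radius in micrometres); this
is the normalization model implied by dividing by a single radius, and
arbitrary segmented shapes are out of scope. For each allele,
$ND = (R - r)/R$, clamped into $[0,1]$; alleles up to 2% of the radius
outside the sphere (segmentation noise) clamp to 0, farther is a
validation error. NDs are binned into ten fixed shells
$[0,0.1), \ldots, [0.9,1]$ with the last bin closed. These equal-width
edges are the operative definition used throughout; note they are *not*
equal-volume shells of the sphere — the uniform reference distribution is
$P(ND \le x) = 1-(1-x)^3$, not $x$, which is exactly why shell 0 holds
27.1% of uniformly placed alleles.

Distribution comparisons use the two-sample two-sided KS test (exact for
both sides $\le 25$ without ties), flagged at the conventional imaging
threshold $p < 10^{-4}$. Lamina colocalization uses imaging-derived
pixel-overlap flags verbatim when present; otherwise a distance rule
(surface distance $\le$ 0.1 µm by default, configurable, also as a radius
fraction) stands in for the pixel criterion. Allelic expression summaries
classify each two-allele cell as silent/mono/biallelic and export
fractions over both denominators (all cells, and expressing cells only),
since published bar graphs use either.

## 4. Synthetic-data generators

The generators are pure functions of (spec, seed) and exist to give every
analysis stage inputs with known ground truth:

* **Genome**: chromosomes tiled by alternating cLAD/ciLAD domains.
  Domain sizes are log-normal (median 500 kb, sdlog 0.6 — the long-tailed
  size regime of mammalian LADs) rescaled so realized cLAD coverage hits
  the target (default 0.40, the constitutive-LAD share of the mouse
  genome) up to integer rounding. Defaults use four 25 Mb chromosomes: a
  scaled-down genome that keeps hundreds of domains while letting a
  permutation test with 1000 shuffles run in seconds.
* **Features**: length 100 bp (pre-miRNA scale), planted fully inside a
  cLAD with probability $q$ (default 0.14, the depleted regime) or a
  ciLAD otherwise, host domain chosen proportionally to its valid start
  positions, position within the domain uniform/center/boundary. Because
  features sit fully inside their host, any-overlap membership recovers
  the planted labels exactly at zero noise.
* **Nuclei**: radius $\mathcal N(4, 0.4)$ µm truncated positive (murine
  lymphocyte scale), two alleles per nucleus, radial law
  $p(r) \propto r^2 e^{\beta r / R}$ with isotropic direction. $\beta = 0$
  is exactly uniform-in-sphere (sampled by inverse CDF $R u^{1/3}$),
  giving the closed-form check above; $\beta \approx 30$ reproduces the
  observed peripheral regime (>50% of alleles in shell 0). $\beta$ is a
  test-fixture dial, not a biophysical claim. Expression is independent
  Bernoulli per allele (default $p = 0.2$), which makes the biallelic
  share of expressing cells $p/(2-p) \approx 0.11$ — the
  mostly-monoallelic profile — and lamina-contact ground truth follows a
  radius-fraction shell (default 0.05).

What the generators do **not** emulate: non-spherical nuclei, spatial
correlation between the two alleles, position-dependent expression,
chromosome territories, domain-size/AT-content covariation, or imaging
noise beyond the sphere-clamp tolerance. Passing tests therefore validate
the estimators and their calibration, not any biological conclusion about
real nuclei.

## 5. Numerical and design choices

* Coordinates are BED-style 0-based half-open at every file boundary;
  in memory they are GRanges. 1-based coordinate lists convert at read
  time via `one_based = TRUE`; chromosome dialects normalize to the
  `chr` prefix; strand is ignored in all overlap work (domains are
  unstranded).
* Membership defaults to any-overlap (the natural semantics of interval
  intersection); the midpoint rule is computed alongside wherever
  per-chromosome tallies are reported, because published counts do not
  always state their rule.
* `classify_genes()` needs a per-tissue high-expression indicator for the
  32-tissue rule; when only values are given, a per-tissue top-50%
  quantile stands in and is explicitly configurable, since the upstream
  atlas cutoff is not part of the rule.
* Uncovered track bp count as zeros in `aggregate_score()` (bigWig
  aggregate convention), keeping scores conservative.
* Pipeline problem sizes used in the shipped checks — 100 Mb genomes,
  2000 features, 1000 permutations, $10^5$ alleles, 500 calibration
  replicates — were chosen so each statistical property is measured well
  inside its tolerance while a full run stays in the minutes range on one
  CPU.

## 6. Known limitations

* The sphere model understates ND for flattened (e.g. adherent-cell)
  nuclei; inputs from such cells should be interpreted shell-wise, not as
  absolute depths.
* Permutation p-values are bounded below by $1/n_{perm}$; claims beyond
  that resolution need more permutations, not extrapolation.
* The shuffle null is uniform genome-wide; it does not condition on GC,
  gene density or assembly gaps. Domain sets whose complement is not
  sequenceable genome will bias coverage fractions accordingly.
* Cross-species reproduction of published membership fractions requires
  the pinned third-party coordinate sets (miRBase Release 21, DamID cLAD
  BEDs); the package ships the machinery and the staging layout
  (`inst/extdata/external/<species>/`) but not the data.
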