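# perimir

Quantitative analysis of gene-locus positioning at the nuclear periphery,
built for studies that ask where microRNA (or any other) gene loci sit
relative to lamina-associated domains (LADs) and to the physical edge of
the nucleus.

Two kinds of evidence are handled by the same package:

* **Genomic coordinates.** Are feature loci enriched in or depleted from a
  domain set (constitutive LADs, constitutive inter-LADs, nucleoporin ChIP
  peaks)? Enrichment is the ratio of the observed overlap to the analytic
  expectation under random placement,
  `E[overlap] = G * cov(features) * cov(domains)` (bp mode) or
  `n * cov(domains)` (feature-count mode), with significance from a
  size-preserving permutation null: features are shuffled genome-wide
  keeping their number and length multiset, and the one-sided p-value is
  the fraction of `N` shuffles reaching an overlap at least (at most) as
  extreme as observed, reported as `<1/N` when none does.
* **Boundary geometry.** How close do features sit to cLAD/ciLAD
  boundaries? For each feature midpoint the distance to the nearest domain
  boundary is divided by that domain's size, giving a scaled statistic on
  `[-1, 0.5]`: 0.5 = domain center, 0 = boundary, negative = outside, and
  features farther than one domain length out are discarded. Groups of
  scaled distances are compared with the two-sided Wilcoxon rank-sum test.
* **3D imaging coordinates.** Per-allele FISH positions inside spherical
  nuclei reduce to normalized distances `ND = (R - r)/R` (0 = periphery,
  1 = center), histogrammed into ten fixed shells
  `[0,0.1), ..., [0.9,1]`, compared across conditions with the two-sample
  Kolmogorov-Smirnov test, and summarized as lamina-colocalization
  fractions and mono-/biallelic expression profiles per cell.

Seeded generators produce every input with known ground truth (an
alternating cLAD/ciLAD genome at a target coverage, features planted inside
cLADs with probability *q*, nuclei with a tunable peripheral bias of the
allele radial law `p(r) ∝ r² exp(βr/R)`), so the whole pipeline is testable
without any external download.

## Worked example

```r
library(perimir)

# a 100 Mb synthetic genome tiled by cLADs/ciLADs at 40% cLAD coverage
gen <- generate_genome(genome_spec(), seed = 1)
gen$clad
#> domain_set 'cLAD': 68 intervals, 40.0% genome coverage

# 2000 loci planted inside cLADs with probability 0.14 (LAD avoidance)
feats <- place_features(feature_spec(n_features = 2000,
                                     inside_probability = 0.14), gen, seed = 2)
permutation_test(feats, gen$clad, mode = "feature_count",
                 n_perm = 1000, seed = 3)
#> Overlap enrichment vs 'cLAD' (feature_count mode, 2000 features)
#>   observed 288, expected 800, enrichment 0.360
#>   1000 permutations: p_enriched 1, p_depleted 0.001 (reported <0.001)
```

288 of 2000 loci touch a cLAD where 800 would be expected by chance
(enrichment 0.36, i.e. 2.8-fold depletion); not one of 1000 shuffles
produced an overlap as low, so the depletion p-value is reported as the
bound `<0.001`.

```r
# radial positions of 4000 alleles in 2000 nuclei with strong peripheral bias
pop <- generate_nuclei(nucleus_spec(n_nuclei = 2000, radial_bias = 30), seed = 4)
nds <- normalized_distance(pop$alleles, pop$nuclei)
shell_histogram(nds)
#> shell histogram of 4000 alleles (shell 0 = periphery)
#> 0.0-0.1 0.1-0.2 0.2-0.3 0.3-0.4 ...
#>   0.958   0.040   0.002   0.000 ...

allelic_summary(pop$alleles)[, c("n_cells", "n_mono", "n_bi",
                                 "frac_mono_expressing")]
#>   n_cells n_mono n_bi frac_mono_expressing
#> 1    2000    607   95            0.8646724
```

95.8% of alleles fall in the most peripheral shell, and 86% of expressing
cells show nascent transcription from only one allele — the monoallelic
profile expected when each allele fires independently with low
probability.

`run_all(config, out_dir)` orchestrates the full comparison (enrichment in
both modes against cLAD and ciLAD, per-chromosome membership counts under
any-overlap and midpoint rules, scaled-distance tables with the rank-sum
comparison, ND histograms, KS matrix, colocalization and allelic
summaries) from a single config; `inst/cli/perimir.R` exposes the same
steps as shell subcommands (`simulate`, `enrich`, `boundary-dist`,
`fish-nd`, `run-all`).

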