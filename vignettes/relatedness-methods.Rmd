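---
title: "Estimating close relatedness from ultra-low-coverage pseudo-haploid data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating close relatedness from ultra-low-coverage pseudo-haploid data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcrelate)
```

## The problem

Ancient-DNA shotgun screening typically yields well under 0.1× genomic
coverage, far too little for diploid genotype calls, yet knowing whether two
skeletons from the same site were parent and child, siblings, or unrelated
shapes every downstream interpretation. `lcrelate` targets exactly this
regime: it asks only for one sequencing read at a site in each of two
individuals, plus a population allele-frequency panel of non-fixed biallelic
SNPs. Using genome-wide panels (tens of millions of candidate SNPs rather
than a capture array's ~1.2M) means even a few hundred thousand aligned
reads can yield the 10,000–20,000 shared SNPs at which 1st- and 2nd-degree
relationships separate cleanly.

## Estimator

Each individual is *pseudo-haploidized*: at every covered panel SNP, one
read that passes the base-quality floor and matches one of the panel's two
alleles is chosen uniformly at random, and its base becomes the individual's
single allele there. For individuals $x$ (alleles $a, b$) and $y$ (alleles
$c, d$) the per-locus Queller–Goodnight value in the $x \to y$ direction is

$$
r_{xy,l} \;=\; \frac{\tfrac12\,(I_{ac}+I_{ad}+I_{bc}+I_{bd}) - p_a - p_b}
                    {1 + I_{ab} - p_a - p_b},
$$

with $I$ allele-identity indicators and $p$ the panel frequency of each of
$x$'s alleles. For pseudo-haploid calls ($a=b$, $c=d$) this reduces to
$(I - p_a)/(1 - p_a)$; the package vectorizes that reduction as the hot path
(`pairwise_hrc()`), keeping the general four-allele form (`rxy_locus()`) for
diploid input and as an independent check in the tests.

Pseudo-haploid sampling halves expected allele sharing, so the pairwise
coefficient is a *halved relatedness coefficient* (HRC) with expectations
0.25 (1st degree), 0.125 (2nd degree), 0 (unrelated). The frequency
correction makes these expectations hold for any non-fixed frequency
spectrum — a property the test suite checks directly.

Two multilocus combinations are provided because the field uses both and
they differ slightly off-equilibrium:

* `mean_of_ratios` (default): average the symmetric per-locus value
  $(r_{xy,l} + r_{yx,l})/2$ across loci.
* `ratio_of_sums`: accumulate numerators and denominators separately per
  direction over loci, form the two multilocus ratios, average them (the
  SPAGeDI-style estimator).

They agree exactly whenever all loci share one allele frequency, and to
Monte-Carlo noise otherwise; the default follows the plain reading of
"averaging $r_{xy}$ and $r_{yx}$ for each locus".

## Classification and confidence

Hard thresholds sit at the mid-points between class means: 0.1875 between
1st and 2nd degree, 0.0625 between 2nd degree and unrelated. Boundary values
are assigned to the *more related* class — conservative for
relative-exclusion workflows, where a missed relative is the costlier error.
Because 3rd-degree relatives (expected HRC 0.0625) overlap the bottom of the
2nd-degree band, estimates in $[0.0625, 0.090)$ are labelled
`second_or_third_degree`; the 0.090 upper edge is configurable
(`classify_hrc(t_third = ...)`) since it is an empirical, not theoretical,
boundary.

Confidence tiers summarize how error behaviour changes with the shared-SNP
count: `high` from 18,000 SNPs (misassignment rare), `medium` from 11,000
(false positives not expected, false negatives possible), `low` from 4,000
(1st-degree pairs reliably detected as related, though possibly at the wrong
degree), `below_threshold` otherwise. Low-count pairs are still reported —
flagged, never suppressed — because with posteriors attached an estimate at
3,000 SNPs can still be informative.

When the panel's ancestry does not match the test population, all HRC values
shift upward together. `normalize_unrelated()` subtracts the mean HRC of
pairs known (archaeologically or genetically) to be unrelated; subtraction
rather than rescaling is used because the distortion is an additive
background-sharing term under a mismatched $p$, and re-centering restores
the expected class ranges while preserving the spacing between classes.

## Monte-Carlo calibration

`simulate_pair()` draws, per locus, $x$'s allele as allele1 with probability
$f$; with probability $k$ (the IBD-copy probability) $y$ copies $x$'s
allele, otherwise $y$ draws independently. Under pseudo-haploid sampling $k$
is exactly the realized kinship, so expected HRC equals $k$: the three
classes use $k = 0, 0.125, 0.25$. This mechanism is chosen precisely because
it provably yields the stated class means for pseudo-haploid data.

`build_distributions()` simulates `n_pairs` pairs per class per SNP count,
drawing a *fresh random locus subset per pair* rather than fixing one subset
per count, so the distribution width reflects both genotype and locus
sampling — matching the real pipeline, where every pair overlaps a different
SNP set. A normal distribution is fitted per class (the simulated HRC is a
mean over thousands of weakly dependent per-locus terms, so normality is
accurate in the regimes used).

From the fitted curves:

* `false_positive_rate()` — the fraction of a class's simulated values
  crossing its own hard-threshold band; the 2nd-degree rate is the usual
  summary since that class can cross into both neighbours.
* `posterior_hrc()` — per-class normal density at the observed HRC,
  normalized across the three classes with equal priors (configurable;
  equal is the honest default absent demographic information). The
  simulated count nearest the pair's actual SNP count is used (default grid
  1,000–30,000), and an estimate outside every curve's support raises an
  error rather than returning a misleading 1.0.

## Synthetic data: what it emulates, and what it does not

`gen_freq_panel()` draws frequencies from a chosen spectrum, truncated to
$[0.001, 0.999]$ so no locus is fixed (0.001 is one allele copy in a
~500-individual panel, the resolution limit of real panels).

The **uniform** spectrum is the default. The choice is driven by the
estimator's per-locus variance, which for an unrelated pair at allele
frequency $p$ is $\mathrm{E}[p^3/(1-p) + (1-p)^3/p + \ldots]$-shaped and
dominated by near-fixed loci. Integrated over a uniform spectrum on
$[0.001, 0.999]$ this gives per-locus variance $\approx 7.6$, i.e. an HRC
standard deviation of $\approx 0.087$ at 1,000 SNPs and $\approx 0.019$ at
20,000 — which places the 2nd-degree threshold-crossing rate near 47% at
1,000 SNPs, a few percent at 10,000 and well under 1% from 15,000. That is
the error-rate-versus-SNP-count behaviour real genome-wide panels exhibit,
so uniform is what the generator's default *means* to emulate. A U-shaped
**beta** spectrum (default `beta(0.2, 0.2)`) is kept as a heavy-tailed
stress case: it roughly doubles the per-locus noise (variance $\approx 42$),
widening class distributions at every SNP count. Class *means* are identical
under both — only calibration widths differ — so mean-recovery results are
reported on the beta spectrum (the harder case) and error-rate results on
the uniform one.

`gen_cohort()` plants pairs at specified $k$ with independent missingness;
`gen_pileup()` wraps calls in mpileup text with Poisson depths, a per-read
error rate, and fixed Q41 qualities. What the fixtures deliberately do *not*
model: post-mortem deamination damage, reference bias, contamination,
read-length variation, linkage disequilibrium between panel SNPs, and
background relatedness within the frequency panel. Passing tests therefore
demonstrate correctness of the estimator and calibration machinery under
clean sampling assumptions — not robustness to aDNA damage, which in
practice is handled upstream (trimming, rescaling) before this method runs.

## Numerical and interface choices

* Base-quality floor: default phred 30, exposed everywhere. It affects only
  which reads survive calling, never the estimator.
* Pileup bases matching neither panel allele (sequencing error, triallelic
  sites) are discarded rather than failing the site — at 0.02× coverage
  every usable locus counts.
* Heterozygous diploid PLINK genotypes are pseudo-haploidized by a seeded
  random draw, since the thresholds are derived for pseudo-haploid data.
* No strand flipping: calls and panel are assumed on the same reference
  strand, so A/T and C/G SNPs are retained. Panels from a different build or
  strand convention must be harmonized upstream.
* Matching pileup sites to the panel is by (chromosome, position), 1-based
  on both sides; `.frq` panels carry positions in `chrom_pos`-style SNP ids
  or an explicit `POS` column.
* All stochastic functions take a `seed` and restore the caller's RNG state,
  so pipeline runs are bit-reproducible and composable.
* Zero-overlap pairs are reported as `NA` with a warning; a single bad pair
  never aborts a cohort run.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to make Monte-Carlo assertions sharp without waste: 500
simulated pairs per class at 20,000 loci for class-mean recovery (standard
error of the mean $\lesssim 0.003$, asserted within $\pm 0.01$), 5,000 pairs
for the error-rate curve (binomial resolution well under 1% at the
thresholds tested), and 3-pair cohorts at 20,000 loci for end-to-end
pileup-to-report recovery.

## Limitations

Only three classes are assessed; 3rd-degree and more distant relationships
are outside the method's resolution and surface only through the
`second_or_third_degree` caveat band. Parent–offspring cannot be
distinguished from siblings (both are 1st degree in expected sharing).
Inbreeding and panel-internal background relatedness are not modelled and
will inflate HRC systematically — the known-unrelated normalization is the
pragmatic correction. Posteriors inherit the simulation's assumption that
the panel frequencies describe the test population.
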