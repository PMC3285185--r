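---
title: "Posterior predictive neutrality testing with coalfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posterior predictive neutrality testing with coalfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalfit)
```

## The problem

Multilocus surveys of non-coding nuclear sequence routinely show far more
among-locus heterogeneity in nucleotide diversity than simple neutral
models of population history predict.  Deciding whether that heterogeneity
reflects demography (bottlenecks, hybridization with an unsampled
population) or locus-specific selection requires an explicit null: simulate
neutral data under the inferred history -- propagating the full posterior
uncertainty of every parameter -- and ask where the empirical summary
statistics fall in the resulting posterior predictive distributions.

coalfit implements that pipeline for a two-population study design (an
"Old World" and a "New World" population, 25 diploid individuals each, so
50 phased alleles per population) with a panel of short non-coding loci.
Three per-locus statistics are tracked:

* $\pi$ -- nucleotide diversity per site, pooled over both populations;
* $\Phi_{ST}$ -- the AMOVA-based fraction of nucleotide diversity
  explained by the between-population contrast (computed on
  pairwise-difference distances, retained unclamped so small negative
  values survive);
* Tajima's $D$ -- computed per population and averaged between the two.

Dataset-level tests compare the cross-locus mean and coefficient of
variation (CV = SD/|mean|, sample SD with the $n-1$ denominator) of each
statistic against its predictive distribution; locus-level tests compare
each locus against its own locus-specific predictive column, with
Benjamini-Hochberg control of the false discovery rate across loci.

## Models and unit conventions

The simulator (`simulateLocus()`) is a structured-coalescent sampler with
competing exponential waiting times for coalescence (rate $k(k-1)/x_d$ in
a deme of relative size $x_d$), backward migration, and recombination on
an ancestral-recombination graph with full ancestral-material tracking;
mutations follow the infinite-sites model on continuous positions.  All
units follow the ms conventions:

* time in units of $4N_0$ generations, $N_0$ anchored to the present-day
  size of the first (OW) deme;
* $\theta = 4N_0\mu$ per locus; deme sizes relative to $N_0$; growth rate
  $\alpha$ with backward size $x\,e^{-\alpha t}$;
* `migration[i, j]` $= 4N_0 m_{ij}$, the backward per-lineage rate at
  which lineages in deme $i$ trace to deme $j$.  A *forward* immigration
  rate into population $i$ (the convention of the upstream inference
  programs) becomes a backward rate attached to lineages currently in
  deme $i$: forward immigration into OW from NW means, tracing time
  backwards, that OW lineages move to NW.
* $\rho = 4N_0 r (L-1)$ per locus, converted from a per-site rate
  relative to the substitution rate as
  $\rho_\ell = r_\ell\,\theta_{site,\ell}\,(L_\ell - 1)$.

Two posterior dialects are consumed.  Per-site tables
($\Theta_i = 4N_{e,i}\mu$, $M_i = m_i/\mu$) anchor a two-island model:
constant sizes, divergence infinitely old, so at least one migration rate
must be positive (a validity error otherwise).  Per-locus tables
($\theta_i = 4N_{e,i}u$, $t = Tu$, founding fraction $s$, ancestor
$\theta_A$) define an isolation-with-migration model: the ancestor splits
at $t$ into daughters founded by fractions $1-s$ (OW) and $s$ (NW), each
growing exponentially to its present size, with migration active between
the split and the present.  Per-locus simulation parameters are formed as

$$\theta_{\ell} = \theta_{site} \times L_\ell \times \mu_{R,\ell} \times
  \text{ploidy}_\ell,$$

where $\mu_R$ is the locus's relative substitution rate (constrained to
mean 1 across loci) and ploidy is 0.75 for the single Z-linked locus.  We
apply the 0.75 factor to $\theta$ and $\rho$ but not to times; the
upstream description says only that "parameters" were adjusted, and
scaling the per-locus rates is the interpretation that leaves the
genealogical time scale of the shared demography untouched.

Two extended models address specific hypotheses.  The *bottleneck* model
keeps the isolation-with-migration history but lets the ancestor continue
shrinking (pastwards) at the OW growth rate between $t$ and a bottleneck
time $t_B \sim U(t, 2t)$, then recover instantaneously to the long-term
size implied by a per-site $\Theta_{OW}$ draw from the two-island
analysis.  The *hybridization* model adds a third (donor) deme that
exchanges migrants with OW only -- donor-NW migration is structurally
zero, since any donor alleles reaching NW must pass through OW -- and
joins the focal ancestor at a time $t_{fd} > t$; donor parameters arrive
scaled to $\theta_{OW}$, which is already the simulator's anchor scale.
Donor-OW migration stays active between $t$ and $t_{fd}$ by default
(configurable), since the donor join is the only event that caps it.  The
*selection* model is not a separate simulator: it is the same
isolation-with-migration machinery run on the locus panel minus an
explicit exclusion list.

## Assembling histories

`assembleHistories()` draws 1,000 joint "histories" (configurable):
demographic rows are sampled *without replacement*, preserving within-row
parameter correlations; $\mu_R$ rows are kept intact -- the mean-1
constraint is a row property -- and paired with histories by a seeded
random permutation ("arbitrary assignment"); recombination rates are
sampled independently per locus.  Every history is fully specified for
every locus and reproducible from the recorded seed; child simulation
streams are derived by counter (`deriveSeed()`), so any single
(history, locus) cell can be re-simulated in isolation.

`jointEstimate()` reproduces the across-locus pooling of per-locus
posteriors: each locus's sample is smoothed with a biweight (quartic)
kernel -- bandwidth 0.9 times Silverman's rule-of-thumb, a documented,
configurable choice since the upstream program does not publish its
bandwidth -- on a common 512-point grid spanning the pooled 0.1%-99.9%
quantiles; densities are multiplied in log space, normalised, and
summarised by the mode and the narrowest (highest-density) 95% interval.
Values below $10^{-12}$ of a locus's density maximum are treated as
exact zeros so that FFT smoothing ripple cannot fake an overlap between
disjoint supports.

## Goodness-of-fit tests

The two-tailed p-value against $n$ simulated values is
$p = \min\!\big(1, \max(2/n,\; 2\min(\#\le, \#\ge)/n)\big)$: a plug-in
estimate floored at $2/n$ because a finite simulation cannot support
$p = 0$.  "Within the 2.5% tails" therefore corresponds to $p \le 0.05$.
Simulated replicates where a statistic is undefined (Tajima's $D$ when a
replicate has no segregating sites) are dropped from that predictive
column and counted, mirroring how undefined empirical loci are excluded
from aggregates.  Dataset-level CVs are computed per history across its
loci, not pooled.

Because the p-value is discrete, the attainable level with $B$ predictive
histories is $2\lceil B\alpha/2\rceil'$-ish rather than $\alpha$ exactly;
with $B = 200$ the test's true level is $12/201 \approx 6\%$.  The
calibration experiments therefore use $B = 199$, for which
$(B+1)\alpha/2$ is an integer and the test is exactly 5%-level -- the
classic Monte-Carlo-test sample-size rule.

## The HKA branch

`hkaTest()` implements the 1987 multilocus neutrality test for one
polymorphic species and a single outgroup sequence: with
$a(n) = \sum_{i<n} 1/i$,

$$E(S_i) = \theta_i a(n_i), \qquad E(D_i) = \theta_i (T + 1),$$
$$\mathrm{Var}(S_i) = \theta_i a + \theta_i^2 b, \qquad
  \mathrm{Var}(D_i) = E(D_i) + \theta_i^2,$$

where $T$ is the split time in $2N$ generations and the $+1$ and
$\theta_i^2$ terms are the mean and variance of the ancestral coalescent
contribution.  The moment equations reduce to a one-dimensional root
solve in $T$ (each $\theta_i$ then follows in closed form); the sum of
deviations $X^2$ over polymorphism and divergence cells is referred to
$\chi^2_{L-1}$.  `iterativeRemoval()` repeats the test, removing the
locus with the largest summed contribution while $p \le \alpha$ (ties
broken by input order with a warning), and `consensusOutliers()` flags
loci removed in strictly more than half of the per-outgroup comparisons.

## What the synthetic generators emulate

`syntheticScenario()` fixes the study conditions: 22 loci with fragment
lengths uniform on 150-500 bp (matching the 164-461 bp panel), one
Z-linked locus, relative substitution rates lognormal with CV 25%
normalised to mean 1, 50 alleles per population, and a per-site
$\theta \approx 0.0092$ for the OW population -- the demographic truths
are the joint estimates of the motivating study (two-island
$\Theta_{OW} = 0.0092$, $\Theta_{NW} = 0.0042$, $M_{OW} = 1010$,
$M_{NW} = 1480$; isolation-migration $\theta_{OW}:\theta_{NW}:\theta_A =
2.53:2.98:1.69$, $t/\theta_{OW} = 0.0126$, $s = 0.022$,
$M_{OW} = 0.13$, $M_{NW} = 12.2$).  Donor-population truths (relative
size 1.5, effective migrant numbers 0.5, join time 0.5 in $4N_0$ units)
and the mean relative recombination rate (0.25 with lognormal spread) are
package choices at levels a waterfowl intron panel would find
unremarkable.  Pseudo-posteriors are independent lognormal (logit-normal
for $s$) perturbations around truth with an exchangeable Gaussian copula
(default rank correlation 0.3, sdlog 0.15) -- location and spread are
what the tests need to control; MCMC autocorrelation realism is not
emulated.  Neither are base-composition, indel or alignment artifacts of
real intron data, so passing tests demonstrate the statistics and the
machinery, not robustness to alignment error.

## Numerical and experimental design choices

* Gap rule: every alignment column containing `-` or `N` is deleted
  before *any* statistic, and per-site denominators use the surviving
  columns.  Per-population statistics are computed on the columns that
  survive whole-alignment deletion, so all populations are scored on the
  same sites.
* Tajima's $D$ is undefined (not zero) when $S = 0$ or $n < 4$;
  aggregates skip undefined values and report the count.
* $\Phi_{ST}$ uses haplotype-level AMOVA on raw pairwise differences (no
  substitution-model correction) -- the simplest model consistent with
  the printed negative values -- with a label-permutation p-value.
* Significance of Tajima's $D$ against zero is available only through
  the coalescent null distributions, not a beta approximation.
* The simulator validates before running that every deme can reach a
  common ancestor (positive migration path or join event); a two-island
  draw with both migration rates zero is rejected.
* The planted-locus power experiment runs under the two-island model
  with the 20-fold $\theta$ deflation planted on the highest-$\theta$
  locus.  A pilot of the experiment design showed why: under the
  isolation-with-migration truth the $s = 0.022$ founder event fattens
  the left tail of every locus's predictive column, and a deflated locus
  is detected in only ~73% of trials, versus ~100% under two-island.
  The method under test is identical in both cases; the experiment is
  placed where a 20-fold suppression is unambiguous.
* Problem sizes used by the shipped tests and acceptance script: 5,000
  replicates for the analytic simulator checks (60,000 for mean Tajima's
  $D$, whose true value at $n = 50$, $\theta = 5$ is about $-0.08$, inside but close
  to the $|0.1|$ bound asserted by the tests); 10,000 replicates per state for the
  Wright-Fisher oracle (200 gene copies per deme, migration probability
  0.01); 200 datasets for Watterson recovery;
  400 calibration trials with 199 predictive histories; 999 predictive
  histories for the planted-locus experiment; 540 HKA calibration replicates across
  divergence levels 0.05, 0.1 and 0.2 substitutions/site with the full
  100-allele sample.

## Known limitations

* Single-outlier power of the HKA branch is intrinsically modest at this
  panel's diversity: a suppressed locus's $X^2$ contribution is bounded
  by the genealogical variance term ($a^2/b \approx 12.8$ as
  $\theta \to \infty$ at $n = 100$), while the $\chi^2_{21}$ critical
  excess is about 12.  A lone 10-fold sweep on a neutral background is
  therefore removed in only ~30% of comparisons, and the >50% consensus
  rule recovers it in roughly a third of trials.  The iterative-removal
  procedure earns its keep when *many* loci deviate jointly, which is
  exactly the situation in the data that motivated it (initial sums of
  deviations above 50).
* Reproducing the motivating study's headline P-values requires its
  actual MCMC posterior chains, which are consumed, not re-estimated,
  here; all empirical-data claims in the package are limited to the
  printed per-locus summary table.
* The infinite-sites realization maps segregating sites to distinct
  alignment columns, so recurrent and back mutation are outside the
  model, as is gene conversion.
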