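---
title: "Mating-system and population-structure estimation from progeny arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mating-system and population-structure estimation from progeny arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matearray)
```

matearray analyses codominant microsatellite (SSR) genotypes of
open-pollinated families — mother trees and their seed progeny — sampled
across several populations, the standard design for scoring the mating
system of a tree species. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic-data generator
does and does not emulate. The running example system is *Toona ciliata*
in South China: six populations, eight SSR loci, 12–30 families per
population with 4–10 seeds each.

## The mixed-mating model

Each offspring of a mother with genotype $g_m$ is either selfed (with
probability $1-t$) or outcrossed (with probability $t$, the outcrossing
rate). Under selfing the offspring genotype arises from the random union of
two maternal gametes; under outcrossing, from one maternal gamete and one
paternal allele drawn from the pollen-pool allele frequencies $p$. The
likelihood of an observed offspring phenotype $y$ is the mixture

$$P(y \mid g_m, t, p) \;=\; t\,O(y \mid g_m, p) + (1-t)\,S(y \mid g_m),$$

summed over the true genotypes consistent with $y$ under null-allele
masking (below). The *multilocus* rate $t_m$ treats the selfed/outcrossed
status as shared across loci (the likelihood multiplies per-locus terms
before mixing); the *single-locus* rates $t_\ell$ mix per locus, and
$t_s$ is their mean. Because an outcross between relatives can look like a
self at any single locus but rarely at all loci jointly, $t_m - t_s > 0$
indicates biparental inbreeding.

Null alleles are handled inside the likelihood: at a locus flagged as
carrying a null allele, the frequency vectors gain a null class, an
apparent homozygote $(k,k)$ is treated as $\{(k,k), (k,\text{null})\}$,
and an untyped phenotype as the null homozygote. Recorded maternal
genotypes that are apparent homozygotes at such loci are integrated over
both candidate genotypes rather than taken literally.

### Estimation

Fitting proceeds in stages:

1. **EM.** Latent variables are each offspring's selfed/outcrossed status,
   its paternal allele per locus when outcrossed, and the maternal genotype
   per family-locus where ambiguous. The M-step updates $t$ (posterior mean
   outcross fraction), the pollen frequencies (expected paternal allele
   counts), the ovule frequencies (expected maternal allele counts) and the
   maternal inbreeding coefficient $F$ (1-D maximization of the expected
   maternal-prior term; since the count-based ovule update is exact only at
   $F=0$, the joint ovule/$F$ update is accepted only when it improves that
   term, keeping the monitored objective monotone). Convergence is declared
   when the log composite likelihood changes by less than `tol` (default
   `1e-6`; `max_iter` 500).
2. **Profile extension.** A mixture weight estimated by EM cannot leave
   $[0,1]$, but maximum-likelihood outcrossing estimates above 1 are a real
   phenomenon in heterozygote-rich progenies and the reference programs
   report them (the study reports $t_m$ up to 1.194). After EM converges,
   $t_m$ and each $t_\ell$ are re-estimated by a 1-D maximization of the
   exact log-likelihood with frequencies frozen, over the interval where
   the per-offspring mixture stays positive (capped at 2). Setting
   `constrain_t_to_unit = TRUE` in `em_options()` keeps estimates in
   $[0,1]$. Cross-population means truncate estimates above 1 to 1
   (`summarize_rate_estimates()`), matching the reporting convention of the
   study system.
3. **Correlated paternity.** $r_p$ is the probability that two outcrossed
   sibs share a father. For each sib pair the ratio
   $R = P(\text{pair}\mid\text{same father}) / P(\text{pair}\mid\text{independent fathers})$
   has the closed form $\prod_\ell (B_\ell + A_{i\ell}A_{j\ell}) / (2 A_{i\ell}A_{j\ell})$
   with $A_{i\ell}$ the marginal outcross probability and
   $B_\ell = \sum_k p_k c_{ik} c_{jk}$; the pairwise composite likelihood
   $\sum w_{ij} \log(r_p R_{ij} + 1 - r_p)$, weighted by the posterior
   probability that both sibs are outcrossed, is maximized in $r_p$
   (multilocus for $r_{p(m)}$; per locus, then averaged, for $r_{p(s)}$).
   $r_{p(s)} - r_{p(m)} > 0$ indicates pollen-pool substructure, and
   $1/r_{p(m)}$ approximates the effective number of pollen donors.
4. **Correlated selfing.** $r_s$ follows a correlated-Bernoulli pair model,
   $P(\text{both selfed}) = s^2 + r_s\,s(1-s)$ with $s = 1 - t_m$,
   maximized over sib pairs with the per-offspring self/outcross
   likelihoods marginalized; it is undefined (reported `NA`) when
   $\hat t_m \ge 1$. $r_{loci}$ is the mean over locus pairs of the
   correlation, across offspring, of the per-locus posterior selfing
   indicators. These two parameterizations are operational choices — the
   reference program's internal definitions are not published — so they are
   validated by simulation recovery, not against published values.
5. **Bootstrap.** Standard errors resample whole families (progeny arrays)
   with replacement, `B = 1000` by default per the field convention;
   failed replicates are dropped and counted.

Where maternal genotypes are unknown, the per-locus maternal posterior is
integrated exactly, but the multilocus offspring likelihood plugs in the
posterior-averaged per-locus terms, a composite-likelihood approximation
(exact whenever mothers are recorded at null-free loci, the dominant case
in this design). For unknown mothers at loci with more than 12 alleles the
candidate set is restricted to alleles observed in the family, a documented
truncation; with four or more offspring the probability that a transmitted
maternal allele is absent from the progeny is below 7%.

## Genotyping-error screening

Screening pools all families of a population (treating members as
unrelated, a deliberate approximation that slightly inflates homozygote
excess and is shared with the standard tooling) and compares observed
genotype-class counts against a Monte-Carlo null that re-pairs the observed
allele copies at random (1000 randomizations and $\alpha = 0.05$ by
default):

* **Null alleles** — flagged when total homozygote excess is significant
  *and* spread evenly across allele classes (at least half the classes in
  excess, no class holding more than half the total excess).
* **Stuttering** — flagged when heterozygotes whose alleles differ by
  exactly one repeat unit are in significant deficit and larger-allele
  homozygotes are in excess.
* **Large-allele dropout** — flagged when the size-rank contrast of the
  homozygote excess, after removing its frequency-proportional component
  (the null-allele signature), is extreme against the Monte-Carlo null,
  two-sided. A per-class rank correlation was tried first and discarded:
  with the 3–10 observable allele classes of a real locus it has almost no
  power.

Null-allele frequencies are estimated by rescaling visible frequencies to
sum to $1-r$ and solving (to $10^{-6}$) for the $r$ that matches the
expected observed-homozygote fraction among typed individuals; the
closed forms $(H_e - H_o)/(1 + H_e)$ and $(H_e - H_o)/(H_e + H_o)$ are
provided as cross-checks.

## Population structure

Allele frequencies are count-based per population, with null-flagged loci
rescaled by the estimated null frequency and a null class appended.
Expected heterozygosity is $1 - \sum_k p_k^2$ including the null class.
Differentiation uses the frequency-based estimator

$$F_{st(s)} = \frac{\sum_i \sum_k n_i\,(p_{ijk} - \bar p_{jk})^2 / ((r-1)\bar n)}
                   {\sum_k \bar p_{jk} (1 - \bar p_{jk})},$$

with $\bar p_{jk}$ the *unweighted* mean over the $r$ populations and
$\bar n$ the mean sample size, tested by $\chi^2 = (r-1)\bar n F_{st(s)}$
on $r-1$ degrees of freedom; the multilocus value is the ratio of summed
numerators to summed denominators. Two properties of this estimator are
worth knowing: it is not bounded by 1 (two populations fixed for different
alleles give exactly 2 under the $(r-1)$ normalisation — asserted in the
tests), and it carries no small-sample correction, so with many rare
alleles the sample estimate exceeds the frequency-level truth. A
Weir–Cockerham-style weighted mean is available via `weighted_mean = TRUE`
for comparison. Isolation by distance regresses $F_{st}/(1-F_{st})$ for
all population pairs on the natural log of the great-circle distance
(haversine, Earth radius 6371.0088 km); because pairwise values are not
independent, a Mantel permutation test of the slope (permuting population
labels) accompanies the OLS coefficient p-values. The altitude analysis is
the Pearson correlation of pairwise $F_{st}$ with absolute altitude
difference.

The island-model helpers expose the closed-form relation between the
composite gene-flow term $N(1-\alpha/2)(m_S + (1-\alpha)m_P/2)$ (with
$N_e = N(1-\alpha/2)$, selfing rate $\alpha$, seed and pollen migration
rates $m_S, m_P$) and the IBD regression, including the numerical
inversion for $\alpha$; the relation is treated as exact algebra and is
not validated against simulation.

## The synthetic-data generator

`simulation_config()` fully specifies a generative run from one seed
(stage seeds are derived as seed + 0/1/2 for frequencies, arrays, errors).
Population allele frequencies start from a symmetric Dirichlet draw and
evolve by multinomial drift ($2N_e$ genes) with island or stepping-stone
migration — drift is simulated at the frequency level, not
individual-based, which is adequate because only frequency-level statistics
are consumed. Progeny arrays implement the mixed-mating model exactly as
estimated, plus three mechanisms the estimator must cope with:

* family-correlated selfing (each offspring copies a family-level status
  with probability $\sqrt{r_s}$, giving pairwise correlation $r_s$);
* correlated paternity (a communal father used with probability
  $\sqrt{r_p}$, so two sibs share a father with probability $r_p$; at
  $r_p = 1$ each family has exactly one father);
* biparental inbreeding (with probability `biparental_rate` a father is a
  "half-relative" constructed by drawing one of his gametes from the
  maternal genotype — a simple mechanism that provably produces
  $t_m > t_s$).

Genotyping errors are applied afterwards: null-allele masking, stutter
(one-repeat heterozygote rescored as the larger homozygote) and
large-allele dropout (probability scaled by the size rank of the larger
allele).

`study_like_config()` pins the generator to the study design: the six
populations at their published coordinates and altitudes, family counts
(23, 12, 16, 20, 24, 30) and seeds-per-family ranges, eight loci with the
published allele counts (14, 44, 30, 30, 5, 24, 47, 14), motifs and size
ranges, per-population selfing rates and paternity correlations inside the
published ranges, null alleles at the loci the study flagged (frequencies
0.05–0.10, values the study does not print), and stepping-stone structure
ordered by longitude with $m = 0.01$, $N_e = 70$, 80 generations — chosen
once so that the sample-based multilocus $F_{st}$ of a generated dataset
sits near the published 0.345. What the generator does **not** emulate:
real allele-frequency spectra (drift from a Dirichlet start is smoother
than real SSR histories), linkage or locus-specific mutation, spatial
structure within populations, and per-population differences in null-allele
frequency. Passing recovery tests therefore demonstrates estimator
correctness under the stated model, not robustness to every field
complication.

## Numerical choices and degenerate inputs

* Frequencies are floored at $10^{-8}$ and renormalised after M-steps;
  per-phenotype probabilities at $10^{-300}$ before logs.
* EM starts at $t = 0.9$, $F = 0$, observed-count frequencies (offspring
  for pollen, mothers for ovules) with 0.5 pseudocounts, and a 0.05 initial
  null-class frequency at flagged loci.
* The maternal genotype prior uses Wright's inbreeding-adjusted
  proportions, clamped at a small floor because $F < 0$ can push
  rare-homozygote terms negative; $F$ is searched in $[-0.95, 0.95]$.
* Monomorphic loci are reported `NA` for per-locus rates and excluded from
  $t_s$; a locus monomorphic across all populations has undefined
  $F_{st}$; pairs with $F_{st} \ge 1$ are excluded from the IBD transform
  with a warning.
* $r_p$ and $r_s$ maximizations are bounded to keep every pair likelihood
  positive; boundary optima are compared explicitly against the interior
  optimum.
* The binomial sampling-error helper implements
  $\sqrt{\hat t(1-\hat t)/n}$; the literal form $\sqrt{\hat t(1-\hat t)}/n$
  sometimes seen in print is dimensionally inconsistent as a standard error
  but is available as `form = "ratio"`.

## Problem sizes used in the test suite

The recovery battery runs at the study scale: 50 replicates of 30 families
× 10 offspring × 8 loci for $t_m$ and $F$; 10 replicates at 100 families
for $r_p$; 20 replicates at $n = 300$ for the null-frequency estimator;
100 clean and 20 contaminated replicates (at 400 Monte-Carlo
randomizations) for the screen's type-I rate and power; 20 stepping-stone
replicates with 199 Mantel permutations for the IBD property. Bootstrap
tests use small `B` explicitly; the default stays at 1000.

## Known limitations

* Exact numeric agreement with the reference program's $r_s$ and
  $r_{loci}$ is not claimed (their internal definitions are unpublished);
  both are validated on simulation recovery only.
* The screen's unrelated-individuals approximation means family structure
  (large full-sib clusters) can mimic homozygote excess; screening the
  study-scale designs simulated here stays calibrated, but extreme designs
  (few, large families) would not.
* The composite-likelihood pair estimators underestimate uncertainty if
  used without the family bootstrap.
* With `constrain_t_to_unit = FALSE`, weakly informative single loci can
  return $t_\ell$ at the positivity cap; such loci contribute noise to
  $t_s$, exactly as in the reference tooling.
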