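---
title: "Supervised ancestry projection: model, uncertainty and aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised ancestry projection: model, uncertainty and aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancestryproj)
library(dplyr)
```

## The problem

Projection (supervised clustering) analysis asks, for each target genome,
what mixture of *previously learned* ancestries best explains its
genotypes. A reference panel supplies ancestry-specific allele frequencies
$p_{km}$ for $K$ ancestries at $M$ biallelic SNPs, learned once from large
present-day cohorts and then held fixed. The quantity estimated per
individual is the admixture-proportion vector
$q = (q_1, \dots, q_K)$ on the probability simplex.

This package implements that analysis for ancient-DNA cohorts, where three
complications dominate: heavy and uneven missingness, pseudo-haploid
genotypes (a single sequenced allele per site, coded as homozygous), and
very small per-population sample sizes, which make per-individual
uncertainty and principled sample-level aggregation essential.

## The likelihood and its maximization

Conditional on $q$, the counted-allele dosage $g_m \in \{0, 1, 2\}$ at a
non-missing marker is Binomial$(c, f_m)$ with
$f_m = \sum_k q_k\, p_{km}$, $c = 2$ for diploid calls and $c = 1$ for
pseudo-haploid calls (with $g_m/2 \in \{0,1\}$ the observed allele).
Markers are treated as unlinked, so the log-likelihood is the sum of the
per-marker binomial terms; missing markers contribute zero.

`project_individual()` maximizes this by EM:
$$q_k' = \frac{1}{cM}\sum_m \left[ a_m \frac{q_k p_{km}}{f_m}
  + (c - a_m)\frac{q_k (1 - p_{km})}{1 - f_m} \right],$$
with $a_m$ the counted-allele count on the $c$-allele scale. The
likelihood is concave in $q$ for fixed frequencies, so the deterministic
uniform start $1/K$ suffices and no multistart is used; the EM step never
decreases the likelihood, and zero components stay zero (the boundary is
absorbing).

The compiled fitter accelerates this map with SQUAREM-style squared
extrapolation: each iteration takes two EM steps, extrapolates along their
secant, and accepts the extrapolated point only if its log-likelihood is
at least that of the second EM step (otherwise the EM step is taken), so
accepted iterations remain monotone. The extrapolation length is bounded
by an adaptive cap that doubles on trusted steps and resets on rejection —
without the cap, an early overshoot can land exactly on a simplex vertex,
which the (absorbing) EM map can never leave. Acceleration here is a
correctness feature, not a luxury: on many-ancestry panels the likelihood
is near-flat along directions mixing correlated ancestries, and plain EM
stalls there — it reports boundary ancestries as slowly decaying positive
dust whose bootstrap replicates barely move, which corrupts the
downstream confidence-interval screen.

Two boundary rules make "this ancestry is absent" a statement the output
can actually express. An extrapolation that leaves the simplex is clipped
to a tiny positive floor ($10^{-8}$), never to exact zero, so the
iteration cannot be absorbed prematurely. After convergence, a component
is reported as exactly zero if it is numerically negligible
($< 10^{-7}$) or if it is small ($< 10^{-3}$) and the EM flow still
points downhill there (growth factor $< 1$): by the KKT conditions of
this concave program, such a component's constrained optimum lies on the
boundary. The removed mass is below the resolution any realistic marker
count can support, and the survivors are renormalized.

Numerical choices:

* **Convergence** — relative log-likelihood change below `tol` ($10^{-6}$
  by default) or `max_iter` (2000). These match common supervised-mode
  practice and make toy problems exactly verifiable against grid search.
* **Frequency clamp** — panel frequencies are clamped into
  $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$; frequencies
  of exactly 0 or 1 would otherwise make the log-likelihood unbounded.
* **`min_markers`** (default 100) — below roughly a hundred informative
  markers the point estimate and especially its bootstrap standard error
  are not meaningful, so the fit refuses and the cohort driver flags the
  individual as failed instead of aborting the run.

## Input harmonization

`align_genotypes_to_panel()` intersects markers by (chrom, pos) and
reconciles alleles. Same-orientation dosages pass through; swapped
REF/ALT dosages are complemented ($g \to 2-g$); strand-ambiguous pairs
(A/T, C/G) are dropped rather than frequency-matched, because
frequency-matching risks silent polarity errors precisely for the drifted
frequencies that carry ancestry information; any other allele combination
is dropped as a mismatch. The four categories are tallied in an alignment
report that partitions the intersection, so nothing disappears silently.
Multi-allelic VCF records are skipped (the panel is strictly biallelic),
and pseudo-haploid individuals are auto-detected (all non-missing calls
haploid) with a manual override.

## Bootstrap uncertainty

Standard errors come from resampling the $M$ aligned markers with
replacement (columns of the dosage vector and the frequency matrix
jointly) and re-fitting; the default is $B = 200$ replicates and the
per-ancestry SE is the sample standard deviation over replicates
(denominator $B-1$). The marker is the exchangeable unit — the likelihood
already assumes unlinked markers, and no block structure is imposed.
Replicate fits start from the point estimate (concavity makes the start
irrelevant to the optimum; it only shortens the iteration path), and each
replicate draws from a stream derived deterministically from
`(seed, individual_id, replicate)`, so results are reproducible and
independent of processing order. Degenerate resamples with fewer usable
markers than `min_markers` are redrawn, capped at $10B$ draws.

## Sample-level aggregation

Individuals within an archaeological sample are combined per ancestry by
inverse-variance weighting that accounts for both within-individual
(bootstrap) and between-individual variance. The between-individual
component $\tau^2$ uses the DerSimonian–Laird moment estimator — the
standard random-effects meta-analysis estimator matching that description:
with fixed-effect weights $w_i = 1/\mathrm{se}_i^2$,
$$\tau^2 = \max\!\left(0,\ \frac{Q - (n-1)}
  {\sum w_i - \sum w_i^2 / \sum w_i}\right), \qquad
  Q = \sum_i w_i (x_i - \bar{x}_{FE})^2,$$
and the combined mean uses $w_i = 1/(\mathrm{se}_i^2 + \tau^2)$ with
$\mathrm{se} = (\sum w_i)^{-1/2}$. A single individual passes through
unchanged and $\tau^2 = 0$ by convention; bootstrap SEs of exactly zero
(boundary ancestries) are floored at $10^{-6}$ for weighting.

Sparsity is then induced per ancestry: a component is kept iff its
two-sided normal 95% CI excludes zero, i.e.
$\hat{\mu}_k - z_{0.975}\,\mathrm{se}_k > 0$ (only the lower bound
matters, since means are non-negative; CIs are not truncated to $[0,1]$
first). Dropped components are set to zero and the survivors renormalized
to sum to 1. No multiple-testing correction is applied across the $K$
ancestries — the procedure is a per-component screen, not a family-wise
test. If nothing survives (tiny samples with huge SEs), the largest mean
is retained alone, with a warning.

Period-level summaries (`summarize_group()`) average sample profiles
weighted by the number of individuals per sample and renormalize. This is
a declared convention: sample sizes are always published alongside such
tables, whereas per-sample variances generally are not, so size weighting
is the reproducible choice. Published period-level means are not always
the size-weighted average of the published per-sample rows (the packaged
tables show exactly this: the size-weighted Southern European mean for the
seven early-farmer samples is 0.470 where the narrative rounds to 47.2%,
but the hunter-gatherer Northern European mean is 63.8% against a narrated
71.6%) — so group means computed here are a convention, while ancestry
*ratios* of published period means reproduce exactly and are what the
acceptance script recomputes.

## Haplogroup composition

`haplogroup_composition()` tallies Y and mitochondrial lineage counts by
plain, case-sensitive string-prefix matching. This is deliberately not
phylogenetic containment: nested names count under their stems ("HV"
under "H", "V9" under "V", "R1" under "R") and parenthesized exclusion
notation like "K(xLT)" matches prefix "K" without parsing the exclusion.
This rule reproduces every published composition percentage in the
packaged tables, which a strict-nomenclature matcher would not (e.g. the
Bronze Age Y figure requires the single "R1" record to count under "R").
Samples recorded without an assignable haplogroup contribute nothing to
the denominators.

## What the simulator emulates — and what it does not

`simulate_panel()` draws an ancestral frequency per marker uniformly on
$[0.05, 0.95]$ (bounded away from fixation so every marker is
informative) and per-ancestry frequencies from the Balding–Nichols
distribution $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ — the standard
one-parameter model of $F_{ST}$-controlled divergence, and exactly the
exchangeable-ancestries structure the projection likelihood assumes.
`simulate_individuals()` draws admixture vectors from a Dirichlet (dense
or fixed-support sparse), genotypes Binomial$(2, f)$, missingness i.i.d.
per entry, and pseudo-haploid coding as a single Bernoulli$(f)$ allele.
Default study conditions mirror the scale of real reference panels
(21 ancestries, $\sim$20,000 markers, $F_{ST} \approx 0.1$).

Real ancient-DNA data differ in ways the simulator does not model:
post-mortem damage and reference bias (missingness here is MAR and
marker-i.i.d., not damage-patterned), linkage disequilibrium (markers are
independent, as the likelihood assumes), and panel misspecification
(targets whose true ancestry is absent from the panel). Passing tests
therefore certify the estimator under its own model assumptions — they do
not certify robustness to model violation.

## Problem sizes used in the checks

The statistical guarantees are exercised at sizes chosen to make the
properties sharp while remaining single-CPU friendly: grid-search
equivalence on $K=2$, $M \le 100$ instances at 0.001 resolution;
parameter recovery RMSE $< 0.05$ over 50 individuals with $K=5$,
$M=20{,}000$, 20% missingness; bootstrap coverage over 200 individuals at
$B=100$ with $K=3$, $M=2{,}000$ and interior Dirichlet(5,5,5) truths
(coverage expected between 90% and 99%); sparse-support recovery on 20
replicate studies of 10 individuals with a shared 4-of-21 ancestry truth
(all components $\ge 0.05$), $M=20{,}000$ and $B=50$, requiring the exact
support in at least 90% of runs.

## A small worked example

```{r example}
panel <- simulate_panel(K = 4, M = 3000, fst = 0.1, seed = 11)
truth <- simulate_individuals(panel, 6, support = c(1, 3),
                              concentration = 5, missing_rate = 0.2,
                              seed = 12)
est <- project_cohort(truth) |>
  add_bootstrap_se(truth, B = 50, seed = 13)
smap <- tibble::tibble(individual_id = rownames(truth$q_true),
                       sample_id = rep(c("siteA", "siteB"), each = 3))
profiles <- aggregate_samples(est, smap)
profiles
```

The sparsified profiles should place all mass on `anc01` and `anc03` —
the simulated support — and they sum to one by construction.

```{r plot, fig.width = 5, fig.height = 3}
autoplot(profiles)
```

## Known limitations

* Frequencies are never re-estimated from the targets (no unsupervised
  mode); a target with ancestry missing from the panel is forced onto the
  nearest available mixture.
* Reference panels estimated from present-day individuals drift away from
  the allele frequencies of truly ancient populations; projection error
  grows with sample age.
* The normal-approximation CI underlying sparsification is crude near the
  simplex boundary, where bootstrap distributions are skewed; components
  with small true proportions and few markers are the ones most easily
  zeroed out.
* No liftover, imputation, genotype-likelihood input or BAM processing;
  inputs are called genotypes in VCF against a fixed panel.
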