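---
title: "Simulating genomic prediction of field-tested DH lines: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genomic prediction of field-tested DH lines: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(gpsim)
library(dplyr)
```

## The question the simulation answers

In a typical barley breeding cycle, doubled-haploid (DH) selection candidates
are evaluated with low intensity in the field — often one single plot per
genotype. The phenotypic value $p$ of a line observed in such a trial is a
noisy estimate of its true genotypic value $g$. An alternative to selecting on
$p$ directly is to use the same trial data to estimate genome-wide marker
effects and to select on the resulting genomic predictions $y$ of the very
lines that were tested. Selection on $y$ is preferable whenever the
correlation $r(y, g)$ exceeds $r(p, g)$.

Since $g$ is never observable in real data, the comparison requires
simulation. gpsim implements the full simulation pipeline: a synthetic genome
and founder panel, meiosis under the Haldane model for factorial and diallel
mating designs, additive genotypic values calibrated to a target genetic
variance, a virtual field trial with a three-component masking variance,
RR-BLUP effect estimation from the simulated phenotypes, and replicated
Monte-Carlo summaries of the correlations $r(p,g)$, $r(y,p)$ and $r(y,g)$.

## Model components

### Genome and founders

The default genome is barley-like: 7 chromosomes of 1.5 Morgan each, with 700
markers on a uniform grid (configurable up to chip densities; the correlation
structure studied here is insensitive to marker count well before that). The
founder panel holds 10 fully homozygous inbreds in two pools — 5 elite lines
and 5 donors. A fraction `pool_divergence` (default 0.3) of the markers is
fixed for opposite alleles between the pools, so those markers segregate 1:1
in every elite $\times$ donor cross; the remaining markers receive
independent alleles per founder subject to a panel minor-allele frequency of
at least `min_maf` (default 0.1, matching the gene-diversity cutoff used in
marker QC). These two values are the package's stand-in for the unavailable
real panel; they produce realistic within- and between-pool modified Rogers'
distances for elite/donor barley material.

The marker-QC utilities (`filter_markers()`) implement the standard rules for
homozygous SNP panels: drop markers with more than 10% missing calls or gene
diversity below 0.1, then drop lines with more than 15% missing calls on the
retained markers. Thresholds are exclusive ("more than", "smaller than");
markers are filtered before lines, and both stages are reported.

### Meiosis

Crossovers follow the Haldane model: per chromosome, a Poisson number of
crossovers with mean equal to the map length in Morgan, locations uniform, no
interference. Restricted to the marker loci this count-location process is
exactly an inhomogeneous two-state Markov chain whose switch probability
between adjacent markers at distance $d$ is the Haldane map function
$r = \tfrac12(1 - e^{-2d})$; the implementation draws gamete origins that
way, vectorised over all gametes of a population, which is distributionally
identical at every observable locus and orders of magnitude faster than
per-gamete crossover lists. A DH line is one doubled gamete of the cross F1 —
a single meiosis fixes the genotype, so DH populations are fully homozygous
by construction.

Whether the historical simulation machinery this emulates used crossover
interference is unknowable from the outside; Haldane (no interference) is
declared as the modelling assumption rather than inferred.

### Genotypic values and calibration

Genotypic values are the additive genome-wide sum $g = \mu + X a$ over the
$-1/+1$ genotype matrix (DH material has no dominance). The default effect
architecture draws i.i.d. Gaussian effects at all markers — the
infinitesimal-like regime in which RR-BLUP converges to GBLUP; Laplace and
sparse architectures are available for sensitivity runs. The intercept
defaults to 85 (centre of a typical winter-barley yield range in dt/ha); it
is cosmetic, since correlations are location-invariant.

Raw effects are rescaled so that the genetic variance of DH populations under
a given mating plan hits its target: $\sigma_g^2 = 20$ for the factorial
scenarios and $\sigma_g^2 = 2$ for the diallel, mirroring the variance gap
between elite $\times$ donor and elite $\times$ elite material. Calibration
simulates a 5,000-line population under the plan, measures the raw variance
and scales by $\sqrt{\text{target}/\text{realised}}$ — on the calibration
draw the match is exact; an independent fresh draw is recorded as a
Monte-Carlo check, whose own sampling error is about
$\sigma_g^2\sqrt{2/n} \approx 2\%$, which is why tests compare it at a 3-SE
tolerance rather than a fixed percentage. Calibration is scheme-specific by
design: anchoring each mating design to its printed variance is what makes
the correlation columns comparable across schemes without access to the
original parents.

### The virtual trial

A trial design is $(E, R, \sigma^2_{ce}, \sigma^2_{le},
\sigma^2_\varepsilon)$: environments, replications per environment, and the
cross-by-environment, line-by-environment and residual variance components.
Masking is simulated directly on the entry-mean scale:

$$p_{cl} = g_{cl} + u_c + v_l + w_\varepsilon, \qquad
u \sim N(0, \sigma^2_{ce}/E),\;
v \sim N(0, \sigma^2_{le}/E),\;
w \sim N(0, \sigma^2_\varepsilon/(ER)),$$

with $u$ drawn once per cross and $v, w$ per line. Simulating $E \times R$
plot values and averaging would be algebraically identical for every
correlation studied here, so the scaled line-mean formulation is used
directly. No field-design factors (replicates, blocks) are simulated; they
belong to the analysis of real augmented designs, which is out of scope.

The closed form
$$E\,[r(p,g)] \approx \sqrt{\frac{\sigma_g^2}{\sigma_g^2 + \sigma_m^2}},
\qquad \sigma_m^2 = \frac{\sigma^2_{ce}}{E} + \frac{\sigma^2_{le}}{E}
+ \frac{\sigma^2_\varepsilon}{ER},$$
(the square root of the entry-mean heritability) is exposed as
`expected_r_pg()` and serves as the analytic oracle for the simulated
$r(p,g)$ in the test suite: because $m$ is independent of $g$ and both are
near-Gaussian, the simulated mean matches it to within Monte-Carlo error in
all 30 standard scenarios.

### RR-BLUP

`fit_rrblup()` solves $\hat a = (X'X + \lambda I)^{-1} X'(p - 1\hat\mu)$ with
$\hat\mu$ the GLS intercept of the kernel model. $\lambda =
\sigma^2_e/\sigma^2_a$ is estimated per replicate by REML of the equivalent
kernel model $p \sim N(1\mu,\, \sigma_a^2 K + \sigma_e^2 I)$, $K = XX'$,
profiled over $\sigma_a^2$ and optimised one-dimensionally over
$\log_{10}\lambda$ on $[-8, 8]$ using the spectral decomposition of the
intercept-projected kernel; a solution at the boundary (the REML estimate of
a vanishing variance component) is kept as the clamped boundary value with a
warning. A fixed-$\lambda$ mode exists for tests and speed
studies. The system is solved in the $n$-dimensional dual space whenever
markers outnumber lines (always, in the standard scenarios); the primal
marker-space solver is retained and tested to agree to $10^{-8}$, as is the
algebraic identity with GBLUP predictions under the kernel $XX'$. Genotype
columns are deliberately not centred or standardised: with the fixed $-1/+1$
coding the intercept absorbs the mean, and recoding would rescale $\hat a$
without changing predictions.

How the original workflow set its variance components inside each simulation
replicate is not documented; REML-per-replicate is this package's declared
choice, and the headline comparison $r(y,g) > r(p,g)$ is insensitive to it.

### Scenarios and replication

`run_scenario()` holds the founder panel and calibrated effects fixed — they
play the role of real parental material and of effects treated as true
values — and redraws meiosis and trial noise each replicate. Per-replicate
seeds are derived from (master seed, replicate index) with a counter-based
mixing function, so any replicate can be recomputed in isolation and results
do not depend on execution order. Replicates with degenerate zero-variance
outcomes are excluded and counted; a scenario with more than 1% flagged
replicates is marked unreliable (with the standard settings none occur).

The default replication is 2,000 runs per scenario. The package's own
acceptance workflow and examples use 200 runs with
standard-error-based tolerances, which resolves mean correlations to about
$\pm 0.005$ (factorial) and $\pm 0.013$ (diallel) at 3 SE — ample for
reproducing values printed to two decimals. The dependent-correlation
calibration study uses 2,000 draws of $n = 250$ triples against a 200-swap
permutation oracle.

`compare_dependent_correlations()` implements the Pearson–Filon (1898) z
statistic for two overlapping dependent correlations, the classical choice
for comparing $r(p, \hat g)$ and $r(y, \hat g)$ that share $\hat g$; the
variant choice is isolated in this one function. The statistic is exactly
antisymmetric under swapping $p$ and $y$; the degenerate case $y \equiv p$
returns $z = 0$ by continuity, and $|r| = 1$ inputs are rejected.

## Numerical and degenerate-input choices

* Thresholds in marker QC are exclusive, matching their verbal definitions;
  filtering is idempotent and marker rules precede the line rule (the order
  is configurable through repeated calls).
* `calibrate_sigma_g()` refuses traits with (near-)zero raw variance
  ("uncalibratable") rather than emitting infinite scale factors.
* Zero phenotypic variance in `fit_rrblup()` yields $\hat a = 0$, $\hat\mu =
  \bar p$, flagged rather than an error, so replicate loops never abort.
* Spearman correlations use average ranks for ties; with continuous
  genotypic values ties are measure-zero but the convention is fixed.
* The REML search space $\lambda \in [10^{-8}, 10^8]$ covers entry-mean
  heritabilities from $\approx 0$ to $\approx 1$ with wide margins.

## What the generator does and does not emulate

The synthetic founders reproduce the pool structure, marker-QC behaviour and
distance geometry of a two-pool elite/donor panel, and the calibration
anchors every scenario's genetic variance to its target, which makes the
$r(p,g)$ column of the standard table architecture-independent and exactly
reproducible. What the generator cannot reproduce is the *internal
structure* of marker effects estimated from a real experiment. Effects
estimated by RR-BLUP from ~250 real lines concentrate genetic variance on
the family/relatedness structure of exactly those crosses (low effective
dimension), which makes them unusually easy to re-estimate from a new noisy
trial of the same families. With i.i.d. effects, the pool-differentiated
markers — which all factorial crosses share at identical midparent value —
contribute only within-cross variance, and prediction accuracy at $n = 250$,
$h^2 \approx 0.29$ levels out near $r(y,g) \approx 0.7$.

Consequently: the superiority $r(y,g) > r(p,g)$ holds robustly in every
scenario and the $r(p,g)$ column is reproduced quantitatively, but the
*absolute* $r(y,g)$ levels under the default Gaussian architecture sit below
those attainable with effects estimated from a structured experiment, and
the strongest cross-design comparison (unreplicated-trial $r(y,g)$ exceeding
replicated-trial $r(p,g)$) is architecture-dependent and not guaranteed by
the defaults. An exploratory check with a minimum-norm ridge-interpolator
architecture (effects confined to the row space of a virtual reference
experiment) gave essentially the same accuracy, confirming that the gap is
about the unavailable family-level concentration of the real effect
estimates, not about the estimator. This limitation is documented rather
than papered over by tuning the generator.

## A worked mini-example

A deliberately small run (140 markers, 20 replicates) so the vignette stays
quick; the package defaults are 700 markers and 2,000 replicates.

```{r example}
cfg_unrep <- scenario_config(
  scheme = "factorial", n_lines_per_cross = 10,
  design = trial_design(E = 1, R = 1, sigma_ce2 = 10, sigma_le2 = 10,
                        sigma_eps2 = 30),
  sigma_g2 = 20, n_reps = 20, seed = 1,
  genome = list(n_markers = 140), n_calibration_lines = 2000
)
res <- run_scenario(cfg_unrep)
glance(res) |> select(E, R, mean_r_pg, mean_r_yp, mean_r_yg, se_r_pg)
expected_r_pg(20, cfg_unrep$design)
```

The mean $r(p,g)$ tracks the analytic $\sqrt{20/70} = 0.535$; the genomic
prediction correlates with the true genotypic values substantially better
than the phenotype does, which is the package's headline comparison.

```{r example-z}
run <- run_replicate(cfg_unrep, 1, keep_data = TRUE)
d <- attr(run, "data")
compare_dependent_correlations(d$p, d$y, d$g)
```

## Problem sizes used in the shipped checks

The package's tests and the acceptance script resolve each scenario with 200
replicates of 250-line populations at 700 markers, 100,000 gametes for the
recombination-fraction oracle, 10,000 draws for variance-component recovery,
and 2,000 Monte-Carlo draws for the z-test calibration — sizes chosen so
every Monte-Carlo comparison has at least 3-SE resolution against its target
while a full run stays comfortably on a laptop.
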