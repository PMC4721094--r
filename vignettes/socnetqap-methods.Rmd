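---
title: "Methods: restricted-QAP temporal network analysis and the nine-arm manipulation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: restricted-QAP temporal network analysis and the nine-arm manipulation models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socnetqap)
```

## What this package computes

`socnetqap` analyses two linked questions about shell-nest augmentation in
communities of a group-living, shell-dwelling cichlid:

1. **Part I — network dynamics.** Daily directed interaction networks are
   built per community (nodes = adults, edge weight = number of interactions
   initiated from one individual toward another). The day-to-day stability of
   each community's network is measured by the Pearson correlation of
   consecutive days' adjacency matrices, tested against a
   *community-restricted* quadratic assignment procedure (QAP) null, and the
   drop in stability across the manipulation day is tested with a Fisher-z
   contrast. Individual-level consequences are modelled as Poisson-lognormal
   GLMMs of four sex-partitioned degree metrics.
2. **Part II — treatment outcomes.** A nine-arm shell manipulation experiment
   (three controls; replace 2/4 broken shells with intact; add 2/4 intact;
   both) with five censuses per group. Territory loss to heterospecific
   usurpers is modelled by MAP Bayesian logistic regression on the arm
   factor; changes in group membership by Gaussian arm-mean models; both are
   summarised by nine planned, FDR-corrected contrasts.

A seeded synthetic-data generator reproduces the statistical structure of
both designs so every stage is testable end to end without the field data.

## The restricted QAP

For two conformable daily matrices $A$ and $B$ (identical node order, zero
diagonal), the association statistic is the product-moment correlation $r$
over the vectorised off-diagonal cells; the structural diagonal is always
excluded, following standard QAP practice. The null distribution is built by
permuting node labels of $B$ — rows and columns simultaneously — and
recomputing $r$. In the *restricted* variant the admissible permutations are
block-diagonal with respect to a sub-group partition: labels may only swap
within a block. Because community structure (who belongs to which social
group) is preserved under the null, the test asks whether *individual*-level
patterns persist beyond what group membership alone explains — a more
conservative null than free label swapping.

The sub-groups come from the Walktrap random-walk algorithm (walk length
$t = 4$, the algorithm's published default, configurable) applied to the
symmetrised network $S = W + W^\top$, with the merge-tree cut chosen by
maximum weighted modularity. Walk probabilities are computed exactly, so the
partition is deterministic. Isolated nodes become singleton blocks. The
partition used for a day pair is detected on the symmetrised **sum of the
two days being correlated**, so the restriction reflects structure common to
both days; a flag (`partition_scope = "day1"`) switches to the first-day
aggregate, and `restriction = "none"` gives the classical unrestricted QAP.
The algorithm itself is delegated to igraph's Walktrap implementation; the
package verifies the contract (exact agreement with exhaustive modularity
maximisation on small graphs, planted-partition recovery) in its test suite.

**p-value rule.** The p-value is the proportion of permutation replicates
whose correlation is *strictly greater* than the observed one. With
all-singleton blocks only the identity permutation is admissible and the rule
yields $p = 0$. The `(k+1)/(n+1)` estimator — which cannot return an exact
zero and is the safer choice for downstream FDR correction — is available via
`add_one = TRUE` and recommended when p-values feed further inference; the
literal rule stays the default for fidelity to the analysis being
reproduced. The default replicate count is 1000. Whenever the number of
admissible permutations is at most 10,000, exhaustive enumeration replaces
Monte-Carlo sampling and the p-value is exact.

**Degenerate inputs.** A day with a constant off-diagonal (e.g. no
interactions at all) has no defined correlation; such pairs are skipped with
a warning rather than imputed. Correlations of exactly $\pm 1$ are clipped at
$\tanh^{-1}(1 - 10^{-12})$ before Fisher transformation, with a warning.

**Reproducibility.** One master seed drives everything; each (community, day
pair) derives a fixed-offset sub-stream, so per-pair results do not depend on
evaluation order.

## The pre/post-manipulation contrast

Each observed correlation $r$ is Fisher-transformed, $z = \tanh^{-1}(r)$,
with sampling variance $1/(m-3)$ where $m$ is the number of off-diagonal
cells. Within community $c$ the contrast is
$d_c = \overline{z}_{\text{pre}} - z_{\text{post}}$ (pre = pairs fully before
the manipulation day; post = the pair spanning it); communities are averaged
with equal weight and the Wald statistic is
$Z = \bar d \,/\, \sqrt{\sum_c (1/K_c + 1)/(m_c - 3)\, /\, C^2}$,
with a two-sided normal p-value. Positive $Z$ means the post-manipulation
correlation dropped. This construction is the package's own choice of
contrast statistic; the source analysis did not print one, so numerical
equality with any previously reported Z is not expected.

## Poisson-lognormal degree models

For male focals, four daily metrics are computed: weighted in-degree from
males, in-degree from females, out-degree toward males and out-degree toward
females — jointly summarising male-male aggression and inter-sexual
affiliation. Counts over the analysis window (days 1–4 by default; the late
heterospecific takeovers disrupt later days) are modelled as

$$y_{i} \sim \text{Poisson}(\mu_i),\quad
\log \mu_i = \mathbf{x}_i^\top\beta + b_{\text{community}} + b_{\text{fish}} +
\varepsilon_i,$$

with day (4-level factor) crossed with the manipulated-male flag as fixed
effects, fish nested in community as random intercepts, and an
observation-level random intercept $\varepsilon_i \sim N(0, \sigma_o^2)$
that absorbs overdispersion (the marginal distribution is Poisson-lognormal).
"Treatment" here means the manipulated-*male* flag (the grouping used to
display degree distributions), not manipulated-community membership.
Estimation is Laplace-approximate maximum likelihood via `lme4::glmer`
(bobyqa optimiser), with Wald z inference to mirror printed Z statistics.
Post hoc, estimated marginal (least-squares) means on the log scale feed
three contrasts — manipulated vs unmanipulated on the post-manipulation day,
and day 4 vs the mean of days 1–3 within each manipulation level — with
delta-method SEs and FDR adjustment across the family.

Two oracle properties anchor the implementation: with all variances at zero
the fixed effects must match an independent Poisson IRLS fit (tolerance
$10^{-3}$ on the link scale), and with a planted observation-level variance
the intercept must estimate $\beta_0$ itself rather than the marginal log
mean $\beta_0 + \sigma_o^2/2$.

## Part II models and the nine planned contrasts

Territory loss (ever lost across the five censuses) is modelled per arm with
one logit mean per treatment and independent Student-t(3, 0, 2.5) priors —
the conventional weakly-informative default; the scale is configurable. The
posterior is summarised by its mode and Laplace covariance, which keeps the
analysis deterministic; the priors regularise arms with zero events to
finite estimates. The omnibus arm effect is a maximum-likelihood
likelihood-ratio test against the intercept-only model (the choice of
omnibus statistic is the package's own; a posterior-predictive alternative
was considered and rejected for determinism). Membership change (last census
minus first, positive = recruitment, computed on never-lost groups only)
uses the same machinery with Gaussian likelihood, a flat prior on
$\log\sigma$, and arm-mean priors scaled by the response SD.

The contrast family is fixed by design: R2 and R4 against the
replacement-style control, A2 and A4 against the adding-style control, AR2
and AR4 against the equal-weight pool of those two controls, plus R4−R2,
A4−A2 and AR4−AR2; p-values are two-sided normal with Benjamini–Hochberg
adjustment across the nine. Because the published description labels the two
active controls inconsistently between sections, the package addresses them
by *function* (`c_repl`, `c_add` arguments, defaulting to C2 and C3); the
contrast labels never mention a bare control code. An alternative family —
each treatment against the pool of all three controls — is provided as a
robustness check (`pooled_control_contrasts`).

**Sign convention.** Deltas are last − first, so female recruitment is
positive. (Read literally, the originating description subtracts in the
other order while reporting recruitment as positive; the package keeps the
convention that matches the reported direction.)

## What the synthetic generator emulates — and what it does not

Part I (`part1_config`): 5 communities × 8 groups on a 1-D lattice (the
mapped transects are not reconstructible, and only adjacency matters to the
rate model); groups of 1–3 adult males, 1–5 adult females, 0–2 juveniles;
8 days; manipulation of one randomly chosen male per community after day 3.
Interaction counts are Poisson per ordered adult dyad per day with rates
λ_within = 1.5 (within group), λ_neighbour = 0.1 (adjacent groups),
λ_male_longrange = 0.02 (male-initiated, non-adjacent) — values chosen so
that the large majority of interactions are within-group (highly modular
communities) and border conflicts dominate the remainder. A persistent,
mean-one lognormal per-dyad multiplier (`dyad_sd = 0.8`) encodes stable
dyadic preferences; it is what makes consecutive days correlate *within*
sub-groups (and hence the restricted QAP significant before manipulation)
and what makes daily counts overdispersed, motivating the Poisson-lognormal
model. From day 4 every dyad involving the manipulated male is scaled by the
matching effect multiplier (default 3 for all four directions — a clear but
not overwhelming effect). From day 5 a daily takeover hazard of 0.2 may
truncate a community's records, reproducing the late predator usurpations
that restricted the original network analyses to days 1–4 (expected ≈3 of 5
communities affected by day 8). Interaction class is assigned by dyad sex
composition (male–male aggressive, otherwise affiliative), with an optional
random flip fraction.

Part II (`part2_config`): 173 groups spread evenly over the nine arms
(largest-remainder allocation, shuffled); initial composition of 1 male,
1 or 2 females (78/173, 95/173) and 0/1/2 juveniles (51/173, 85/173,
37/173); five censuses. Territory loss is an absorbing state with a constant
per-census hazard chosen to reproduce the configured overall per-arm loss
probability (defaults follow the experiment's observed pattern: ≈0.05 in
controls, replacing and weak adding arms; 0.45, 0.25 and 0.4 in A4, AR2 and
AR4). Surviving groups gain a female per interval with probability 0.05
(0.30 in A4/AR2/AR4 — the attractiveness effect), gain a male rarely
(0.01 / 0.05), and lose members at small background rates; these values were
fixed once to produce mean female recruitment of roughly +1 in the augmented
arms, the magnitude the experiment reported, and are not tuned thereafter.

The generator does **not** emulate: observation-effort variation between
sessions (equal effort is assumed), spatial covariates such as distance
between territories beyond lattice adjacency, behavioural mechanism (no
decision-making or movement model), within-day temporal order of
interactions, or re-identification error. Passing tests therefore show that
the *statistical machinery* recovers effects planted under the assumed
sampling models; they cannot validate field-specific artefacts outside those
models.

## Numerical choices

* Exhaustive QAP enumeration cut-off: 10,000 admissible permutations.
* MAP optimisation: BFGS (logistic) / L-BFGS-B with $\log\sigma \ge
  \log 10^{-3}$ (linear), relative tolerance $10^{-14}$; Laplace covariance
  from the numerically differentiated Hessian at the mode.
* GLMM: bobyqa, lme4 defaults otherwise; singular variance components are
  reported as zero rather than raised as errors.
* Modularity ties in brute-force comparisons break toward fewer blocks.
* All validation errors are raised early (self-loops, ids missing from the
  roster, non-monotone territory loss); groups with a census count other
  than five are excluded with a warning rather than an error.

## Problem sizes used in the automated checks

The shipped test-suite calibrations use sizes chosen to balance statistical
resolution against a few minutes of single-CPU runtime: 500 null datasets of
12 nodes at 200 permutation replicates for the uniformity check of the
unrestricted QAP; 100 planted-partition graphs (4 blocks × 6 nodes) for
community recovery; 100 simulated designs of 5 communities × 8 males ×
4 days for GLMM interval coverage; 200 replicates of the 173-group design
for the Part II contrast pattern. The methods themselves have no intrinsic
size limits beyond memory.

## Known limitations

* The restricted QAP's conservativeness depends on the partition actually
  reflecting the permutation-invariance one wants to preserve; a badly wrong
  partition makes the test either too liberal or needlessly conservative.
* The strictly-greater p rule can return exactly zero, which is awkward for
  FDR pipelines; use `add_one = TRUE` where that matters.
* With ~19 groups per arm, individual arm-vs-control loss contrasts at
  moderate effect sizes (e.g. 0.1 vs 0.45 loss probability) have limited
  power after FDR correction (roughly 25–60% depending on the contrast's
  effective sample size); the package's power simulations document this
  rather than hide it.
* MAP + Laplace summaries approximate the posterior; for small arms with
  rare events the Gaussian approximation on the logit scale is crude, though
  adequate for contrast testing.
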