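---
title: "Models and methods: meat transfer in a multi-level society"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: meat transfer in a multi-level society}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

meatshare studies how meat — a high-quality, shareable resource — moves
through a multi-level primate society of one-male **units** nested in
**parties** nested in **gangs** (the Guinea baboon social system). The
package implements a two-part analysis: a Bayesian two-stage model of who
receives meat, and a frequentist ordinal model of how tolerant the
transfer is, plus a synthetic-society generator that provides ground
truth for every inference stage.

## The sociality stage

Individual *gregariousness* $g_i$ (a general tendency to interact) and
dyadic *affinity* $a_{ij}$ (a pair-specific preference net of
gregariousness) are estimated jointly from three focal-follow behaviours
aggregated over the 90 days preceding each meat-eating event:

$$
\begin{aligned}
\mathrm{approach}_{ij} &\sim \mathrm{Poisson}\!\big(\exp(\mu_{ij} + b_{0,\mathrm{app}} + \log \mathrm{eff}_{ij})\big)\\
\mathrm{groom}_{ij},\ \mathrm{contact}_{ij} &\sim \mathrm{Beta}\big(m\,\phi,\ (1-m)\,\phi\big),\quad m = \mathrm{logit}^{-1}(\mu_{ij} + b_0)\\
\mu_{ij} &= 0.5\,(g_i + g_j) + a_{ij},\qquad
g \sim N(0, \sigma_g^2),\quad a \sim N(0, \sigma_a^2)
\end{aligned}
$$

with priors $\sigma^2 \sim \mathrm{Exp}(1)$,
$b_{0,\mathrm{app}} \sim N(0,1)$, $b_{0,\mathrm{groom}}, b_{0,\mathrm{contact}} \sim N(-6, 2^2)$
(grooming occupies a small fraction of observation time, so the
logit-scale intercept sits far below zero), and $\phi \sim \mathrm{Exp}(0.1)$.
The additive constant $0.5$ on $(g_i + g_j)$ is kept exactly as written.
Proportions are time-in-behaviour divided by summed dyadic observation
effort — the only denominator consistent with the effort offset in the
approach sub-model. Because the Beta likelihood requires values strictly
inside $(0,1)$, `jitter_proportions()` adds Uniform$(0, \varepsilon)$
noise with $\varepsilon = 10^{-6}$ to *all* values (not only zeros), so
the perturbation is exchangeable across dyads; results are insensitive
to $\varepsilon$ anywhere in $[10^{-8}, 10^{-5}]$ since the smallest
observed non-zero proportions are orders of magnitude larger.

Sampling uses JAGS. Defaults are 4 chains × 1,000 warmup + 1,000 kept
draws; convergence is summarized by the maximum potential-scale-reduction
factor over the scalar parameters and flagged (never hidden) when it
exceeds 1.1. One fit is made per unique (party, 90-day window) and cached
across transfers that share the window.

## The transfer stage

Three independent sub-models take the sociality posteriors as
predictors.

* **Audience size** (control): zero-truncated Poisson — there is always
  at least one individual within ~10 m of a possessor —
  $k \sim \mathrm{Poisson}^{+}(\exp(c_0 + c_{0,\mathrm{party}} + c_{0,\mathrm{poss}} + c_1 g))$,
  with Exponential(1) priors on the varying-intercept variances. The
  truncation term $\log(1 - e^{-\lambda})$ is evaluated through
  `log(-expm1(-lambda))` for numerical stability.
* **Audience composition** (control): membership counts over the adult
  party roster follow
  $\mathrm{Multinomial}(\mathrm{softmax}(c_\mathrm{affi}\, a),\ n = \text{audience size})$
  with per-event roster lengths.
* **Transfer choice** (primary): the recipient is a categorical draw
  over the ragged audience,
  $\mathrm{softmax}(b_\mathrm{affi}\, a + b_\mathrm{sex}\,\mathrm{sex} + b_{0,\mathrm{partner}})$,
  where sex is the *candidate recipient's* sex (female = 0, male = 1)
  and $b_{0,\mathrm{partner}} \sim N(0, \sigma^2_\mathrm{partner})$
  absorbs identity-specific propensities to receive meat. A positive
  $b_\mathrm{affi}$ means closer associates of the possessor are more
  likely to receive meat. The headline summary is the posterior median
  with an 89% equal-tailed credible interval.

**Uncertainty propagation.** The sociality posteriors enter downstream
models as distributions, not point estimates. This is implemented as
multiple imputation: the downstream model is refitted once per thinned,
index-matched sociality draw set ($K = 50$ by default) and the
posteriors pooled by concatenation. A single-fit mode (fixed predictor
values) exists for comparison; propagating uncertainty can only widen
the pooled posterior, a property checked in the test suite.

**Data funnel.** Before fitting, transfers are removed in order, each
with a logged reason: unknown transfer type; steal transfers (they do
not reflect the possessor's motivation to share); cross-party dyads (no
affinity can be estimated); transfers whose 90-day window has no focal
data. The choice model additionally requires audiences of at least two
candidates — a singleton audience carries no information about choice.
Audience members from outside the possessor's party are excluded from
the choice set with a logged count. A recipient absent from the recorded
audience is a hard error by default (a configurable repair that appends
the recipient is available in the data-building step).

## The tolerance stage

Transfer types are ordered by tolerance: steal < scavenge/succeed <
share (scavenge and succeed are collapsed — both are neutral types
occurring without direct interaction). The cumulative-logit mixed model

$$
P(Y \le k) = \mathrm{logit}^{-1}(\theta_k - \eta), \qquad
\eta = X\beta + u_\mathrm{poss} + u_\mathrm{rec} + u_\mathrm{dyad} + u_\mathrm{event}
$$

has fixed effects for shared social level (reference: same unit/same
party), possessor sex, recipient sex, and their interaction (reference
sex: female), with four crossed random intercepts. With steal as the
lowest category, positive effects mean "more tolerant"; the original
report does not state its sign convention, so ours is documented here.

Crossed grouping factors rule out quadrature, and the full–null
likelihood-ratio test requires maximized likelihoods; the marginal
likelihood is therefore a Laplace approximation over the stacked
random-effect vector, with a sparse-Cholesky Newton inner optimization
(warm-started across outer iterations) and quasi-Newton (`nlminb`) outer
optimization on $(\theta_1, \log\Delta\theta, \beta, \log\sigma)$.
Standard errors come from the observed information (central-difference
Hessian of the marginal log-likelihood); p-values are Wald z tests.
Variance estimates that hit the boundary ($\sigma < 0.005$) are clamped
to 0 with a logged note. The implementation is validated in the test
suite against `lme4::glmer` on dichotomized responses, against
`MASS::polr` when all variances are truly zero, and against adaptive
numerical integration on small-variance toys (agreement < 1e-3).

Inference guards: an overall full–null LRT (null = same random
structure, no fixed predictors; df = 5) against cryptic multiple
testing; a reduced model without the sex interaction; a
proportional-odds diagnostic comparing the ordinal estimates with two
binary mixed logistic fits (response cut below and above the middle
category, both coded so 1 = the more tolerant side); leave-one-level-out
stability refits; and a parametric bootstrap (default N = 1,000) for
95% percentile intervals, with non-converged replicates dropped and
counted.

A known limitation of the Laplace route: with (near-)singleton clusters
on a categorical response the profiled variance of that factor is weakly
identified and the approximation can drift upward — the same regime in
which observation-level random effects misbehave in `glmer`. The
grouping structures used here (repeated dyads, multi-transfer events)
keep clusters informative; fits flag non-convergence rather than hide
it.

## The synthetic society

`simulate_dataset()` generates the study conditions end to end:
a nested roster (defaults: 2 gangs × 2 parties × 3 units, one male and
two females per unit), truth draws $g, a$, behaviour from the exact
sociality likelihoods, and 109 meat-eating events. Defaults mirror the
scale of the reported analysis: $\sigma_g = \sigma_a = 1$,
$b_{0,\mathrm{app}} = -1$, $b_{0,\mathrm{groom}} = b_{0,\mathrm{contact}} = -6$,
$\phi = 10$, $c_0 = 0.7$, $c_1 = 0.15$, $c_\mathrm{affi} = 0.15$,
$b_\mathrm{affi} = 0.3$, $b_\mathrm{sex} = 0$, 30 h of focal effort per
dyad per window.

Choices the source analysis leaves open, fixed here once:

* **Transfer chains**: the number of transfers per event is
  zero-truncated Poisson with rate 1.6 (mean ≈ 2.0, matching the
  reported median of 2); the recipient of transfer $k$ possesses the
  carcass for transfer $k+1$. The initial possessor is uniform over
  adult party members (capture probability is not modelled).
* **Zero-transfer events**: with probability 22/109 an event is a small
  prey item consumed whole (kept in event summaries, absent from
  tallies).
* **Audience sampling**: the likelihood specifies only softmax
  multinomial form, not a generative scheme; membership is sampled
  sequentially without replacement with softmax renormalization. A
  size draw exceeding the candidate pool is truncated at the pool size
  and counted.
* **Cross-party exposure**: with probability 0.1 per transfer the
  candidate pool extends to same-gang members of other parties (weight
  at affinity 0). This produces the cross-party transfers that the
  tolerance model stratifies and the Bayesian funnel excludes.
* **Tolerance-scale heterogeneity**: possessor / recipient / dyad /
  event random intercepts share s.d. 0.5 on the latent scale;
  thresholds $(-1, 1)$ with level effects $(0, -1.2, -2.3)$ give the
  share > scavenge/succeed > steal gradient across levels.

What the generator deliberately does not emulate: spatial movement and
prey ecology, juvenile/infant behaviour, demographic turnover within a
window, observer error in audience records, and temporal drift in
sociality. Passing recovery tests therefore show that the estimators
invert the stated generative model at realistic sizes — not that real
field data satisfy that model.

## Numerical choices and problem sizes

Equal-tailed quantile intervals (mass 0.89) summarize all posteriors;
softmax is computed with max-subtraction; dyads are keyed unordered
(`dyad_key()`); all randomness flows from explicit seeds (JAGS chain
RNGs are derived from the config seed, so every fit is reproducible).
The test suite exercises recovery at the sizes a reviewer can wait for:
sociality recovery at 20 individuals × 30 h effort; choice-model
coverage at the analyzed sample size of 148 choices × 30 replicates;
LRT size under the null at 150 records × 200 replicates; ordinal
recovery at 2,000 records. The pipeline smoke test runs a reduced
society (30 events, short chains, $K = 2$) and checks byte-identical
reports under a repeated seed.
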