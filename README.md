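# meatshare

Meat transfer through a multi-level primate society.

Guinea baboons live in a nested society — one-male **units** inside
**parties** inside **gangs** — and they catch prey and transfer meat
tolerantly. Two questions structure the analysis this package
implements for behavioural ecologists working with such data:

1. **Who gets the meat?** Is an audience member's chance of receiving
   meat predicted by the strength of their social relationship with the
   possessor?
2. **How is it transferred?** Do more tolerant transfer types
   (share > scavenge/succeed > steal) concentrate at the base of the
   society and fade at higher levels?

## Models

**Sociality stage.** Individual gregariousness `g` and dyadic affinity
`a` are estimated jointly from focal-follow behaviour in the 90 days
before each meat-eating event:

```
approach_ij ~ Poisson(exp(mu_ij + b0_app + log(effort_ij)))
groom_ij, contact_ij ~ Beta(m * phi, (1 - m) * phi),  m = logit^-1(mu_ij + b0)
mu_ij = 0.5 * (g_i + g_j) + a_ij,   g ~ N(0, sg^2),  a ~ N(0, sa^2)
```

**Transfer stage.** Three sub-models take the sociality posteriors as
predictors, with uncertainty propagated by multiple imputation over
thinned draws: audience size (zero-truncated Poisson in possessor
gregariousness), audience composition (multinomial softmax in affinity
over the party roster), and the primary transfer-choice model

```
recipient ~ Categorical(softmax(b_affi * a + b_sex * sex + b0_partner))
```

over the ragged audience of each transfer. A positive `b_affi` means
meat flows along stronger relationships.

**Tolerance stage.** Transfer type (steal < scavenge/succeed < share)
follows a cumulative-logit mixed model in shared social level, sexes
and their interaction, with crossed random intercepts for possessor,
recipient, dyad and event, fitted by a Laplace-approximated marginal
likelihood, with a full–null likelihood-ratio test, proportional-odds
diagnostics, stability refits and a parametric bootstrap.

A synthetic-society generator (`simulate_dataset()`) produces all five
data tables under exactly these generative assumptions with known
ground truth, so every estimator in the package is exercised against
recoverable truth in the test suite.

## Worked example

```r
library(meatshare)

# a small synthetic society with known truth (b_affi = 0.3)
sim <- simulate_dataset(society_config(
  n_gangs = 1, parties_per_gang = 2, units_per_party = 3,
  females_per_unit = 1, n_events = 60, p_cross_party = 0.25, seed = 42L
))

report <- run_pipeline(sim, run_config(
  mcmc = mcmc_config(chains = 2, warmup = 500, iter = 500),
  k_propagation = 5, bootstrap_n = 0, seed = 42L
))
report
#> <meatshare_report>
#>   funnel: 82 transfers -> 40 (sub-models) -> 25 (choice model)
#>   b_affi: median 0.457, 89% CI [-0.063, 1.109]
#>   ordinal LRT: chi2 = 7.928, df = 5, p = 0.1603
```

The funnel line mirrors the bookkeeping of the field analysis: raw
transfers, minus unknown-type/steal/cross-party/no-focal-data
exclusions for the Bayesian sub-models, then audiences of at least two
for the choice model. `b_affi` is the affinity slope of the
transfer-choice model — here its posterior pools 5 imputation sets of
sociality draws, and with only 25 choices the interval is wide but
centred near the generator's truth of 0.3. The ordinal LRT compares the
tolerance model against a null lacking all fixed predictors (df = 5).

Each fitted stage has `tidy()`, `glance()` and `autoplot()` methods:

```r
tidy(report$transfer_models$transfer_choice)
#> # A tibble: 3 x 6
#>   term       median   lower upper  mass n_draws
#>   <chr>       <dbl>   <dbl> <dbl> <dbl>   <int>
#> 1 b_affi     0.457  -0.0630 1.11   0.89    1000
#> 2 b_sex     -0.0464 -0.872  0.939  0.89    1000
#> 3 spartner2  0.482   0.0901 1.85   0.89    1000

# the softmax choice rule at the fitted slope, audiences of 2 and 3
plot_choice_curve(0.28)
```

The choice rule itself is a one-liner — for a two-member audience with
affinities -1 and +1 and slope 0.28, the probabilities of receiving
meat are:

```r
softmax(c(-1, 1), slope = 0.28)
#> [1] 0.3629857 0.6370143
```

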