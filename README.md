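# kiteIPM

Integrated population modelling of a small raptor population subject to
illegal poisoning, built around the insular red kite (*Milvus milvus*)
setting: a closed island population of 8–19 breeding pairs surveyed for
twelve years, ~140 birds radio-tagged at fledging, and a sparse series of
unmarked carcasses (poisoned vs other causes) handed in by the public.

The package is for quantitative ecologists who need to (i) estimate
survival, cause-specific mortality, tag loss, detection/reporting rates,
fecundity and a latent breeding proportion *jointly* from heterogeneous
monitoring streams, and (ii) translate those estimates into the
management question: by how much does poisoning suppress population
growth, and where is the break-even point?

## The model

Four likelihoods share parameters through one joint posterior:

* **Radio-tracking** — a multistate capture–recapture model over 16
  latent states (6 alive-with-radio age classes, 5 alive-without-radio,
  4 recently-dead states crossing cause of death with radio status, 1
  absorbing unobserved-dead state), evaluated by the exact forward
  algorithm. Survival φ is age-independent; the probability that a death
  was by poison is age-specific (m_juv, m_1y, m_2my); radio retention has
  three age classes tracking battery decay.
* **Counts** — a state-space model with female age classes N1, N2, N3:
  recruitment N1′ ~ Poisson(φ (f/2) B), survival binomial, observed pairs
  y ~ Poisson(B) with B = 0.1 N2 + γ N3 and γ latent.
* **Productivity** — fledglings J ~ Poisson(R f_t) with hierarchical
  log-normal year effects, log f_t ~ N(μ, σ²).
* **Dead recoveries** — latent deaths multinomial out of the population,
  thinned binomially by the *same* reporting rates rP, rO as the
  multistate model.

Nested variants MS / IPM1 / IPM2 add the streams one group at a time.
Sampling is adaptive Metropolis-within-Gibbs with integer random-walk
updates for the latent counts (see the methods vignette,
`vignettes/integrated-model.Rmd`). A deterministic pre-breeding Leslie
matrix

    A = | 0        0.1 (f/2) φ_juv   γ (f/2) φ_juv |
        | φ_1y     0                 0             |
        | 0        φ_2my             φ_2my         |

with φ_a = φ*_a (1 − Δ_a), φ*_a = φ + (1 − φ) m_a (additive mortality),
supplies growth rate, sensitivities/elasticities (exact chain rule) and
break-even poisoning levels.

## Worked example

```r
library(kiteIPM)

# 1. simulate a study-scale dataset from the reference parameters
g <- generate_bundle(scenario_config(), seed = 42)
g$bundle
#> <kite_bundle> 1999-2010
#>   counts:      12 years, 127 breeding-pair records
#>   productivity: 318 fledglings from 127 broods
#>   recoveries:   21 poisoned, 1 other causes
#>   histories:    143 tagged birds in 11 cohorts

# 2. fit the full integrated model (desk-scale settings)
fit <- run_mcmc(g$bundle, "IPM2", chains = 3, iter = 6000,
                burnin = 2500, thin = 5, seed = 1)
summary(fit)          # posterior mean, sd, 95% CrI, Rhat per parameter
derived_quantities(fit)$summary   # phi*_a, Delta_a, lambda_t, mean lambda
project(fit, horizon = 3, seed = 1)

# 3. deterministic perturbation analysis at the reference estimates
v <- vital_rates_from_estimates(phi = 0.808, m = c(0.428, 0.764, 0.764),
                                f = 1.825, gamma = 0.631)
growth_rate(v)$lambda
#> [1] 1.081578
vital_rate_perturbation(v)
#>      parameter sensitivity elasticity
#> 1 phi_star_juv   0.2112291 0.17384887
#> 2  phi_star_1y   0.1969555 0.17384887
#> 3 phi_star_2my   0.7390012 0.65230226
#> 4    delta_juv   0.2071544 0.01768095
#> 5     delta_1y   0.2221671 0.03156132
#> 6    delta_2my   0.8335981 0.11842192
#> 7            f   0.1030307 0.17384887
#> 8        gamma   0.2828136 0.16499543
sapply(c("juv", "1y", "2my"), function(a) breakeven_reduction(v, a))
#>       juv        1y       2my
#> 0.4470498 0.4844148 0.2516649
```

Read: the population grows ~8.2% per year at the estimated rates; growth
is dominated by the adult (2+) class; and poisoning would tip the
population into decline if it cut juvenile, 1-year-old, or adult survival
by ~45%, ~48% and ~25% respectively (adult survival falling to ~0.71).

A thin CLI wraps the same functions:
`Rscript scripts/kiteipm.R simulate|fit|perturb --help`.

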