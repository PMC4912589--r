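# famcr

Bayesian multistate capture–recapture models of **family association** in
long-lived birds, with matrix-projection fitness and a cost–benefit
simulator of "leaving home" strategies.

In geese, offspring can stay with their parents — and afterwards with
siblings — for many winters. Staying improves survival; leaving opens the
door to breeding. `famcr` estimates the demographic rates of this tradeoff
from winter encounter histories of birds marked in their first winter, and
asks at what age departure from the family pays.

## The model

Observations are annual winter codes per marked bird: 0 not seen, 1 with
parents, 2 with ≥1 sibling, 3 independent/nonbreeder, 4
independent/breeder. States are forward-only (1→2→3→4, with skips), state 4
is absorbing, and the latent process adds an unobservable dead state. For
age classes *a* = 1…7+ :

* survival: φ_s(a) = logit⁻¹(α_s + β_s·a), state-specific intercept and
  slope;
* transitions: multinomial logit per (state, age) with the last allowed
  destination back-transformed as ψ_n = 1 − Σ ψ_i;
* detection: state-specific resighting probability p_s.

The likelihood conditions on first capture (age 1, with parents) and
marginalizes latent states with the hidden-Markov forward algorithm
(compiled kernel; plain-R reference implementation kept and cross-tested).
`sample_posterior()` draws from the posterior by adaptive block Metropolis
(Normal(0, √1000) priors on coefficients, Uniform(0,1) on detection) and
`gelman_rubin()` checks convergence.

Each posterior draw then populates a 21-stage (age × nonbreeder-state)
projection matrix in which a transition to breeding contributes one recruit
into the (age 1, with parents) stage, after which the breeder is lost to
population growth. The dominant eigenvalue λ_wt (`wildtype_fitness()`) is a
relative fitness proxy. `strategy_grid()` forces departure from parents at
age *p* and from siblings after *s* further years (probability 1, observed
survival and breeding otherwise) and tests ω = λ_wt − λ_s per draw, with
P = Pr(ω < 0): P < 0.05 means the forced strategy is credibly worse than
the wild type.

Because the original field data are not public, the package ships a
generator (`simulate_population()`) whose `default_truth()` pins every
published posterior mean (e.g. remaining with parents: 0.60 at age 2, 0.83
at age 5; sibling→breeder: 0.35 at age 5; detection 0.94 for breeders, 0.64
for independent nonbreeders) and documents the unpublished remainder as
plausible defaults.

## Worked example

```r
library(famcr)
cfg <- study_config(years = 1:15, cohorts = setNames(rep(125L, 8L), 1:8))
ch  <- simulate_population(default_truth(), cfg, seed = 7)
fit <- sample_posterior(ch, mcmc_config(n_chains = 2, n_iter = 4000,
                                        n_burnin = 1500, thin = 5, seed = 3))
summarize_posterior(fit, rhat = TRUE)
#>         parameter mean  lo95 hi95 Rhat
#> 30  psi_P_to_P_a2 0.57 0.507 0.63  1.0
#> 94          p_INB 0.64 0.613 0.68  1.0
#> 95           p_IB 0.91 0.842 0.95  1.0   (selected rows)

wildtype_fitness(fit)
#> fitness posterior (wild type): mean 0.8062, 95% CRI [0.7730, 0.8392], 1000 draws

strategy_grid(fit, valid_strategies()[c(1, 2, 9, 10), ])
#>   leave_parents_age sibling_years omega_mean omega_lo95 omega_hi95     P credible
#> 1                 1             0    0.00784   0.003137    0.01575 0.000     TRUE
#> 2                 1             1    0.00349  -0.000639    0.01019 0.064    FALSE
#> 3                 2             0    0.00354   0.000401    0.00966 0.006     TRUE
#> 4                 2             1   -0.00051  -0.004196    0.00468 0.653    FALSE
```

The posterior mean of remaining with parents at age 2 (0.57, 95% CRI
0.51–0.63) recovers the generating value 0.60 even at this reduced scale;
detection probabilities recover almost exactly. The ω rows read: forcing
birds to leave parents and siblings at age 1 or 2 costs fitness
(ω > 0, P < 0.05, credibly worse than the wild type), while leaving parents
at 2 with one sibling year is statistically indistinguishable from the wild
type — the qualitative "stay for the first years" signal.

Descriptives on the same simulated data:

```r
association_durations(ch)
#> association durations for 1000 individuals
#>   mean parent association: 1.71 years (92% lasted <= 3)
#>   birds with any sibling association: 82 (8%)
breeding_summary(ch)$prop_breeders
#> [1] 0.053
```

## Package layout

| Area | Functions |
|---|---|
| I/O & conventions | `read_capture_histories`, `write_capture_histories`, `write_mark_inp`, `modal_state`, `age_class` |
| Simulation | `study_config`, `default_truth`, `simulate_population`, `latent_states` |
| Estimation | `sample_posterior`, `forward_loglik`, `transition_row`, `survival_prob`, `log_prior`, `gelman_rubin`, `summarize_posterior`, `credible_difference` |
| Fitness | `build_projection_matrix`, `dominant_eigenvalue`, `wildtype_fitness` |
| Cost–benefit | `strategy_spec`, `forced_transition_tables`, `strategy_fitness`, `fitness_difference`, `strategy_grid`, `monitor_draw_correlations` |
| Descriptives | `association_durations`, `breeding_summary` |
| Orchestration | `pipeline_config`, `run_pipeline` |

See `vignettes/family-association-models.Rmd` for the full account of the
model, priors, simulator design, and numerical choices.
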