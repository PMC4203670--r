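# antimix

Simulated maximum likelihood for panel mixed multinomial logit (MMNL)
models, built around one idea: if the quasi-random draws behind the
simulated likelihood are not symmetric, the likelihood value depends on the
*signs* of the estimated Choleski factor — an artifact with no statistical
content that can silently invalidate likelihood-ratio tests. `antimix`
implements fully antithetic Halton draws, which remove the artifact exactly,
together with the diagnostics that expose it.

## Who this is for

Researchers estimating random-parameter discrete choice models (and, more
generally, any model fit by maximum simulated likelihood with normally mixed
parameters) who need LR tests they can trust at practical draw counts, and
who want to verify whether their own software's draws are the problem.

## The model and the problem

For individual *i* choosing among *J* alternatives in situations
*t = 1, …, T*, the mixed logit likelihood integrates the conditional logit
panel product over the mixing distribution of the random coefficients
*β*:

    P_i(θ) = ∫ ∏_t  [ exp(V_itj*) / Σ_j exp(V_itj) ]  f(β | θ) dβ

with normal mixing β = b + Q z, z ~ N(0, I), where Q is the
lower-triangular Choleski factor of the mixing covariance Ω = Q Qᵀ. The
integral is approximated by averaging over R quasi-random draws per
individual (Halton sequences, one prime base per mixing dimension):

    SP_i(θ) = (1/R) Σ_r  ∏_t P(chosen | b + Q z_ir)

Because Ω = Q Qᵀ is invariant to flipping the sign of any *column* of Q,
there are 2ⁿ equivalent factorizations of the same covariance — one per
"quadrant" of the sign space of the Choleski diagonal. The theoretical
likelihood is identical in all of them; the *simulated* likelihood is not,
unless each individual's draw set is symmetric under all 2ⁿ coordinate
sign flips. Conventional Halton draws are not symmetric, so optimizers land
in different quadrants with different simulated likelihood values ("false"
local maxima), LR statistics between models whose optima sit in different
quadrants can even go negative, and p-values scatter.

Fully antithetic draws fix this by construction: every Halton base point
u = (u₁, …, uₙ) is paired with all 2ⁿ − 1 mirrors obtained by replacing any
subset of coordinates with 1 − u_k, all mirrors staying with the same
individual (so R must be a multiple of 2ⁿ). The mapped normal draws are
then exactly closed under every sign-flip pattern and the simulated
likelihood is quadrant-invariant to machine precision. One-dimensionally
antithetic draws (pairing only the single global complement) symmetrize
just one of the 2ⁿ − 1 mirror directions and do not solve the problem.

A second, subtler failure survives even with antithetic draws: when a
restriction removes one mixing dimension (a standard deviation set to
zero), standard software re-bases the restricted model's draws on the
*first* n − 1 primes regardless of which dimension was dropped. The
restricted likelihood then rides on different draws than the dimensions it
shares with the unrestricted model, shifting the LR statistic. `antimix`
tracks the prime-to-dimension assignment through restrictions
(`reduce_draw_config()`, policy `"keep_assigned"` vs `"naive_first"`) and
measures the resulting gap (`prime_policy_gap()`).

## Worked example

Simulate a panel at a known optimum, then scan the likelihood over all 8
quadrants with conventional and with fully antithetic Halton draws:

```r
library(antimix)

sim <- simulate_panel(sim_spec(n_individuals = 200, n_situations = 10,
                               n_alternatives = 4, seed = 1))
params <- true_params(sim)   # realized sample moments of the latent betas

cfg_conv <- draw_config(primes = c(B = 2, C = 3, D = 5),
                        draws_per_individual = 96, n_individuals = 200,
                        antithetic = "none")
quadrant_scan(sim$panel, params, build_draws(cfg_conv))
#> Quadrant scan over 8 sign-flipped Choleski factorizations
#>       +++       -++       +-+       --+       ++-       -+-       +--       ---
#> -2451.516 -2451.283 -2452.365 -2449.799 -2452.446 -2451.601 -2448.887 -2450.669
#> max |difference|: 3.55928

cfg_anti <- draw_config(primes = c(B = 2, C = 3, D = 5),
                        draws_per_individual = 96, n_individuals = 200,
                        antithetic = "full")
quadrant_scan(sim$panel, params, build_draws(cfg_anti))
#> Quadrant scan over 8 sign-flipped Choleski factorizations
#>       +++       -++       +-+       --+       ++-       -+-       +--       ---
#> -2451.593 -2451.593 -2451.593 -2451.593 -2451.593 -2451.593 -2451.593 -2451.593
#> max |difference|: 0

rejection_threshold(0.05, 1)
#> [1] 1.920729
```

Read the two scans together: the eight quadrant labels are the diagonal
signs of the Choleski factor, and all eight parameterizations imply the
*same* covariance, so the eight values should be equal. With conventional
draws at R = 96 they spread over 3.56 log-likelihood units — well past the
1.92 that decides a 1-df LR test at the 5% level, enough to flip a test's
conclusion depending on which quadrant each optimizer run happens to reach.
With fully antithetic draws at the same R the spread is exactly zero.

Estimation, LR machinery and the experiment tables work the same way:
`fit()` (quasi-Newton on the simulated likelihood, fixed draws),
`lr_test()`, `cross_quadrant_lr()` (all 64 ordered quadrant pairs),
`run_quadrant_table()` / `run_lr_table()` for draw-count sweeps, and a thin
command-line interface in `inst/scripts/antimix`
(`simulate | evaluate-quadrants | lr-scan | prime-compare`).

## Scope

Normal mixing and the logit kernel only; no scrambled or shuffled Halton
variants, no Bayesian estimation, no robust standard errors. See the
methods vignette (`vignettes/antithetic-draws.Rmd`) for the model details,
parameter choices and limitations.
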