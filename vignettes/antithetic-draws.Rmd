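---
title: "Antithetic Halton draws and reliable LR tests in panel mixed logit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Antithetic Halton draws and reliable LR tests in panel mixed logit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antimix)
```

## The model

`antimix` estimates panel mixed multinomial logit models in which the
alternative-specific constants of the non-base alternatives are normally
mixed across individuals. Individual $i$ faces $T_i$ choice situations with
$J$ alternatives; conditional on a coefficient vector $\beta$ the choice
probabilities are conditional logit, and the panel product over situations
is integrated over the mixing distribution
$\beta \sim N(b,\, \Omega)$, $\Omega = Q Q^\top$ with $Q$ lower triangular:

$$P_i(\theta) \;=\; \int \prod_{t=1}^{T_i}
  \frac{e^{V_{i t j^*_t}(\beta)}}{\sum_j e^{V_{itj}(\beta)}}\,
  \phi(\beta;\, b, \Omega)\, d\beta .$$

The integral is simulated: draws $z_{ir} \sim N(0, I_n)$ are produced
quasi-randomly, transformed as $\beta_{ir} = b + Q z_{ir}$, and the
conditional panel likelihood is averaged over $r = 1,\dots,R$. The whole
computation stays in log space — the panel product is a sum of log
probabilities, the draw average a log-sum-exp — because a product of twenty
choice probabilities underflows raw double precision long before it becomes
numerically uninteresting.

## Why quadrants matter

$\Omega$ determines $Q$ only up to column signs: flipping any subset of
columns leaves $Q Q^\top$ bit-for-bit unchanged (`flip_factor()` tests
this exactly). The $2^n$ sign patterns are the *quadrants* of the
factorization, labeled here by the diagonal signs. A flipped column $k$ is
equivalent to negating $z_k$ in every draw, so the simulated likelihood is
quadrant-invariant exactly when each individual's draw multiset is closed
under all $2^n$ coordinate sign-flip patterns. Conventional Halton draws
are not; the simulated likelihood then differs across quadrants even at a
fixed parameter point, optimizers report different "optima" with identical
covariances (false local maxima), and LR statistics assembled from models
whose optima landed in different quadrants are biased or even negative.

A note on the definition: sign combinations of *individual elements* of
$Q$ do not generally preserve $Q Q^\top$; column flips are the unique
family that always does, and they generate exactly $2^n$ distinct
factorizations. `antimix` therefore defines quadrants by column flips
throughout.

## The draw generators

`build_draws()` composes three pieces, each exposed on its own:

* **Halton streams.** `radical_inverse()` reverses the base-$b$ digits of
  the integer index; `halton_sequence()` returns consecutive elements. One
  prime per mixing dimension, and the assignment of primes to dimensions is
  explicit and named — it is part of the model configuration, not an
  implementation detail (see the reduction problem below).
* **Antithetic expansion.** `make_full_antithetic()` pairs each base point
  with all $2^n - 1$ coordinate mirrors $u_k \mapsto 1 - u_k$ (binary-mask
  order, base point first); `make_one_dim_antithetic()` pairs only the
  global complement. Mirrors stay within the individual: individual blocks
  are contiguous runs of the Halton stream, and $R$ must be a multiple of
  $2^n$ (full) or $2$ (one-dimensional). Invalid counts are a hard error
  naming the nearest valid multiples; `round_draws_up()` performs the
  documented, never silent, adjustment.
* **Normal mapping.** The standard-normal quantile, `unit_to_normal()`.
  Mirroring happens in the unit cube, so the mapped pairs satisfy
  $z(1-u) = -z(u)$ up to quantile round-off ($\sim 10^{-15}$); the
  package's symmetry assertions use $10^{-10}$ (sums, skewness) and
  $10^{-8}$ (likelihood differences) to absorb summation-order noise.
  These tolerances are far below anything of statistical relevance — an
  optimizer converging at gradient tolerance $10^{-4}$ cannot distinguish
  them from zero.

The default `drop = 10` discards the first ten Halton elements of each
stream, removing the strongly correlated initial run; it is configurable
and all results here are insensitive to it.

Fully antithetic draw sets are closed under every sign-flip pattern per
individual, have per-dimension mean and skewness zero, and make
`quadrant_scan()` exactly flat. One-dimensional antithetics symmetrize only
the all-coordinates flip; the package's tests confirm both the closure they
do provide and the closure they do not.

## Likelihood evaluation

`simulated_loglik()` evaluates individuals in vectorized blocks of draws.
Two code paths produce identical results (tested against each other and
against a per-draw oracle): a count-based path when utilities contain only
alternative-specific constants — the per-individual choice counts are
sufficient statistics — and a general row-level path when attribute columns
with fixed coefficients are present. Draw blocks are sized to roughly
4 million doubles; per-individual log-sum-exp accumulates across blocks, so
memory is flat in $R$. Underflow of an individual's entire simulated
probability (all draws at $-\infty$) is reported with the individual's id.

Degenerate inputs behave by convention rather than accident: a zero
Choleski factor reproduces the conventional logit likelihood at $\beta = b$
for any draw set; an empty mixing (all dimensions restricted away) needs no
draws at all and is the conventional logit; `logit_choice_prob()` subtracts
the maximum utility, so utilities of $\pm 700$ are safe.

`simulated_kernel_loglik()` is a small diagnostic evaluator for arbitrary
kernels: with zero means, a diagonal factor and a kernel symmetric in each
coordinate of $\beta$, quadrant differences vanish *even with conventional
draws*, isolating the interaction of kernel asymmetry (the logit) with draw
asymmetry as the cause of the problem.

## Estimation and LR machinery

`fit()` maximizes the simulated likelihood by BFGS with central-difference
gradients (relative step $10^{-6}$), holding the draw set fixed across all
parameter values — the standard requirement for comparable simulated
likelihoods. Convergence is declared at gradient max-norm $10^{-4}$
(iteration cap 500). By default only the Choleski diagonal is estimated
(uncorrelated mixing); `correlation = TRUE` frees the full lower triangle.
The raw signed estimate is kept alongside the canonical non-negative-
diagonal version, so quadrant bookkeeping of estimation runs (which
quadrant did this start land in?) remains possible; `fit_multistart()`
automates the perturbed-starting-value sweep.

`lr_test()` and `rejection_threshold()` wrap the $\chi^2$ calibration
(1.92 log-likelihood units decide a 1-df test at 5%). Negative LR
statistics are flagged, not clipped, and excluded from p-value summaries —
their share is itself the headline diagnostic of
`cross_quadrant_lr()`, which forms the statistic for all $(2^n)^2$ ordered
pairs of (unrestricted quadrant, restricted quadrant). Restrictions with a
standard deviation pinned at zero sit on the boundary of the parameter
space; the package follows common practice and uses the plain $\chi^2$
reference distribution rather than a boundary-corrected mixture, a choice
the user can revisit by transforming the reported statistics.

## Reducing the mixing dimension

When a `fix_sd_zero` restriction removes a dimension, the restricted
model's draws must come from somewhere. `reduce_draw_config()` implements
both policies: `keep_assigned` retains each surviving dimension's original
prime (recommended — the restricted likelihood then shares its draws with
the dimensions it shares with the unrestricted model), and `naive_first`
reassigns the first $n-1$ primes in canonical order (what standard software
does). `prime_policy_gap()` evaluates the restricted likelihood under both
with identical $R$ and returns the signed difference; both are consistent
approximations of the same integral, so the gap vanishes as $R \to \infty$,
but at practical draw counts it is large enough to matter for borderline
tests.

## The synthetic generator

`simulate_panel()` draws each individual's coefficients from the generating
normal, then picks the utility-maximizing alternative under additive
Gumbel(0,1) noise — distributionally identical to multinomial sampling from
the logit probabilities, and chosen to mirror the utility-maximization
story (ties, a probability-zero event, break to the lowest alternative
index). One seeded stream is consumed in a fixed order (coefficients first,
then noise, situation-major), so a specification reproduces its panel
bit for bit. The *realized* sample moments of the latent coefficients are
recorded: in a finite sample they differ from the generating values, and
they — not the population values — are the "true optimum" at which the
quadrant-scan experiments evaluate the likelihood (`true_params()` exposes
both).

Default study conditions follow the simulated design the package's
experiments emulate: panels of individuals making repeated choices among 4
alternatives, three normally mixed alternative-specific constants with unit
means and unit, uncorrelated variances, base utility zero. Two presets
encode regimes the experiments need: `"paper-like-c"` (one dimension with
SD 0.1, making a zero-SD restriction only mildly false) and
`"mildly-false-mean"` (first mean 0.05, so a zero-mean restriction's LR
signal is of the same order as the conventional-draw quadrant spread —
the borderline regime where draw asymmetry actually flips test
conclusions; a grossly false null would be rejected in every quadrant and
hide the pathology).

What the generator does *not* emulate: real choice data has attributes,
correlated tastes, unbalanced panels and misspecified kernels. Passing
tests on this generator shows the simulation machinery is correct and the
antithetic invariance holds exactly as the symmetry argument predicts; it
does not show that any particular empirical model is well specified.

## Experiment scale

The packaged experiments and tests run at desk scale: panels of 200
individuals × 10 situations (500 for the recovery study), draw counts
96–4096, chosen so the full suite completes in well under a minute while
still exhibiting every qualitative phenomenon — quadrant spreads of several
log-likelihood units at R = 96 with conventional draws, exact flatness
under full antithetics, negative LR shares and p-value scatter on a mildly
false null, and a prime-policy gap that shrinks with R. Users reproducing
magnitudes closer to published large-panel studies should scale
`n_individuals`, `n_situations` and `draw_counts` up; nothing in the code
depends on the desk-scale values.

## Known limitations

* Normal mixing only; log-normal or triangular mixing distributions (which
  share the sign-symmetry issue through their scale parameters) are not
  implemented.
* Full antithetics require $R$ to be a multiple of $2^n$; for
  high-dimensional mixing ($n \gtrsim 8$) this forces large $R$ and the
  construction becomes impractical — the method is for small-dimensional
  mixing.
* The optimizer reports the quadrant of its landing point but does not
  search quadrants; with conventional draws, different starts genuinely
  land in different quadrants (that is the phenomenon, reproducible via
  `fit_multistart()`).
* No robust/sandwich standard errors or simulation-bias corrections;
  inference beyond LR tests is out of scope.
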