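---
title: "A Bayesian day-specific model for the sex of the baby"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian day-specific model for the sex of the baby}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The sex ratio at birth is close to a biological constant — about 106 boys per
100 girls, an implied female-birth probability of roughly 0.485 — yet a long
line of hypotheses claims that biometrical variables shift it: the timing of
intercourse relative to ovulation, or the length of the follicular phase of
the conception cycle.  Testing such claims from prospective fecundability
data is not straightforward, because most conception cycles contain several
intercourse acts and nobody observes which act was responsible.  `cyclesex`
implements a Bayesian model that handles this aggregation honestly and
returns exact posterior probabilities for the "no effect" hypotheses.

Records are conception cycles.  Each cycle carries the sex of the resulting
baby ($Y_i = 0$ male, $1$ female), twelve binary intercourse indicators
$X_{i1}, \dots, X_{i,12}$ for the fertile window — the days $-8$ to $+3$
relative to the mucus peak (MP), the last day of best-quality cervical mucus,
used as the proxy for ovulation day — and the follicular-phase length $w_i$
(days from the first menstruation day to the MP), coarsened into four ordered
classes: $\le 13$, $14$–$16$, $17$–$19$, $> 19$ days.

## The model

Each intercourse day is treated as an independent Bernoulli opportunity to
"produce a male"; a cycle yields a female only if no intercourse day does.
With $q_{ik}$ the day-specific probability that intercourse on day $k$ alone
results in a male,

$$P(Y_i = 1 \mid X_i, z_i) \;=\; \prod_{k=1}^{12} (1 - q_{ik})^{X_{ik}},
\qquad
q_{ik} \;=\; 1 - \exp(-\lambda_k \xi_i),
\qquad
\xi_i \;=\; \prod_{h < z_i} \gamma_h .$$

The complementary log-log link makes the per-day survival probability
$1 - q_{ik} = \exp(-\lambda_k \xi_i)$, so the cycle-level probability
collapses to $\exp(-\xi_i \sum_k X_{ik} \lambda_k)$.  The $\lambda_k > 0$ are
day-specific baseline parameters on the hazard scale; $\gamma_h > 0$ is the
multiplicative change associated with moving from follicular class $h$ to
$h+1$, and $\xi_i$ is the partial product over the classes below the cycle's
own class $z_i \in \{1,\dots,4\}$ (empty product 1).

Two algebraically incompatible readings of the day-level link are possible —
a survival form $1 - q_{ik} = \exp(-\lambda_k \xi_i)$ and a direct product
form $1 - q_{ik} = \lambda_k \xi_i$.  This package uses the survival form
throughout: it is the form under which the gamma priors below are
conditionally conjugate once Poisson latent counts are introduced, which is
the computational strategy the whole sampler is built on.  Consequently
$\lambda_k$ is not itself a probability (its prior is unbounded above);
`day_hazard()` converts to the implied one-day male probability and
`1 - day_hazard()` to the female one when a probability-scale reading is
wanted.

Cycles with no intercourse anywhere in the window are rejected at ingest:
their female-probability is the empty product, identically 1 regardless of
parameters, so they contribute nothing and only distort summaries.

### Priors and hypothesis testing

* $\lambda_k \sim \mathcal{G}(a_{0k}, b_{0k})$ independently, default
  $a_{0k} = b_{0k} = 1$ (mean 1, variance 1 — diffuse on the hazard scale).
* $\gamma_h \sim \pi_h\, \delta_1 + (1 - \pi_h)\, \mathcal{G}(a_{0h}, b_{0h})$,
  a **one-inflated gamma**: a point mass at exactly 1 ("no effect") mixed
  with a gamma density.  Defaults $\pi_h = 0.5^{1/3}$ — so the joint null
  $\gamma_1 = \gamma_2 = \gamma_3 = 1$ carries prior probability exactly
  $0.5$ — and $a_{0h} = b_{0h} = 0.1$, a heavy-tailed alternative.

Because the sampler sets the point-mass state *exactly*, the posterior
probability of no follicular-length effect is estimated as the fraction of
draws with $\gamma_h$ literally equal to 1; no density estimation or
approximate window is involved.

## Posterior computation

The sampler augments each cycle/day with independent latent counts
$W_{ik} \sim \text{Poisson}(\lambda_k \xi_i X_{ik})$ and identifies the
outcome with the event "no count anywhere": $Y_i = 1 \iff \sum_k W_{ik} = 0$.
This reproduces the likelihood exactly and yields a clean Gibbs scan:

1. **Latent counts.** Female cycles: $W_{i\cdot} = 0$.  Male cycles: the
   total is zero-truncated Poisson with rate
   $\eta_i = \xi_i \sum_k X_{ik}\lambda_k$ (drawn by inverse-CDF on the
   conditioned law — exact, no rejection loop that could stall at small
   rates), allocated across intercourse days multinomially with
   probabilities $\propto \lambda_k$ (drawn by sequential binomial
   thinning, which is an exact multinomial and vectorizes over cycles).
2. **Day parameters.** Conjugate:
   $\lambda_k \mid \cdots \sim \mathcal{G}(a_{0k} + \sum_i W_{ik},\;
   b_{0k} + \sum_i X_{ik}\xi_i)$.
3. **Class multipliers.** For $h = 1, 2, 3$ in a fixed scan, with
   $A_h = \sum_{i: z_i > h}\sum_k W_{ik}$ and
   $B_h = \sum_{i: z_i > h}\sum_k X_{ik}\lambda_k
   \prod_{h' < z_i, h' \ne h}\gamma_{h'}$, set $\gamma_h = 1$ with
   probability
   $\pi_h e^{-B_h} \big/ \big[\pi_h e^{-B_h} + (1-\pi_h)
   \tfrac{b_{0h}^{a_{0h}}}{\Gamma(a_{0h})}
   \tfrac{\Gamma(a_{0h}+A_h)}{(b_{0h}+B_h)^{a_{0h}+A_h}}\big]$,
   otherwise draw $\gamma_h \sim \mathcal{G}(a_{0h}+A_h,\, b_{0h}+B_h)$.
   The mixture weight is evaluated in log space, so latent totals in the
   thousands cannot overflow.

All moves are exact conditional draws; there is no acceptance bookkeeping.
The scan order is fixed (latents, $\lambda_1 \dots \lambda_{12}$,
$\gamma_1, \gamma_2, \gamma_3$) for determinism and simpler testing; a random
scan would change nothing about validity.  Initialization draws $\lambda$
from the prior and starts every $\gamma_h$ at 1, inside the point-mass state,
so both mixture branches are exercised from the first iterations.  Chain $c$
is seeded with `seed + c` using the Mersenne-Twister generator, so any run is
reproducible to the bit on any platform.

Defaults follow the original analysis scale: burn-in 5,000 and 40,000
retained iterations.  Two chains are the default: the Gelman–Rubin statistic
needs at least two, and the cost is linear.

### Validation strategy

The exact full conditionals above are stated as contracts and verified two
independent ways, neither of which shares code with the sampler:

* **`brute_force_posterior()`** evaluates prior × likelihood in closed form
  (no augmentation) on a tensor grid for reduced models with at most three
  free dimensions, with the $\gamma_1$ point mass as an explicit atom.  Each
  continuous dimension is discretized at midpoint prior quantiles
  ($(j-\tfrac12)/m$), i.e. a midpoint rule in prior-probability space; this
  absorbs the integrable singularity of the $\mathcal{G}(0.1, 0.1)$ density
  at zero and makes every node carry equal prior weight $1/m$.  The
  discretization error vanishes as $m$ grows; the practical error check is
  doubling $m$, and the test suite verifies monotone refinement against a
  conjugate closed form.
* **A prior-preservation (successive-conditional) test** draws parameters
  from the prior, simulates outcomes, then alternates one full Gibbs sweep
  with outcome re-simulation.  The parameter marginals of this joint chain
  must stay at their priors; the tests check the $\mathcal{G}(1,1)$ mean and
  quartiles for every $\lambda_k$ and the exact point-mass frequency
  $\pi_h$ for every $\gamma_h$, with Monte-Carlo error bands based on
  effective sample sizes.  Most sampler bugs (a wrong sufficient statistic,
  a missing exposure term) move these marginals far outside the bands.

## Summaries and diagnostics

`summarize_posterior()` reports the posterior mean, median, SD and the 95%
equal-tailed credible interval (2.5% and 97.5% empirical quantiles) per
parameter, plus $\hat P(\gamma_h = 1)$ for the multipliers.  Equal-tailed
intervals are the reporting convention here; quantiles use the inverse
empirical CDF with linear interpolation (`stats::quantile()` type 7), stated
so summaries are reproducible to the digit.  Diagnostics follow standard
practice: Geweke $z$ (first 10% vs last 50%, spectral variance, via `coda`),
the classic Gelman–Rubin PSRF $\sqrt{((n-1)/n\,W + B/n)/W}$ — implemented
directly because its degenerate minimum $\sqrt{(n-1)/n}$ at zero
between-chain variance is part of the tested contract — and effective sample
size $n/(1 + 2\sum_t \rho_t)$ with Geyer's initial-positive-sequence
truncation.  Constant chains raise a defined error rather than returning a
silent 0; the table-level wrapper records `NA` and continues.

## The synthetic generator

The individual-level study data (521 conception cycles joined from two
prospective fecundability studies) are available only on request, so the
package ships a generator that reproduces their *reported* structure and
makes every module testable:

* per-day intercourse probabilities equal to the published marginal relative
  frequencies (20.34%, 17.66%, 23.80%, 25.53%, 29.37%, 23.03%, 31.67%,
  29.56%, 38.96%, 24.57%, 19.19%, 18.62% for days $-8 \dots +3$);
* follicular-class probabilities 28.21%, 29.75%, 22.84%, 19.19%
  (renormalized to sum exactly to 1);
* default $n = 521$ cycles; true parameters $\lambda_k \equiv 0.5$,
  $\gamma = (1,1,1)$ — a flat day profile at the scale of the prior mean,
  with no follicular effect, matching the study's headline finding of no
  follicular-length association;
* sex outcomes drawn from the model itself at those parameters.

Choices a user should know about:

* **Independence across days.**  Only the marginals are published; the
  joint distribution of intercourse days is unidentifiable from them.  Days
  are generated independently.  The inference model conditions on the
  indicators, so this affects the information content of a synthetic
  dataset, not the correctness of the fit.
* **All-zero cycles are redrawn** (default), so $n$ is exact and every cycle
  passes validation; this inflates each per-day marginal by the factor
  $1/(1 - \prod_k(1 - p_k)) \approx 1.05$ at the defaults, and the tests
  check marginals against the adjusted targets.
* **Representative lengths.**  Each class gets a mid-bin length (12, 15, 18,
  and 22 for the open-ended class) — only the class enters the model.
* **Not emulated:** within-woman dependence across her cycles (the written
  model has no such term either), non-conception cycles, daily mucus scores,
  and the measurement difference between the two studies' peak-day
  definitions.  Passing tests therefore demonstrate correctness of the
  machinery under the model's own assumptions, not robustness to violations
  of them in real data.

## Problem sizes used in the shipped checks

Oracle comparisons run reduced models (one or two active days, 20–30 cycles,
quadrature grids of 200–300 nodes per dimension).  Parameter recovery uses
10 replicate datasets of $n = 2000$ at the null truth (burn-in 1,000 +
5,000 retained draws each) — at that size the 95% intervals should cover the
true $\lambda$ at nominal rate and the posterior null mass on each
$\gamma_h$ should rise above its prior $\pi_h$ — and 3 replicates of
$n = 5000$ at $\gamma_1 = 3$, where the posterior null mass should collapse
below 0.05.  The prior-preservation chain runs 3,000 sweeps on a 30-cycle
design.  These sizes give Monte-Carlo error bands tight enough for 3–4
standard-error checks while keeping a full run of the suite comfortable on a
single CPU.

## Known limitations

* The multiplier structure forces a *monotone-in-class* dose-response on the
  log-hazard scale per $\gamma_h$; interactions between day and follicular
  class are out of scope.
* Cycles of the same woman are treated as independent; no woman-level random
  effect is provided.
* A cycle whose only information is "no fertile-window intercourse" cannot
  be represented — by design.
* `brute_force_posterior()` refuses more than three free dimensions; it is
  an oracle, not a fitting routine.
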