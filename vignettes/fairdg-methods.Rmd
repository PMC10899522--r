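---
title: "Modelling fairness decisions in framed dictator games with fairdg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fairness decisions in framed dictator games with fairdg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairdg)
```

## The task and its arithmetic

`fairdg` analyses a modified dictator game. On each round a dictator
receives `T` tokens and keeps `T_s` of them, sending the remaining
`T_o = T - T_s` to an anonymous recipient. Tokens convert to cents at an
exchange ratio `(r_s : r_o)`: the dictator's payoff is `M_s = r_s T_s`
and the recipient's is `M_o = r_o T_o`. Five ratios are crossed in the
design (3:1, 2:1, 1:1, 1:2, 1:3). Two within-subject factors complete
the design: *Role* — the dictator allocates for themself (first-party)
or on behalf of another dictator (third-party) — and *Frame* — tokens
convert to gains or to losses. In the loss frame both payoffs carry a
negative sign; this is the representation under which the purely selfish
strategy keeps 100% of the budget in the gain frame and 0% in the loss
frame, which is how the task's selfish reference rule is defined. The
four role-by-frame combinations are indexed `k = 1..4` (first/gain,
first/loss, third/gain, third/loss).

Choices are analysed as kept fractions `T_s / T`, so rounds with
different budgets are comparable. Two model-free scores summarize each
choice: the *selfish deviation* (distance from the payoff-maximizing
rule, `|1 - c|` in gain and `c` in loss for kept fraction `c`) and the
*equal deviation* (distance from the payoff-equalizing kept fraction
`r_o / (r_s + r_o)`, which is 75% at ratio 1:3 down to 25% at 3:1).

## Utility models and choice rule

Five candidate utility functions map a payoff pair to a subjective
value, all nested around the Fehr–Schmidt inequity-aversion form:

* **M1** `U = M_s - alpha_k * max(M_s - M_o, 0)` — only advantageous
  inequity (being ahead) matters. Negative `alpha_k` is
  *advantage-seeking*: being ahead adds utility.
* **M2** `U = M_s - beta_k * max(M_o - M_s, 0)` — only disadvantageous
  inequity (being behind) matters.
* **M3** `U = M_s - omega_k * |M_s - M_o|` — inequity matters but the
  two directions are not dissociated. The absolute difference is used;
  the alternative reading (a signed difference) would make M3 a linear
  altruism/spite model rather than an inequity model, which does not
  match its role as the "undifferentiated aversion" candidate.
* **M4** both `alpha_k` and `beta_k`, unconstrained.
* **M5** as M4 with `alpha_k, beta_k > 0` — pure aversion, no
  advantage-seeking. Comparing M4 and M5 is what lets the analysis
  detect advantage-seeking: if children's first-party `alpha` is truly
  negative, M5 cannot express it and loses the information-criterion
  race.

Choice probabilities follow a softmax over all `T + 1` whole-token
allocations: `P(j) = exp(lambda U_j) / sum(exp(lambda U_j'))`. The
inverse temperature `lambda` (units 1/cents) is shared across the four
conditions — the choice rule carries no condition subscript — and is
strictly positive in estimation; `lambda = 0` (uniform choice) is
permitted in simulation and diagnostics. Utilities are computed on raw
cent payoffs with no normalization, and every softmax goes through a
log-sum-exp guard so `lambda |U|` up to at least 1e4 cannot overflow.

## Synthetic cohorts

Because the analysis is validated entirely on simulated data, the
generator is a first-class module. A schedule reproduces the protocol:
4 blocks (one per condition) of 20 rounds, each ratio exactly 4 times
per block (the only balanced assignment of 5 ratios to 20 rounds),
block order following a balanced 4x4 Latin square cycled over
participants. Token budgets are drawn from {12, 24, 36, 48}; multiples
of 12 make the equal split a whole number of tokens at every ratio, so
perfectly equitable agents are exactly representable. The default
group sizes are 34 (children) and 31 (adults), typical of developmental
samples of this kind.

Agents are generated hierarchically: condition-k weights are drawn from
`Normal(mu_0k, sigma_0k)` on the scale the model samples on (identity
for unconstrained weights, log for `lambda` and for M5's constrained
weights). The default group-level means are the child-like and
adult-like condition profiles (advantage-seeking first-party `alpha`
for children, uniformly positive `alpha` for adults, positive `beta`
everywhere); `sigma_0 = 0.5` for weights and
`lambda ~ exp(Normal(log 0.3, 0.5^2))` were chosen once as a realistic
degree of individual heterogeneity and choice determinism — with cent
payoffs in the tens, `lambda ~ 0.3` produces clearly patterned but
noisy choices, neither random nor rigid. One master seed drives
per-participant substreams, so cohorts are reproducible regardless of
generation order.

What the generator does *not* emulate: response times, within-trial
mouse dynamics, attention lapses, missingness, or any drift across the
session. Passing tests therefore demonstrate that the estimation and
comparison machinery is correct and well calibrated *for the assumed
generative family*, not that real children or adults obey it.

## Behavioral analysis

Deviation scores are averaged per participant and condition cell and
enter a 2 (Role) x 2 (Frame) within x 2 (Group) between mixed ANOVA.
The decomposition is computed from sums of squares on per-subject
orthogonal contrasts: the between stratum tests Group on subject means,
and each within stratum tests one within effect and its Group
interaction against that stratum's subject-level error. Main effects
are unweighted (Type III), so the unequal group sizes are handled; with
two-level factors sphericity is automatic. Partial eta squared is
`SS_effect / (SS_effect + SS_error)`. The implementation is deliberately
written from the sums of squares themselves (not delegated to `aov`) so
that an independent oracle test against `aov`'s stratum decomposition
is meaningful; a 400-replicate null simulation additionally checks the
type-I rate of every effect at the 5% level.

Post-hoc simple effects for the Role x Group interaction report group
differences within each role (pooled-variance comparison of per-subject
role means, averaged over frames) and role differences within each
group (paired comparison). P-values are uncorrected by default, with a
Bonferroni flag; the group post-hocs average over frames because the
interaction of interest is Role x Group.

## Hierarchical Bayesian estimation

Each between-subject group is fitted independently. Individual
condition-k parameters are drawn from `Normal(mu_0k, sigma_0k)`
populations on the unconstrained scale, with `mu_0 ~ Normal(0, 1)` and
`sigma_0 ~ half-Cauchy(0, 2)` priors. Positivity (always for `lambda`,
for `alpha`/`beta` under M5) is handled by a log link: the hierarchy
lives on the log scale and draws are exponentiated. The prior family
and scales are configurable through `prior_spec()`; note that the
default `Normal(0, 1)` mean prior is deliberately weak only near zero —
group means of magnitude 2–4 (as inequity weights often are) sit in its
tail and are noticeably shrunk when the likelihood is weak. This
matters mostly for `beta` in cohorts that almost never choose
below-equal allocations, where the likelihood only bounds the weight
from below.

Sampling uses an adaptive Metropolis-within-Gibbs scheme written for
this model family, with the trial-level softmax log-likelihood in
compiled code:

* individual weights and `log lambda`: random-walk Metropolis, one
  scalar at a time, proposal scales tuned in warmup batches of 25
  toward the 0.44 optimal scalar acceptance rate;
* population means: conjugate Gibbs draws (normal likelihood in the
  individual draws, normal prior);
* population sds: random-walk Metropolis on the log scale, *plus* an
  interweaved non-centered move that holds the standardized residuals
  `z = (theta - mu)/sigma` fixed and rescales `sigma` jointly with all
  individual values. This second move is what defeats the funnel
  geometry of hierarchical scales at small n; without it the population
  sds mix an order of magnitude more slowly.

The default configuration matches the study protocol: 3 chains, 2000
warmup and 2000 retained iterations each, 6000 saved draws. A `thin`
option trades iterations for autocorrelation at fixed storage.
Convergence is monitored with split-chain Gelman–Rubin R-hat; fits with
any R-hat above 1.01 are flagged (warning plus `converged = FALSE`),
never silently accepted. Initialization draws from jittered priors with
the half-Cauchy scale clamped to a moderate range (0.4–1.2) — an
initialization choice only, not a prior truncation; failed chains are
retried with fresh jitter before erroring. Random-walk samplers need
longer chains than gradient-based ones for the same effective sample
size; the package's tests run reduced configurations (2 chains,
400–600 warmup and draws, 12–15 participants) chosen so that posterior
means and 95% intervals are stable while a full test run stays in the
minutes range. A long-run check (3 chains, 2000 + 3000 thinned
iterations, 15 participants) reaches max split R-hat ≈ 1.02 with
posterior means matching a well-identified generator.

## Model comparison

Pointwise log-likelihoods for every saved draw and trial feed WAIC
(`-2(lppd - p_waic)`, log-sum-exp throughout) and PSIS-LOO. The PSIS
implementation follows the standard recipe: per trial, the largest 20%
of log importance ratios are tail-fitted with a generalized Pareto
distribution (Zhang–Stephens profile-likelihood estimator with the
usual weak prior pulling the shape toward 0.5), replaced by expected
order statistics, truncated at the raw maximum; trials with shape
`k > 0.7` are flagged. A posterior concentrated at a point is handled
exactly and reproduces WAIC. Model weights are Akaike-type
(`exp(-Delta/2)`, normalized — so a 10-point score difference is about
a 148:1 weight ratio); stacking weights over the pointwise elpd matrix
are available behind a flag since the literature uses both. The winner
is declared by LOOIC with WAIC breaking ties, LOOIC being the primary
criterion throughout.

## Posterior predictive checks and evidence rules

`posterior_predict()` re-simulates the task from a fitted model, by
default once per participant from posterior-mean parameters (the
simplest reading of individually generated synthetic data), optionally
from multiple joint posterior draws. `ppc_correlations()` correlates
actual and simulated per-participant mean kept fractions within each
condition (across participants) and per-round-position means averaged
over participants (across the 20 trial positions; a flag switches to
concatenated participant-trials instead), and reruns the mixed ANOVA on
the simulated data for behavioral recovery. Zero-variance cells yield
an explicit undefined-correlation flag rather than NA propagation.

Evidence for a parameter or contrast differing from zero is
categorized from highest-density intervals computed by the
shortest-window method on sorted draws: *meaningful* if the 97.5% HDI
excludes zero, *limited* if only the 85% HDI does, *none* otherwise;
reports always carry the posterior mean and 95% HDI for display. Both
the 97.5% and 95% intervals are computed because reporting conventions
differ on which one accompanies the decision rule.

Condition contrasts on group-level means sum over the collapsed factor
(role contrast `(k1 + k2) - (k3 + k4)`, frame contrast
`(k1 + k3) - (k2 + k4)`): summing, not averaging, is the convention
uniquely consistent with published contrast magnitudes for this task
family, and the package's tests document the identity on the printed
condition means. Cross-group contrasts difference two independent fits
draw-wise after a seeded within-fit shuffle, preserving the marginal
posteriors while removing chain-order artifacts; unequal draw counts
are resampled to match, with a warning.

## Calibration experiments

Two simulation studies back the estimation machinery, at sizes chosen
to keep a full run in the minutes range:

* **Recovery**: a 15-participant cohort with advantage-seeking
  first-party `alpha` (-0.2), aversive third-party `alpha` (+2),
  `beta = 2.5`, `sigma_0 = 0.5`, fitted at 2 chains x (500 + 500). The
  correlation between true and posterior-mean individual `alpha` across
  participants and conditions exceeds 0.7 by a wide margin (~0.97).
* **Interval calibration**: 10 cohorts of 12 participants whose
  group-level means are themselves drawn from the `Normal(0, 1)` prior,
  fitted at 2 chains x (400 + 400); 95% HDIs for the 8 group-level
  weight means must cover the generating values at >= 80%. Drawing the
  truths from the prior makes coverage a well-defined property of the
  implementation; with truths fixed deep in the prior's tail the
  Normal(0, 1) mean prior shrinks weakly identified parameters (see
  above) and nominal coverage is not expected — that is a property of
  the prior, not a defect of the sampler, and the prior is kept literal
  because it is part of the method being implemented.

Model recovery is checked the same way: data generated from M4 with
`alpha != beta` must be won by M4 or M5 under LOOIC, and data generated
from M1 must not see M1 beaten by M2 by more than the 10-point
decisiveness threshold.

## Known limitations

* The sampler is random-walk based; for much larger cohorts or models
  with many more parameters per participant a gradient-based sampler
  would scale better.
* `beta` is only weakly identified for near-perfectly equitable agents
  (the likelihood bounds it from below), so its group mean inherits
  prior shrinkage; report HDIs, not point estimates, for such cohorts.
* The generator and likelihood assume a single `lambda` per participant
  and independence across trials; sequential effects (fatigue,
  anchoring on the previous round) are outside the model family.
* Third-party trials are modelled with the same utility arithmetic as
  first-party trials (the represented dictator's payoff plays the role
  of `M_s`), which is the task's intended reading but is itself a
  modelling assumption.
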