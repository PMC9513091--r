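---
title: "Temporal discounting models of procrastination: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal discounting models of procrastination: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procrastinatr)
```

# The modeling problem

Why do people postpone a chore they could finish today, day after day,
until a deadline forces them? This package implements a decision-theoretic
account in which procrastination emerges from *differential temporal
discounting* of costs and benefits, and provides everything needed to
study that account quantitatively: a subjective-valuation step, a family
of discounting choice models with Bayesian model comparison, a one-shot
now/tomorrow choice model, and two generative models of recurrent
completion delay. Because the package is designed to be testable without
any empirical data set, it also ships a synthetic-data generator that
emulates the statistical structure of the behavioral study design it
models.

# Subjective valuation

Participants rate, for each item in a catalog of rewards (e.g., food,
goods), efforts (cognitive, motor) and punishments (bodily, abstract),
the quantity they judge equivalent to gaining or losing 1€ (`q1`) and 5€
(`q5`). `unit_value()` averages the two per-euro quantities,
$Q = (q_1 + q_5/5)/2$, and inverts, $v = 1/Q$ euros per unit.

The rating-averaging sentence this rule implements is genuinely
ambiguous between averaging per-euro *quantities* then inverting
(`method = "quantity"`, the default — the literal reading) and averaging
the two implied per-unit euro values $1/q_1$ and $5/q_5$
(`method = "euro"`). The two agree exactly for self-consistent ratings
($q_5 = 5q_1$) and differ by harmonic-vs-arithmetic averaging otherwise;
both are exposed rather than silently choosing. Option values are linear
in quantity — a deliberate first-order approximation appropriate for
values of a few euros; no power-utility fitting is included.

# Discounting families and the choice rule

Four families generate the discounted value of an option offering $N$
units of item $i$ at delay $D$ days:

* **hyperbolic, category-specific**: $V = N R_i / (1 + k D)$ with
  separate rates $k_R, k_E, k_P$ per outcome category;
* **hyperbolic, shared**: one rate for all categories;
* **present bias**: $V = \beta N R_i$ for $D > 0$, undiscounted at
  $D = 0$;
* **quasi-hyperbolic (βδ)**: $V = \beta\,\delta^D N R_i$ for $D > 0$,
  undiscounted at $D = 0$.

Choices follow the softmax $P(A) = 1/(1 + e^{-\theta(V_A - V_B)})$ with
inverse temperature $\theta$ (per euro). The implementation is
overflow-safe (hard 0/1 limits for extreme drive) and likelihoods clip
probabilities at $10^{-12}$ so log-likelihoods stay finite.

Aversive categories use a single sign convention: the discounted *cost*
enters the softmax negated, so the model prefers the option with the
lower discounted cost. One code path then serves all categories, and it
reproduces the characteristic preference for *later* efforts: raising
$k_E$ makes delaying a cost more attractive.

Whether the β and βδ models should carry one bias parameter per category
is not determined by the design they mirror; the package fits one shared
β (and δ) across categories, the most parsimonious reading, and the
family tag records exactly what was fitted.

# Now/tomorrow choices and recurrent delay

A now/tomorrow offer pairs $N_R$ units of a reward with $N_E$ units of
an effort; its net value at delay $D \in \{0, 1\}$ is

$$V = \frac{N_R R_i}{1 + k_R D} - \frac{N_E E_j}{1 + k_E D}.$$

Both components share the same delay — the one-day postponement moves
reward and effort together. The discount rates are *rigidly
incorporated* from the intertemporal-choice stage: `fit_now_tomorrow()`
exposes a single free parameter, the inverse temperature, so the model's
predicted procrastination level is driven entirely by independently
measured time preferences. With $k_E > k_R$ there exist offers whose
undiscounted net value is positive yet whose tomorrow option dominates —
the core mechanism the package exists to study.

The home task (reward $R$ on completion, effort cost $E$, deadline $D$
days) admits two accounts:

* **static** (`static_optimal_delay()`): one pre-committed choice of the
  day maximizing $V_d = R/(1+k_R d) - E/(1+k_E d)$; ties break toward
  the earliest day. When $k_R \ge k_E$ (and $R > E$) the optimum is
  always day 0, so any systematic delay requires steeper effort
  discounting.
* **dynamic** (`dynamic_completion_distribution()`): the decision is
  repeated each day. The completion hazard on day $d$ is the softmax
  probability of acting now against all remaining days
  ($e^{\theta V_0} / \sum_{t=0}^{D-d} e^{\theta V_t}$), with values
  re-discounted from the current day (a time-invariant value function
  over a shrinking horizon — this is what makes the deadline bite). The
  hazard equals 1 on the deadline day by construction, so the CDF
  reaches exactly 1 and the expected delay
  $\sum_d d\,P(\tau = d)$ is always well defined.

The static model's argmax readout is degenerate as a likelihood (it puts
mass on a single day), so likelihood-based comparison always scores the
static account through its softmax readout; `delay_loglik()` refuses the
argmax mode.

# Inference

Models are fitted per participant by MAP estimation with
Laplace-approximated log model evidence (`fit_map()`):

$$\log m \approx \log p(y \mid \hat\vartheta) + \log p(\hat\vartheta)
 + \tfrac{p}{2}\log 2\pi - \tfrac12 \log \det H,$$

with $H$ the Hessian of the negative log posterior at the MAP, computed
by central finite differences (`pracma::hessian`) and jitter-regularized
(and flagged) if not positive definite. The optimizer is BFGS with a
Nelder–Mead fallback, restarted from the prior mean plus prior draws
(10 restarts by default, deterministic given the seed).

Priors follow the convention of the study design: standard normal on the
native-scale discount rates, and standard normal on $\log\theta$ — which
preserves the stated prior location of 1 as the prior *median* of
$\theta$ while respecting $\theta \ge 0$. β is given a standard normal
prior on the logit scale (median 0.5). δ's logit-scale prior is centered
at 2.2 (median 0.9): δ is a *daily* exponential factor, so mass near 0.5
would imply implausible total discounting ($0.5^{30} \approx 10^{-9}$
over a month); centering the prior near 1 reflects what a daily factor
can plausibly be, not any property of a particular data set. Rates are
fitted on the native scale (keeping their stated Gaussian priors
literal) with the hyperbolic guard $1 + kD > 0$ enforced through the
likelihood.

Two subtleties of Laplace model comparison are worth recording. First, a
*fully inert* extra parameter with a standard normal prior integrates
out exactly — its prior, Hessian and normalization terms cancel — so it
carries no complexity penalty; the penalty appears for parameters that
interact with the likelihood, as in the nested shared-vs-specific
hyperbolic comparison the test suite uses. Second, on one- and
two-parameter posteriors the Laplace value agrees with direct numerical
integration to well under 0.1 nats at the trial counts used here, which
is the regime in which group-level summed-evidence comparisons (log
group Bayes factors, `compare_models()`) are trustworthy.

Fit diagnostics mirror standard practice: `balanced_accuracy()` averages
per-class accuracies at a 0.5 threshold (a predicted probability of
exactly 0.5 counts as half correct — unbiased under chance), and
`calibration_bins()` splits trials into eight equal-count bins of
modeled probability, flagging degenerate cases.

# The synthetic-data generator

`population_spec()` / `generate_dataset()` emulate the behavioral study
design end to end:

* **Discount rates** are log-normal across participants — rates are
  positive and right-skewed — with default medians $k_R = 0.06$,
  $k_E = 0.15$, $k_P = 0.10$ per day (sdlog 0.5). The ordering
  median $k_E >$ median $k_R$ is the empirically observed population
  tendency and is what makes procrastination possible at all; the
  punishment rate sits in between. The magnitudes are conventions chosen
  to put indifference points inside the 0–30-day delay window, not
  values taken from any data set.
* **Inverse temperature** is log-normal with median 2 per euro (sdlog
  0.3), giving choice accuracy in the high-but-stochastic regime
  typical of such tasks.
* **Ratings** invert a latent log-normal per-unit value (median 0.4
  €/unit) with multiplicative log-normal jitter (sdlog 0.1) on each of
  the two questions; no further response model (truncation, anchoring)
  is simulated.
* **Choice sets** draw the two delays from the standard ten-delay set
  {0, 1, 2, 3, 5, 7, 10, 14, 21, 30}, never repeat an item within a
  block, and adjust quantities so the discounted-value differences under
  an a-priori rate cover a uniform grid (default ±4€) — the
  "evenly sample the value space" calibration. The target difference is
  inverted for the later quantity and rounded to the nearest positive
  integer; the delay pair is resampled when the later/greater-quantity
  constraint cannot be met, and strongly negative targets raise the
  sooner option's base value so they stay reachable. Rounding noise is
  negligible at the default unit values, and the uniformity of realized
  differences is property-tested.
* **Now/tomorrow offers** draw reward values and effort costs from the
  same uniform distribution (default 1–10€), as in the task design.
* **The home task** gives each participant a compensation drawn from
  40–60 and a rated form-filling cost from 20–40 (the reference
  simulation ranges, in arbitrary units) and simulates the return delay
  under the dynamic model with $\theta = 0.5$ and a 30-day deadline; one
  decision per day (the decision rate is exposed as a knob for
  reminder-style extensions but defaults to 1/day).
* **Covariates** (age ~ 23 ± 2.5, bounded 18–40; gender ≈ 60% coded 1;
  a 1–5 questionnaire score) are generated independent of the
  parameters by default, so regressions on them are null tests.

Value normalization deserves its own note. When *fitting* observed
delays, net values are normalized per participant (default: divide by
the maximum absolute net value over the horizon; z-scoring is the
documented alternative) to absorb interindividual differences in value
range — participants' subjective units differ, and θ would otherwise be
confounded with unit scale. When *simulating* populations that share one
arbitrary-unit scale (the generator and the rate-plane grid), there are
no unit differences to absorb, and the defaults therefore apply the
softmax to raw values — the regime of the reference grid simulations
(θ = 0.5 with values of tens of a.u.). Normalizing there would make
every completion distribution nearly uniform and erase the structure
over the rate plane. Both paths accept the same `normalize` flag.

What passing tests on these data do and do not show: the generator
reproduces the *statistical structure* the analyses assume — softmax
choices under known parameters, rating noise, the designed choice sets,
dynamic-model delays — so green tests demonstrate internal consistency
of the pipeline (parameter and model recovery, sign patterns, calibration)
under those assumptions. They cannot certify that real participants
satisfy the assumptions (linear utility, stable rates across tasks,
one decision per day), which is an empirical question.

# Numerical choices and degenerate inputs

* Probabilities clipped at $10^{-12}$ in all Bernoulli likelihoods.
* Softmax and hazards computed with max-shifted exponentials; the
  deadline-day hazard is exactly 1 by construction, not by rounding.
* Hessian regularization by escalating diagonal jitter, flagged in the
  fit; optimization failures are flagged results, never exceptions.
* Argmax ties resolved toward the earliest day (conservative and
  deterministic).
* Zero trials: the MAP is the prior mean. Zero free parameters: the
  evidence is the log-likelihood exactly. Single-class data in balanced
  accuracy, and degenerate probability vectors in calibration, return
  flagged results instead of NaN.
* Negative rates are admitted down to the guard $k > -1/D_{max}$
  (negative time preference is a real phenomenon under some framings),
  but priors and defaults center on positive rates.
* Every stochastic function is a pure function of its inputs and a
  `seed` argument, and restores the caller's RNG state.

# Problem sizes

The test suite and the acceptance script run everything at sizes chosen
to exercise the claims meaningfully on a desktop: parameter recovery at
50 participants × 120 trials per category (40 in the acceptance script),
model recovery at 20 replications × 6 participants × 180 trials,
generative-chain sign checks at 20 replications × 43 participants,
Monte-Carlo validation of the completion-time expectation at $10^5$
simulated agents per task, and the rate-plane grid at $2 \times 10^4$
sampled tasks (the grid function scales to arbitrarily many samples).

# Known limitations

* No hierarchical (random-effects) pooling across participants; fits are
  per participant with fixed priors, and group Bayes factors are
  fixed-effects sums.
* The variational scheme the design descends from is approximated here
  as MAP + Laplace; on near-Gaussian posteriors they coincide, but
  heavy-tailed or multimodal posteriors are only guarded by multistart.
* No reaction-time or sequential-sampling modeling; no
  anticipation/dread utility for dated aversive events; no modeling of
  never-returners (their delays are treated as missing, matching the
  exclusion convention).
* The now/tomorrow model ties reward and effort to the same delay;
  separate delays are a documented possible generalization, off by
  default.
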