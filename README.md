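# procrastinatr

Computational models of procrastination grounded in temporal discounting,
for behavioral scientists studying intertemporal choice and real-world
task-completion delay.

The core idea: completing a task yields a delayed benefit (a reward *R*)
and an upfront cost (an effort *E*), both of which lose subjective value
with delay — but possibly at *different rates*. If effort is discounted
more steeply than reward (k<sub>E</sub> > k<sub>R</sub>), postponing a
chore makes its cost shrink faster than its benefit, so "tomorrow" can
look better than "now" every single day. Repeated daily, that one-step
bias produces long completion delays that end only when a deadline
forces the issue.

## Models

**Valuation.** Monetary-equivalence ratings (the quantity of an item
judged worth 1€ and 5€) are converted to per-unit values
`v = 1 / ((q1 + q5/5) / 2)` euros, and option values scale linearly in
quantity.

**Discounted value.** Hyperbolic discounting

&nbsp;&nbsp;V = N·R<sub>i</sub> / (1 + k·D)

with category-specific rates (k<sub>R</sub>, k<sub>E</sub>,
k<sub>P</sub> for reward, effort, punishment), compared against a shared
single-rate variant, a present-bias model (V = β·N·R for D > 0) and a
quasi-hyperbolic βδ model (V = β·δ<sup>D</sup>·N·R for D > 0). Choices
are stochastic through a softmax,
P(A) = 1/(1 + e<sup>−θ(V_A − V_B)</sup>).

**Now/tomorrow choices.** An offer combining reward and effort is
evaluated at delay D ∈ {0, 1} by the net value
V = N<sub>R</sub>R<sub>i</sub>/(1 + k<sub>R</sub>D) −
N<sub>E</sub>E<sub>j</sub>/(1 + k<sub>E</sub>D); discount rates are
rigidly incorporated from the intertemporal-choice fits and only θ is
free.

**Recurrent delay under a deadline.** The *static* model picks the day
d\* = argmax<sub>d</sub> [R/(1 + k<sub>R</sub>d) − E/(1 + k<sub>E</sub>d)]
once. The *dynamic* model repeats the decision daily: the completion
hazard on day d is the softmax probability of "now" against every
remaining day before the deadline, which equals 1 on the deadline day;
the predicted procrastination duration is the expectation of the
resulting completion-time distribution.

**Inference.** Models are fitted per participant by MAP estimation under
Gaussian priors (rates on the native scale, θ on log, β/δ on logit
scale), with the log model evidence from the Laplace approximation and
group-level comparison by summed evidence (log group Bayes factors).

## Worked example

```r
library(procrastinatr)

# 1. generate a synthetic cohort: 43 participants, 30-day deadline
spec <- population_spec(n_participants = 43, seed = 42)
dataset <- generate_dataset(spec, n_trials_per_category = 60)
#> <synthetic_dataset> 43 participants; 7740 intertemporal trials; 6450 now/tomorrow trials

# 2. fit the category-specific hyperbolic model to every participant
fits <- fit_population_discounting(dataset$trials, "hyperbolic_specific",
                                   n_restarts = 4, seed = 1)
summary(fits[, c("k_R", "k_E")])
#>       k_R               k_E
#>  Median :0.06229   Median :0.17977
```

Recovered rates reproduce the generating population's signature —
steeper discounting for effort than for reward (median k̂<sub>E</sub> =
0.18 vs k̂<sub>R</sub> = 0.06 per day).

```r
# 3. which discounting family explains the choices best?
cmp <- compare_discounting_families(dataset$trials, n_restarts = 3, seed = 2)
round(cmp$comparison$group_evidence, 1)
#> hyperbolic_specific   hyperbolic_shared    quasi_hyperbolic        present_bias
#>             -2228.0             -2614.3             -2782.3             -4475.7
```

The category-specific hyperbolic family wins with a log group Bayes
factor of 386 over the runner-up, as expected for data generated under
it.

```r
# 4. predict the form-return delay for an illustrative task
task <- procrastination_task(R = 100, E = 85, k_R = 0.05, k_E = 0.2,
                             theta = 0.5, deadline = 30)
static_optimal_delay(task)
#> [1] 8
dynamic_completion_distribution(task)
#> <completion_distribution> days 0..30; expected delay 16.912 days
```

A pre-committing (static) agent with these preferences would plan to act
on day 8; the iterated daily decision process stretches the expected
delay to ~17 days.

```r
# 5. does effort discounting drive simulated procrastination?
sm <- cbind(dataset$population$participants,
            form_delay = dataset$form_delays$form_delay)
regress_procrastination(sm, outcome = "home")
#>          term   estimate      t  df        p
#>   (Intercept)      14.35   9.96  38  3.9e-12
#>           k_R      -7.35  -4.64  38  4.0e-05
#>           k_E       5.22   3.55  38  1.1e-03
#>           age      -0.15  -0.10  38  0.92
#>        gender      -1.17  -0.76  38  0.45
```

Simulated home delays load positively on the effort discount rate and
negatively on the reward rate — the dynamic model's defining
cross-participant pattern.

A command-line wrapper over the same functions is installed with the
package (`system.file("scripts", "procrastinatr", package = "procrastinatr")`),
with subcommands `synth`, `fit-discounting`, `compare-models`,
`fit-now-tomorrow`, `predict-delay`, `simulate-grid`, `group-analysis`
and `report`.

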