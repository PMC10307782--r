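---
title: "Modelling social-distance-modulated third-party punishment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling social-distance-modulated third-party punishment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tppunish)
```

## The task and the utility model

A third-party observer watches a dictator split 100 CNY with a recipient and
may spend part of a 50 CNY per-trial endowment to reduce the dictator's
payoff by three times the amount spent, choosing among seven options
(0, 5, ..., 30 CNY). Punishment is either deducted from the observer's
endowment (costly condition) or not (free/control condition). The dictator
is a person at a stated social distance SD from the observer
(1, 2, 3, 5, 10, 20, 50, 100; 1 = closest friend, 100 = stranger).

The third-party inequity-aversion (TPIA) utility of punishing by `p` is

$$U(x_1, x_2, x_3, p) = \max(x_3 - p,\, 0) \;-\;
  \gamma \,\bigl|\max(x_1 - 3p,\, 0) - x_2\bigr|$$

with $x_1$ the dictator's payoff, $x_2$ the recipient's, $x_3 = 50$ the
observer's endowment, and $\gamma \in [0, 1]$ the weight on
dictator–recipient inequity. Both `max(·, 0)` clamps are part of the task:
neither the observer's payoff nor the dictator's post-punishment payoff can
go below zero. In the free condition the observer's own term is $x_3$
without deduction, while punishment still reduces the dictator's payoff —
the condition removes only the cost, nothing else.

Social distance enters through one of four transforms applied before the
utility:

* **hyperbolic punishment** — $p = (1 + \frac{1}{k\,SD})\,p_{SD}$: the same
  nominal punishment *feels* larger when directed at a close other, so
  nominal punishment rises with distance;
* **hyperbolic inequity** — $\gamma = \sigma\!\bigl((1 + \frac{1}{k\,SD})\,
  \gamma_{SD}\bigr)$: inequity caused by a close other weighs more;
* **power punishment** — $p = p_{SD} + k\,SD^{W}$;
* **power inequity** — $\gamma = \sigma(\gamma_{SD} + k\,SD^{W})$,

where $\sigma$ is the logistic sigmoid. The sigmoid is our reading of a
scalar "softmax": it is the only standard squashing of a single real value
onto $(0, 1)$ consistent with the constraint $0 \le \gamma \le 1$, and it
lets the baseline $\gamma_{SD}$ of the inequity-level models take any real
value. For the punishment-level models $\gamma$ is the weight itself and is
kept in $[0, 1]$.

The transformed punishment replaces the nominal one at *every* occurrence of
$p$ in the utility — in the observer-cost term as well as the
dictator-reduction term. This is the literal composition of the two
equations; whether the original estimation substituted into the cost term
too cannot be determined from the published description, so the choice is
documented here rather than claimed as ground truth.

### A consequence worth knowing: the clamped regime

Because of the two payoff clamps, the hyperbolic punishment model has a
degenerate regime at small $k \cdot SD$: once
$(1 + \frac{1}{k\,SD})\,p_{SD}$ exceeds both the observer's endowment and
$x_1/3$ for every nonzero option, all nonzero punishments yield identical
utility and the softmax spreads choice nearly uniformly over them. Mean
punishment is then *not* monotone in SD (it is artifactually high at the
closest distances). At moderate discount rates (e.g. $k = 0.2$) the model is
in its intended regime and the model-implied mean punishment rises
monotonically with SD in the costly condition for all three allocations; in
the free condition the *optimal* option rises monotonically while the mean
oscillates slightly because the option grid is discrete. The test suite
asserts exactly these properties. A related boundary effect: when punishment
can overshoot (drive the dictator to zero), the residual inequity equals
$x_2$, so the best attainable utility can *increase* with the unfairness of
the split; the "utility falls with inequity" pattern holds whenever
overshoot cannot occur.

## Choice rule

The original description has subjects deterministically pick the
highest-utility option, which makes the likelihood degenerate. We therefore
use a softmax choice rule with inverse temperature $\beta > 0$,

$$P(p_j) = \frac{e^{\beta U_j}}{\sum_l e^{\beta U_l}},$$

fitted as a free parameter of every model (standard in this literature, and
the deterministic rule is the $\beta \to \infty$ limit). Exact utility ties
need no tie-breaking: the softmax gives them equal probability. The
implementation uses a log-sum-exp shift, so probabilities are invariant to
adding a constant to all utilities and stable at large $\beta$.

## Estimation

Each subject × model fit maximizes the penalized log-likelihood over
unconstrained transforms (logit $\gamma$ for the punishment-level models,
$\log k$, $\log \beta$, identity for $W$ and for the inequity-level
$\gamma_{SD}$), equivalent to MAP estimation under independent
$\mathcal N(0, 3^2)$ priors on the transformed parameters. The priors are
deliberately weak — at $\sigma = 3$ the implied 95% range for $k$ spans
roughly $e^{-6}$ to $e^{6}$ — and exist mainly to regularize degenerate
datasets (e.g. a subject who never punishes) where the pure ML estimate
diverges. The optimizer is BFGS with 10 starts by default: one central
start ($\gamma$ at the middle of its range, $k = 0.1$, $W = 1$,
$\beta = 0.5$) plus dispersed Gaussian perturbations (sd 1.5 on the
transformed scale), seeded for reproducibility. Trials without a response
and the quasi-fair filler trials are excluded from every likelihood; both
payment conditions enter one likelihood with shared parameters, since the
free-condition utility is fully specified above.

The log model evidence is approximated by Laplace's method at the posterior
mode,

$$\log p(y) \approx \log p(y \mid \hat\theta) + \log p(\hat\theta)
  + \tfrac{d}{2}\log 2\pi - \tfrac12 \log \lvert H \rvert,$$

with $H$ the numeric Hessian of the negative log joint. The priors the
original analysis used inside its variational toolbox are unreported, so
these are explicitly ours; the BIC-style evidence
($\mathrm{LL} - \frac{d}{2}\log n$) is available as an alternative and as
the automatic fallback when $H$ is not positive definite (flagged in the
fit). Because both approximations penalize dimensionality, the extra power
exponent must earn its keep — on data generated from a hyperbolic model the
simpler model's mean evidence is higher, which the tests assert.

Diagnostics per fit: convergence flag, number of successful starts,
parameters at extreme transformed values (|transformed| > 5), the Hessian
condition number, and *weakly identified* parameters — those whose
likelihood-only curvature at the mode (penalized Hessian minus the known
diagonal prior contribution) is below 1 nat. A subject who never punishes,
for instance, leaves the discount rate $k$ without curvature and it is
flagged.

## Random-effects model selection

Model identity is treated as a random effect across subjects: population
model frequencies $r \sim \mathrm{Dir}(\alpha_0)$ with $\alpha_0 = 1$
(uniform over frequencies, exposed in the interface), each subject's model
multinomial in $r$, and the data entering through the per-subject log
evidences. The variational posterior iterates responsibilities
$u_{nk} \propto \exp(\mathrm{ev}_{nk} + \psi(\alpha_k) - \psi(\sum\alpha))$
and $\alpha = \alpha_0 + \sum_n u_n$ to convergence. Exceedance
probabilities are Monte-Carlo estimates (default $10^6$ Dirichlet draws,
seeded); the two-model case has the closed form
$P(\mathrm{Beta}(\alpha_1,\alpha_2) > \tfrac12)$, kept as an analytic
cross-check. The Bayesian omnibus risk compares the variational free energy
of the random-effects model with that of the equal-frequency null,
$F_0 = \sum_n \bigl(\mathrm{logsumexp}_k\,\mathrm{ev}_{nk} - \log K\bigr)$,
via $\mathrm{BOR} = 1/(1 + e^{F_1 - F_0})$, and the protected exceedance
probabilities are $\mathrm{pEP} = \mathrm{EP}\cdot(1 - \mathrm{BOR}) +
\mathrm{BOR}/K$. Only within-subject evidence differences matter anywhere in
this machinery, which the tests verify directly.

## The synthetic-data generator

The generator reproduces the scanned protocol: 6 sessions × 54 trials; per
session 48 unfair targets covering all 24 SD × allocation combinations once
per condition, grouped 4 per block into 12 blocks (6 costly, 6 free, order
shuffled); 6 quasi-fair fillers (65 vs 35, 60 vs 40, 55 vs 45, each twice)
per session. The published description does not say whether fillers were
split evenly between conditions; the default places 3 in costly and 3 in
free blocks (`filler_assignment = "balanced"`), with `"any"` as the
alternative. Fillers get a random social distance — the protocol does not
specify one — and are simulated like any trial but flagged and excluded from
fitting, mirroring their role of preventing unfairness normalization rather
than measuring it. An optional miss rate injects no-response trials
(default 0), which load as missing and never enter likelihoods. One master
seed derives independent sub-streams for parameter draws, per-subject design
shuffles and choice sampling, so a population is reproducible from
`(model, priors, design, seed)`.

For recovery studies the default population distributions are
$\gamma \sim U(0.2, 0.8)$ (punishment-level models; $U(-1, 2)$ for the
unbounded baseline of the inequity-level models), $k \sim U(0.02, 0.5)$,
$\beta \sim U(0.2, 1.0)$, and $W \sim U(0.2, 1.0)$ for the power models —
dispersed enough that subjects differ qualitatively (the $k$ range spans the
clamped and the smooth regime) while staying in a behaviorally sensible
band.

What the generator does *not* emulate: reaction times, trial timing and
jitter, learning or order effects, and any systematic deviation from the
softmax-TPIA family itself. Passing recovery tests therefore show that the
estimation machinery is consistent — that parameters and the generating
model are recoverable *when the model family is true* — not that the models
describe real participants.

## Problem sizes and numerical choices

The package-level recovery analysis simulates 31 subjects × 288 target
trials (the study's sample size and per-subject trial count) from the
hyperbolic punishment model, fits all four models at default settings and
runs the BMS; unit tests use smaller populations (6–20 subjects, 3–6
optimizer starts) chosen to exercise the same code paths quickly. Dirichlet
exceedance probabilities use $10^5$–$10^6$ draws depending on the tolerance
being checked. The variational BMS iterates to $\max|\Delta\alpha| <
10^{-8}$ (cap 500 iterations, warning on non-convergence). Degenerate inputs
are rejected rather than repaired: social distance below 1, non-positive
$k$ for hyperbolic transforms and $\beta \le 0$, non-finite utilities or
evidences, option grids that do not start at 0 or are not strictly
increasing.

## Known limitations

* The evidence approximation is Laplace/BIC, not the variational free
  energy used originally; rankings agree at this data size in our
  simulations but the numbers are not comparable across toolboxes.
* Laplace evidence is parameterization-dependent; ours is defined on the
  transformed scale where the priors live.
* With strongly separated synthetic data the winning model's pEP reaches
  0.999; on real data, with unknown priors and a toolbox we do not
  re-implement, equality of such statistics should not be expected.
* The behavioral statistics of the original study (condition means,
  F statistics) require the real data and are out of scope; the summary
  module produces the descriptive analogs only.
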