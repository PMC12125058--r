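---
title: "Modeling choice patterns in the Iowa gambling task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling choice patterns in the Iowa gambling task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igtrl)
library(dplyr)
```

## The task and its payoff structure

The Iowa gambling task (IGT) presents four decks of cards. Decks A and B pay
100 points per draw, decks C and D pay 50; per block of ten draws, A takes
five losses of 250, B one loss of 1250, C five losses of 50 and D one loss of
250. Every ten draws therefore net −250 points on A and B (the
*disadvantageous* decks) and +250 on C and D (the *advantageous* ones); A and
C have *frequent* losses, B and D *infrequent* ones. Participants learn these
contingencies only through experience, which is what the reinforcement-
learning (RL) models below formalize.

`igt_schedule()` realizes this scheme exactly. The positions of losses
within each ten-card block are not constrained by the published scheme, so
the package either shuffles them uniformly within each block (seeded;
default) or uses a fixed documented layout (`fixed_canonical`), which is
convenient when bit-identical fixtures are needed. Either choice preserves
every block aggregate, which is the only constraint the scheme states.

```{r schedule}
sch <- igt_schedule(100, seed = 1)
sch$cards |>
  group_by(deck) |>
  summarise(gain10 = sum(gain[1:10]), net10 = sum(net[1:10]))
```

## The models

**ORL** (outcome-representation learning) tracks three per-deck signals.
Expected value follows a delta rule on the net outcome `x(t)` with separate
learning rates for rewarded (`A_rew`) and punished (`A_pun`) trials.
Expected win frequency follows the same rule on `sgn(x(t))`; unchosen decks
receive a *counterfactual* update toward `−sgn(x(t))/3`, using the learning
rate of the opposite outcome type (a win on the chosen deck is a relative
loss for the alternatives — this is the original formulation of the model,
which we follow; a published tabulation that reuses the chosen-deck rate
exists, but it is inconsistent with the model's counterfactual reasoning and
with the reference implementation). Perseverance is set to `1/(1+K)` for the
chosen deck and decays by `1/(1+K)` elsewhere, with `K = 3^K' − 1`,
`K' ∈ [0,5]`. Choice is a unit-sensitivity softmax on
`V = EV + β_F·EF + β_P·PS`.

**VSE** (value plus sequential exploration) combines an exploitation weight
— a `Δ`-decaying accumulation of the utility `v(t) = Gain^θ − Loss^θ` — with
an exploration weight that resets to zero on the chosen deck and drifts
toward the exploration bonus `φ` for unchosen decks at rate `α`. Choice is a
softmax on `(Explore + Exploit)·c` with `c = 3^β − 1`; `β = 0` yields
uniformly random choice. At `θ = 0` we adopt the power convention
`0^0 = 1`, under which `v(t) ≡ 0` and choice is driven purely by
exploration, matching the intended "pure directed exploration" limit.

The classical EV, PVL, EV-PU and PVL-Delta models are provided in their
standard formulations (valence or prospect utility; delta or decay
learning; trial-dependent `(t/10)^c` or `3^c − 1` sensitivity) as
comparison baselines.

**Outcome scaling.** Raw points saturate the softmax for most parameter
values (a single ±1250 outcome dominates every weight), so outcomes are
multiplied by `outcome_scale` before entering the model equations. The
default 1/100 maps the 100-point reward to 1, the conventional rescaling in
this literature. All functions expose the scale, and every result object
echoes it.

**Initial states** are zero for all models, so first-trial choice
probabilities are exactly uniform; trial-`t` probabilities use the state
after the trial-`t−1` update. Softmax computations subtract the maximum
logit, so they cannot overflow, and exact ties give exactly uniform
probabilities.

```{r simulate}
trials <- simulate_agent(vse_params(theta = .5, delta = .8, alpha = .3,
                                    phi = .5, beta = 1), seed = 42)
count_choices(trials)
```

## Choice patterns and sequential exploration

A session is summarized by its deck counts. The *broad* classification
computes a value contrast `d_value = (nC+nD) − (nA+nB)` and a frequency
contrast `d_freq = (nB+nD) − (nA+nC)` and labels the session by the dominant
dimension — GOB/BOG by the sign of the value contrast, IOF/FOI by the sign
of the frequency contrast — with the value dimension taking priority on
magnitude ties and `Remaining` only when both contrasts are exactly zero.
This makes the five labels exhaustive and mutually exclusive, so pattern
proportions sum to one. The tie-break had to be decided here (the published
definitions do not fix it); it is isolated in `classify_broad()` so
alternative operationalizations can be swapped in. The *restricted*
classification additionally requires the dominant pair to reach 65 of 100
trials (`C+D ≥ 65` for GOB, `A+B ≥ 65` for BOG, `B+D ≥ 65` for IOF; FOI has
no restricted category), and `classify_restricted()` therefore insists on
100-trial sessions unless the thresholds are explicitly overridden.

Sequential-exploration (SeqE) indices count directed exploration: `DE3` and
`DE4` are sliding-window counts of 3- and 4-trial windows containing all
distinct decks, and `DE4F` partitions the session into `floor(n/4)`
non-overlapping chunks of four (25 chunks at 100 trials) and counts the
all-distinct chunks.

## Parameter space partitioning

PSP asks what fraction of a model's parameter space generates each choice
pattern. `psp_grid()` lays an equally spaced, endpoint-inclusive grid over
every parameter range (the full design uses 60 points per parameter —
60^5 = 777,600,000 sets — streamed by index and never materialized;
`run_psp()` defaults are sized for a desk run at 10 points = 100,000 sets,
which takes seconds). Unbounded parameters (`β_F`, `β_P`, `φ`) must be
truncated for gridding; the default bounds are `[−5, 5]` on the
scaled-outcome convention, chosen so that the frequency/perseverance terms
can both dominate and be dominated by the value signal. Each parameter set
simulates one 100-trial subject with a seed mixed deterministically from
(global seed, set index), so results are independent of chunking and
parallel partitioning; proportions are commutative counts.

```{r psp}
psp_vse <- run_psp(psp_grid("vse", points = 6), seed = 1)
psp_orl <- run_psp(psp_grid("orl", points = 6), seed = 1)
compare_parameter_spaces(list(psp_orl, psp_vse))
```

At these conditions ORL devotes the bulk of its space to Good-Over-Bad and
Frequent-Over-Infrequent patterns with little Bad-Over-Good — the
qualitative signature reported for this model. Two quantitative caveats are
worth stating plainly, because they bound what the package reproduces of
the published proportions. First, VSE's strong-exploration corner (`φ` large
and positive with high consistency) cycles through the decks
deterministically, producing exactly 25/25/25/25 counts that the exact-tie
rule sends to `Remaining` (≈7% of the default grid); published analyses
report essentially no Remaining mass for VSE, implying a different (but
unstated) treatment of such ties. Second, the published Frequent-Over-
Infrequent shares (≈44% for ORL, ≈24% for VSE) exceed what these equations
generate under any combination of outcome scale, truncation bound and
exclusive classification rule we examined; the package reports what the
stated conditions produce rather than calibrating toward the published
figures. The affected acceptance checks are left failing by design.

## Simulated cohorts

`generate_cohort()` draws subject-level parameters from group-level normal
distributions on the unconstrained (probit) scale — group SD 0.3, a
moderate, realistic individual variability for healthy cohorts — simulates
each subject, classifies it with the restricted definition, and
rejection-samples until the requested pattern composition holds. The
`"gob"` preset reproduces the construction of a pattern-curated reference
dataset: 20 subjects, half ORL and half VSE, admitting only restricted
GOB/IOF subjects (hence provably no Bad-Over-Good instance); `"bog"` is the
mirror image, using ORL means with punishment learning switched nearly off
(losses barely update value, keeping the high-gain decks attractive) and
low-sensitivity VSE means (win-frequency-driven, contributing IOF
subjects). Metadata records each subject's generating model, parameters and
simulation seed, so any subject can be replayed exactly.

What the generator deliberately does *not* emulate: real populations mix
strategies continuously rather than by preset, show nonstationarity within
a session, and produce response times; passing tests on these cohorts
therefore validates the pipeline's statistical machinery, not the models'
adequacy for any clinical population.

## Hierarchical estimation

Both ORL and VSE are estimated hierarchically: individual parameters are
drawn from group-level normals on an unconstrained scale and mapped to
their ranges by a probit transform scaled to the range width (`K'` uses
`5·Φ(·)`, `β` likewise; unbounded weights use the identity). Hyperpriors
follow each model's convention: for ORL, `μ ~ N(0,1)` with half-normal(0.2)
hyper-SDs on bounded parameters and half-Cauchy(1) on the unbounded
weights; for VSE, normal hyperpriors with SD 3.0 throughout.

Two deterministic-given-seed backends satisfy one contract (S posterior
draws plus the pointwise log-likelihood matrix):

* `backend = "advi"` — mean-field Gaussian variational inference with
  reparameterized stochastic gradients (default 10,000 iterations), using
  analytic forward-sensitivity gradients of the trial-level likelihood.
* `backend = "hmc"` (default) — Hamiltonian Monte Carlo with dual-averaging
  step-size adaptation and a diagonal mass matrix estimated during warmup,
  on the same gradients.

HMC is the default because parameter-recovery evaluation on simulated
cohorts (20 subjects × 100 trials) showed the mean-field intervals
undercover the generating group means — the classic variance
underestimation of mean-field families on correlated hierarchical
posteriors — while the sampler's intervals cover all five group means with
acceptance rates near 0.95 at a few seconds per fit. The variational
backend remains available and is considerably faster on large cohorts.

`tidy()` reports the natural-scale *group mean* as the posterior of the
average subject-level parameter (the finite-population mean), which is the
estimand a recovery study compares against the generating means; the
transformed group location `Φ(μ)` is reported alongside as `group_median`.

Model comparison uses AIC, BIC and WAIC. WAIC comes from the pointwise
matrix (`lppd − p_waic`, with the usual variance-based penalty and standard
error); AIC/BIC need a point log-likelihood and a parameter count, which a
hierarchical fit does not define uniquely — the package evaluates the summed
log-likelihood at per-subject posterior means with `k = 5 × n_subjects` and
`n =` total trials, and echoes all three conventions in the result.
`compare_models()` declares a model superior only when AIC, BIC and WAIC
all agree *and* the WAIC gap exceeds the larger of the two WAIC standard
errors; everything else is `inconclusive`.

## Numerical and design choices, in brief

* Grid points sit on inclusive endpoints of each stated range (a one-point
  grid sits at the midpoint); degenerate boundary dynamics (e.g. `A_pun=0`,
  `β=0`) are genuine members of the parameter space and are retained.
* Per-run and per-subject seeds are mixed with a counter-based splitmix64
  generator, so every simulation is replayable in isolation and aggregation
  order never matters.
* Probabilities are floored at 1e−300 inside log-likelihoods; WAIC's
  `log mean exp` uses a max-shift.
* Subject data enter fits sorted by trial within subject; likelihood totals
  are invariant to subject order up to floating-point summation and Monte
  Carlo error.
* Problem sizes used in the shipped checks — 10-point PSP grids (100,000
  runs), cohorts of 20 subjects × 100 trials, 10 replicate cohorts per
  recovery condition, 500–1000 posterior draws — are desk-scale choices
  that keep a full run in minutes while leaving the estimators' behaviour
  clearly visible.

## Known limitations

* The exclusive broad-classification tie-break and the treatment of
  deterministic cyclers are package decisions where the published
  definitions are silent; both are documented above and isolated in code.
* Mean-field ADVI underestimates posterior spread on these models; use HMC
  when interval calibration matters.
* AIC/BIC conventions for hierarchical RL fits vary across the literature;
  compare only values computed under the same convention.
* The `|ΔWAIC| > max(SE)` superiority rule is conservative: at moderate
  effect sizes (20 subjects × 100 trials) the WAIC can favour the
  generating model in every cohort while most verdicts remain
  `inconclusive`, because the per-model WAIC standard errors are large
  relative to the gap. A paired standard error of the WAIC *difference*
  would be more sensitive, but the unpaired max-of-SEs rule is the one
  implemented because it is the published decision criterion.
* The classical-model tier transcribes the standard published equations;
  subtle per-study variants (e.g. alternative PVL2 utilities) are out of
  scope.
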