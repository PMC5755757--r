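---
title: "Modelling epistemic visual foraging: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling epistemic visual foraging: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`epiforage` implements a complete analysis chain for a gaze-contingent
scene-categorisation task under active inference: a discrete generative
model of the task, agents that choose saccades by expected free energy,
inversion of observed scan-paths to subject-level prior beliefs, a
hierarchical (between-block) analysis by parametric empirical Bayes with
Bayesian model reduction and averaging, and canonical correlation
phenotyping. Because no empirical recordings ship with the package, a
synthetic-cohort generator emulates the study design end to end; every
downstream stage is exercised and tested against it.

## The task and its generative model

A scene is a 2x2 grid whose hidden category is defined by the relative
position of a bird and a second object: in FLEE scenes a cat sits
row-adjacent to the bird, in FEED scenes a seed sits row-adjacent, in WAIT
scenes the seed is on the same diagonal. Two binary spatial
transformations (a vertical and a horizontal flip) move the objects around,
giving 3 x 2 x 2 = 12 scene configurations. The observer starts at a
central fixation; saccading to a quadrant discloses the object there
(possibly nothing), and saccading to one of three choice locations is the
categorisation response, answered with RIGHT or WRONG feedback.

The generative model is a discrete partially observed Markov decision
process with four hidden factors — context (3), sampling location (8,
observed), vertical flip (2), horizontal flip (2) — and two outcome
modalities (six *what* cues; eight *where* outcomes, an identity on
location). All likelihoods are deterministic. Only the location factor is
action-dependent: actions 1–8 are saccades to the eight locations; action
9 executes a deterministic, subject-specific *heuristic* state–action
kernel `H` (e.g. a reading-like left-to-right order). Context and flips
are constant within a trial, so their transition tables are identities.
Base layouts put the bird at the top left; the choice is arbitrary (the
task's published description is pictorial) and only fixes a coordinate
frame, since the flips generate the full orbit.

Prior preferences encode the scoring rules in nats: +2 for a correct
categorisation, −4 for an incorrect one, and a stacking sampling cost that
makes remaining undecided at a non-choice location at time step `tau` worth
−0.25·(tau−1). Two log-scaling coefficients tune how precisely these rules
are felt: `k_cor = exp(ln_C_cor)` multiplies the feedback utilities,
`k_q = exp(ln_C_q)` the urgency costs. Scaling is multiplicative on the
printed point values, which keeps "the rules of the game" and "how much a
subject cares" cleanly separated. First-step utilities are zero.

## Policy evaluation

Policies are one-step (re-evaluated at every saccade; no deep tree). For
each policy the expected free energy decomposes as
`G = -epistemic - pragmatic`:

* the **epistemic value** is the expected Bayesian surprise — the
  predictive-outcome average of the KL divergence between the posterior
  and prior over the 12-state joint of scene factors — computed on the
  joint induced by the factor marginals;
* the **pragmatic value** is expected utility under the preferences.

The policy posterior is `softmax(E - F - G/beta)` with `E = (0,…,0, E_h)`
the log prior over policies and `beta` a per-subject inverse precision
(smaller `beta`, sharper selection). The past free energy `F` is common to
all one-step policies here — every policy shares the realised history and
location is observed — so it cancels in the softmax; it is retained in the
interface for fidelity. `beta` is a fixed subject parameter: no
within-trial precision updating is modelled. A subject is therefore the
quadruple `theta = (ln beta, E_h, ln C_cor, ln C_q)`.

With `E_h = log 2`, the softmax prior gives the heuristic policy
probability 0.2 against 0.1 for each of the other eight — i.e. twice any
single alternative. (A published description of this prior calls the ninth
policy "about three times" more likely; the softmax arithmetic gives 2x,
and the package implements the softmax.)

## Belief updating: mean field and its failure mode

Within a trial, beliefs over context and flips are updated by
coordinate-ascent mean field: each factor's marginal is refreshed from the
expected (floored) log likelihood of the full history under the other
marginals, sweeping factors until the largest change falls below 1e-6 or
16 sweeps. Likelihood entries are floored at `exp(-16)` before logs so
that impossible observations stay finite; a history inconsistent with all
12 joint states raises a structured error that the inversion uses to
reject malformed files.

Because the likelihood is deterministic, observations act as hard
constraints, and the exact posterior support is often *not* a product set.
A single empty quadrant is the canonical case: seeing NULL at the top left
leaves six joint states whose context and flip assignments are entangled.
The exact marginals (by 12-state enumeration, also provided as
`exact_beliefs()`) give P(vflip) = 5/6 there; the mean-field fixed point
drives it to ~1. This overconfidence is intrinsic to the factorised
approximation — deterministic likelihoods make it worse, not better — and
it has two visible consequences that the test suite pins down rather than
hides:

* mean-field marginals match the exact oracle to 1e-6 only on
  product-support histories (fully disambiguated scenes, feedback-only
  evidence); on ambiguous histories the total-variation gap reaches ~0.5;
* the simulated agent occasionally *revisits* a quadrant it has seen:
  under the factorised joint, mass leaks onto history-inconsistent states,
  so a revisit looks informative. Under exact beliefs revisits carry no
  epistemic value and essentially vanish (<1%). `run_trial()` exposes
  `beliefs = "exact"` to isolate the artefact.

The estimation pipeline is internally consistent — the same mean-field
scheme generates and scores the data — so parameter recovery and model
comparison are unaffected by this approximation gap.

## Simulation and scoring

`run_trial()` runs the agent–environment loop to a choice or to the
horizon `T = 6` time steps (the initial fixation plus at most five
saccades; `T` is configurable). Scoring: ±(2/−4) on feedback, −4 on a
time-out (the task's wall-clock limit is mapped onto the step horizon —
the model has no clock, and the staircase adjustment of the limit is
deliberately not simulated), plus the stacking exploration cost over
*distinct* quadrants attended; a time-out trial still pays the sampling
costs it incurred. Saccade counts exclude the choice saccade; a
self-transition under the absorbing heuristic kernel is a held gaze, not a
new fixation.

## Inversion

The data are locations, not policy labels, so the likelihood of an
observed saccade marginalises the policy posterior to the location level:
`P(L) = pi_L + pi_9 · [H(current) = L]`, floored at 1e-12 per step; choice
saccades are scored identically (choice locations are the targets of
policies 6–8). Each subject's `H` is estimated from their own empirical
transition frequencies (argmax successor per location, ties to the lowest
index, unvisited locations self-mapped).

Fitting is MAP with a Laplace approximation: quasi-Newton ascent on the
log joint from the prior mean `N(0, 0.25·I)` on `theta` (weakly
informative on the log scale; the prior moments are a package default, not
an empirical quantity), covariance from the central-difference Hessian
(step 1e-3, symmetrised, jittered to positive definite when needed), and
`log evidence = loglik + log prior + (d/2)·log 2π + ½·log det Sigma`.

One implementation point worth knowing: for fixed scan-paths the belief
trajectory and the per-policy epistemic values do not depend on `theta`,
which enters only through `E`, `beta` and the two preference scales. The
likelihood therefore precomputes per-saccade epistemic and base-utility
vectors once (`replay_scanpaths()`) and evaluates any `theta` by a
vectorised softmax — identical, to machine precision, to the step-by-step
evaluation (a test asserts this), and fast enough to make the recovery and
cohort experiments routine on one CPU.

The epistemic-versus-extrinsic comparison fits both model variants
independently on the same replay and reports the difference in Laplace log
evidence. On simulated epistemic agents (100 trials) the difference
exceeds 3 nats per subject; on agents simulated without the epistemic term
it vanishes or reverses. The pooled magnitude depends on cohort size and
trial counts, so only its sign and per-subject scale are meaningful
claims for synthetic data.

## Between-block analysis

Per subject, the five block posteriors are treated as observations of a
Gaussian linear model with design `(1, exp(-(b-1)))` — a constant and an
exponential decay with a one-block time constant — over each of the four
parameters, giving 8 second-level effects. The observation noise is the
block posterior covariance plus a fixed between-block covariance
`(1/16)·I`; fixing it (rather than estimating it by restricted maximum
likelihood) keeps the module closed-form, and is a deliberate
simplification. The second-level prior is `N(0, 0.25·I)`.

Bayesian model reduction scores all 2^8 = 256 on/off patterns of these
effects analytically from the full prior/posterior pair; "off" is a prior
variance of 1e-8 at mean zero. Evidence is pooled by summing over subjects
(conditional independence given the model) and softmaxed into model
probabilities; Bayesian model averaging moment-matches the mixture of
reduced posteriors. On cohorts whose drift is planted only on the
preference scales, the winning pattern excludes the precision and
heuristic-bias decay terms — the structure-recovery analogue of the
between-block analysis.

## Phenotyping

Canonical correlation analysis runs on column-standardised matrices (mean
zero, sum of squares one) via the singular value decomposition of the
whitened cross-covariance; rank-deficient within-set covariances get a
1e-8 ridge with a warning. Dimensionality is assessed with Bartlett's
sequential chi-squared statistic (chosen over Rao's F; the difference is
immaterial at these sizes), with log p-values in nats. Sign indeterminacy
is fixed by making the largest-magnitude x-weight positive.

`cva()` reports both canonical **vectors** (weights) and **structure
loadings** (correlations of each variable with its canonical variate).
Qualitative claims — e.g. "heuristic bias loads against percentage
correct in the leading pair" — are made on the loadings: weights of
collinear predictors are partial coefficients whose signs are unstable
under resampling, whereas loadings are the standard interpretable object.

## The synthetic cohort: what it emulates, and what it does not

Defaults mirror the study design: 22 subjects, 5 blocks, 100 trials,
uniform scenes, starting score 100. The population is Gaussian on the log
scale — SD 0.5 per coordinate, SD 1 for `E_h` so that both heuristic and
epistemic phenotypes occur; drift is planted only on the two preference
scales (coefficient −0.5 each: preferences sharpen over blocks and
plateau, the practice effect). Fixed-form orders are assigned with
reading-like (0.5) and clockwise (0.3) dominating, the other 22 sharing
the remainder. All randomness flows through the single seed in the
configuration; a cohort is byte-reproducible from it.

The two planted preference drifts pull saccade counts in opposite
directions: rising urgency (`ln_C_q`) shortens exploration, while a rising
accuracy preference (`ln_C_cor`) makes uncertain choices more aversive and
lengthens it. Under the default joint drift the two roughly cancel, so the
downward saccade trend over blocks is measured on cohorts whose drift is
planted on the urgency scale alone; at the default magnitude (-0.5) the
trend is visible in the group means but modest relative to sampling noise
in the late, plateaued blocks.

Two generator choices deserve emphasis:

* **The heuristic-bias/accuracy coupling is planted, not emergent.** In
  this agent, a moderate heuristic bias mildly *helps* accuracy (extra
  scripted saccades disclose extra cues before the choice) — there is no
  mechanical reason heuristic reliance should hurt accuracy, and the
  empirical association is exactly that, an association. The generator
  therefore induces it as a population covariance: `E_h` is drawn
  correlated (default 0.7) with `ln beta`, whose accuracy effect is strong
  and mechanical (imprecise policy selection produces premature and wrong
  choices). Default cohorts consequently show a stable negative
  correlation (≈ −0.6) between heuristic bias and percentage correct,
  which the CVA stage detects.
* **Timing is synthetic and never modelled.** The `isi_ms` column is a
  subject-level log-normal supplied only so the four-column behavioural
  interface can be exercised; it carries no task information.

What passing tests on this cohort do *not* show about real data: the
generator draws from the model family being fitted (no model mismatch), its
noise is exactly the softmax channel (no lapses, no oculomotor error, no
calibration drift), and its couplings are planted. Results on synthetic
cohorts validate the machinery — identifiability, calibration, structure
recovery — not the empirical claims themselves.

## Numerical choices and problem sizes

Log floor `exp(-16)` on likelihood entries; per-step likelihood floor
1e-12; mean-field tolerance 1e-6 with 16 sweeps; Hessian step 1e-3 with
power-of-ten jitter to positive definiteness; "off" prior variance 1e-8;
CVA ridge 1e-8; argmax ties to the lowest index throughout. The bundled
experiments use problem sizes chosen to run comfortably on a single CPU:
20 replications of 100 trials for recovery, four subjects per arm for the
model comparison, ten 6-subject x 5-block x 40-trial cohorts for the
model-reduction analogue, and one full default cohort for the behavioural
trend and phenotype checks; the analysis drivers under `analysis/` run the
full design.

## Known limitations

* The mean-field overconfidence described above is faithful to the
  modelling scheme but measurably wrong on ambiguous histories; exact
  enumeration is cheap here (12 states) and available, but the package
  deliberately keeps the factorised scheme as the default agent.
* The Laplace evidence is a local approximation; with 40 trials or fewer
  per block the decay effects are weakly identified and shrink toward the
  prior (visible as slightly-below-nominal coverage for second-level tail
  effects).
* No learning of the likelihood or transition arrays, no habit learning,
  no multi-step planning, no within-trial precision dynamics.
* The between-block error covariance is fixed, not estimated; pooled
  evidence differences on synthetic cohorts are therefore comparable
  within this package, not directly against hierarchical schemes that
  re-estimate it.
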