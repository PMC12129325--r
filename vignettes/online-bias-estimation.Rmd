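---
title: "Online estimation of perceptual and decision biases in 2AFC tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online estimation of perceptual and decision biases in 2AFC tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(perceptbias)
```

## The problem

Animals cannot be told to report what they perceive; they are trained to
report for reward. When a stimulus context (for example, background optic
flow simulating self-motion) biases perception away from the physically
"correct" answer, any fixed reward rule gives the animal an incentive to
compensate: over tens of thousands of trials a reward-maximizing subject
will shift its decision criterion until the measured bias shrinks or
vanishes, and the experimenter loses access to the very quantity under
study. `perceptbias` implements the closed-loop alternative: estimate the
perceptual bias online, trial by trial, and place the reward boundary at
the current estimate, so that reporting the subjective percept is already
reward-maximizing and nothing pushes the criterion around.

## The observer model

Each trial presents a stimulus direction $\omega$ (degrees, positive =
rightward of the reference) in one of three interleaved contexts
$k \in \{L, N, R\}$ (leftward-biasing, neutral, rightward-biasing). The
choice is Bernoulli with rightward probability

$$\theta_{k}(\omega) = \lambda_{1,k} +
  (1 - \lambda_{1,k} - \lambda_{2,k})\,
  \Phi\!\left(\frac{\omega - B_k}{S_k}\right),$$

a cumulative-Gaussian psychometric function with empirical bias $B_k$
(horizontal shift), sensory noise $S_k$ (slope), and lapse rates
$\lambda_{1,k}, \lambda_{2,k}$. The key structural assumption is the bias
decomposition

$$B_L = P_L + D, \qquad B_N = D, \qquad B_R = P_R + D:$$

each biased context has its own perceptual bias $P_k$, while the
decision bias $D$ (criterion, motor, and response contributions) is
shared across the interleaved contexts — interleaving removes any
incentive to maintain context-specific criteria, and the neutral
condition anchors $D$ directly. This is what makes $P_L$ and $P_R$
identifiable from a single task.

Priors: $P_L, P_R, D$ are Gaussian with means and SDs supplied per
session (typically from the multi-session model below); $S_k \sim
\Gamma(8, 0.5)$ with the second parameter a *rate*, giving prior mean 16
deg — on the scale of psychometric slopes in trained macaques (a scale
reading would give mean 4 deg, implausible); all lapse rates share a
$\mathrm{Beta}(1, 10)$ prior. A flat option replaces the bias priors with
$\mathrm{Uniform}(-180, 180)$, making the bias estimates
maximum-likelihood-like. Angles are plain degrees without wraparound; the
tasks this targets span a few tens of degrees.

## Posterior computation

`fit_posterior()` runs componentwise adaptive random-walk Metropolis on
unconstrained scales ($\log S_k$, $\mathrm{logit}\,\lambda$), with
proposal scales adapted toward a 0.44 acceptance rate during burn-in only
(the retained draws come from a fixed kernel, so the chain is a valid
Metropolis sampler). Defaults are 5000 draws with 2500 burn-in. Two
implementation choices matter for online use:

* **Binomial aggregation.** Trials are collapsed to right-choice counts
  per (condition, stimulus) cell before likelihood evaluation, so a
  likelihood evaluation costs the number of distinct cells (33 under the
  default design), not the number of trials. A full 990-trial fit takes
  a fraction of a second; per-trial refitting is comfortably inside the
  3–3.5 s inter-trial interval typical of primate training rigs, and
  `replay_session()` warns when any refit exceeds a configurable latency
  budget.
* **Warm starts.** Online refits start from the previous posterior's
  final state and proposal scales. A fresh seeded fit never perturbs the
  caller's RNG stream (the sampler saves and restores it), so embedding
  refits inside a running simulation leaves the simulation's randomness
  untouched.

Diagnostics are the split-chain convergence statistic (threshold 1.05;
chains are halved, so a single chain still yields a usable value) and
Geyer initial-positive-sequence effective sample sizes. Non-convergence
flags the summary with a warning rather than failing, because online use
must degrade gracefully. Chains initialize at the prior means (jittered
for additional chains); 4 chains are recommended for offline validation,
1 for online speed. The likelihood clamps $\theta$ to
$[10^{-12}, 1-10^{-12}]$ to keep degenerate parameter corners finite.

Correctness is established in the test suite against a brute-force
grid-quadrature posterior on small instances (total variation below 0.05
on a shared 1-degree lattice, with noise and lapses clamped to truth),
against a direct ML optimizer in the flat-prior large-$n$ limit, and by
a 100-run calibration study (68% interval coverage within its binomial
band when truth is drawn from the prior).

A deliberate property of the full model, visible in recovery studies: at
990 trials the free lapse rates trade off slightly against the biases and
noise (posterior means of $S$ sit roughly 1 deg below the generating 15
deg, biases within about 1 deg), because the extreme stimuli cannot fully
pin the asymptotes. Clamping lapses at zero removes the effect; we keep
them free because real subjects lapse.

## Reward allocation

`online_estimator()` follows the per-trial loop: before one repetition of
every distinct stimulus has been seen (33 trials under the default
design) the bias estimates are the prior means and rewards are based
solely on the prior; from then on the posterior is refit every
`refit_cadence` trials (including the current trial's choice). The reward
boundary for each biased context glides toward the posterior mean of that
context's *perceptual* bias — the decision-bias estimate is never added,
because the boundary lives in stimulus coordinates around the task
reference — by at most `max_step` degrees per trial (default 1 deg, one
percent of the 80-deg stimulus range). The clamp is applied every trial,
not only at refits, so the boundary trajectory is 1-Lipschitz at any
cadence. The neutral boundary is fixed at 0. A stimulus exactly on the
boundary is rewarded regardless of choice: a deterministic tie-break,
relevant in simulation where grid stimuli can sit exactly on a veridical
boundary (it slightly softens conventional-reward penalties at that one
grid point), and measure-zero against posterior-mean boundaries.

## The learning agent

To compare reward strategies we simulate a criterion-learning agent. It
perceives $\hat\omega \sim N(\omega - P_k, \Sigma_k)$, chooses by MAP
against its criterion $\psi_k$ (tie rightward), predicts reward with
confidence $q = \max(\hat\theta, 1-\hat\theta)$,
$\hat\theta = \Phi((\hat\omega - \psi_k)/\Sigma_k)$, and updates

$$\psi_{t,k} = \psi_{t-1,k} - \alpha\, C_t\, (r_t - q_t),$$

with signed choice $C_t = \pm 1$ and reward $r_t \in \{0,1\}$; $q$ uses
the pre-update criterion, and no single trial can move $\psi$ by more
than $\alpha$. This is the sign-simplified temporal-difference rule (the
full gradient form is replaced by its sign); we implement only this
simplified rule. Defaults $\alpha = 0.04$ deg/trial and $\Sigma_k = 16$
deg approximate learning speeds and psychometric slopes of trained
macaques; the learning rate is deliberately keyed apart from the Gamma
shape hyperparameter of the noise prior, since both are conventionally
written with the same Greek letter. Criteria start at 0 (subjects are
pre-trained to unbiased neutral performance) and can be independent per
context or shared.

Strategies: *veridical* (boundary 0), *oracle* (boundary at the true
$P_k$ — simulation only), *estimated* (boundary from the online
estimator), and the conventional *always / never / random* treatments of
ambiguous trials, where a trial is ambiguous when its stimulus lies in
the closed interval between 0 and the context's true bias. The random
variant's probability defaults to 0.5 and is configurable (published
studies have used 0.5, 0.8 and 1.0). `run_rl_experiment()` reproduces the
strategy-comparison protocol (10 replicates of 50 sessions of 990 trials)
and summarizes each session with lapse-free ML psychometric fits per
condition — the fit is multi-start Nelder–Mead probit (started at grid
quantiles, lowest-bias tie-break for determinism), cross-checked in the
tests against `glm(..., binomial("probit"))`.

One quantitative subtlety the simulations expose: under the *oracle*
strategy with the standard fixed grid, the criteria do not rest exactly
at zero. Because the stimulus set is asymmetric around each context's
boundary, the expected TD drift vanishes at $\psi_L^* \approx +1.9$ deg
and $\psi_R^* \approx -2.8$ deg (we verified these fixed points by direct
quadrature of the expected update), so session-mean measured biases sit
2–3 deg from truth even under ground-truth rewards. Centering each
context's grid on its true bias (`symmetric_grid = TRUE`) removes the
effect (criteria stay within 1 deg of zero). This is a property of
criterion learning with fixed stimulus sets, not of the estimator.

## Synthetic sessions

`make_design()` builds block-randomized sessions: every block presents
each of the 33 (stimulus × condition) cells exactly once in fresh random
order; defaults are 30 blocks of the 11-direction grid (−40 to 40 deg in
8-deg steps), i.e. 990 trials. `simulate_session()` draws choices from
the observer model with zero lapses by default (the generator emulates a
non-lapsing simulated observer; lapse scenarios are a parameter away).
Optional non-stationarities:

* decision-bias drift $D_n = 10\sin(\pi n/2000)$ (`decision_bias_at()`),
* piecewise-linear perceptual-bias decay from $P_0$ to $P_0/s$ between
  trials $t_{b1}$ and $t_{b2}$ (`gradual_change()`, steepness default 3;
  in multi-session runs the change spans sessions 11–41, i.e.
  $t_{b1} = 10 \times 990$, $t_{b2} = 41 \times 990$ — we take the
  session boundaries as the breakpoints, a convention choice),
* win-stay/lose-shift contamination: with probability $T_{se}$ (0.25 in
  the reference setting) the subject ignores the stimulus and repeats a
  rewarded previous choice or switches after an unrewarded one,
  conditioned on the immediately preceding trial regardless of its
  context (contexts are interleaved and no per-context history is
  specified). Sequential generation then requires rewards trial by
  trial; the generator rewards relative to the ground-truth bias
  boundaries in that mode.

Seeding: one master seed per experiment is split into per-session
substreams (`split_seed()`), so any session can be regenerated in
isolation. What the generator does *not* emulate: within-session
motivation drifts, aborted trials and fixation breaks, stimulus rendering
noise, or any reward-magnitude sensitivity. Passing recovery tests on
these sessions therefore demonstrates correctness of the inference
machinery under the model's assumptions (plus the specific violations
exercised — criterion drift, decision-bias drift, sequential effects),
not robustness to everything real data can do.

## Pooling sessions

When task covariates (heading direction, eccentricity) vary across
sessions, per-session perceptual biases are modeled linearly:
$P \sim N(\beta^\top X, \sigma)$ with weakly informative $N(0, 1000)$
hyperpriors on each weight and on $\log\sigma$ (the log scale respects
positivity; the constraint handling is our choice). An intercept column
is included by default — a through-origin model cannot represent a
context bias at zero heading. `fit_hypermodel()` implements the
*two-stage empirical-Bayes* path: per-session posterior means enter as
observations with their posterior SDs as known measurement error, so
session $i$ contributes $N(\beta^\top X_i, \sqrt{\sigma^2 + se_i^2})$.
We chose the two-stage fit as the implementation (rather than a joint
hierarchical MCMC over all sessions' latents) because it is orders of
magnitude cheaper, is exactly what between-session prior refreshing
needs, and its generate-and-recover behavior — weight coverage,
width shrink-then-plateau near the residual SD, no prior-vs-posterior
drift — is verified in the test suite; a joint fit remains a possible
extension.

`session_prior_from_hyper()` maps a new session's covariates to a
ready-to-use prior: perceptual means $\hat\beta^\top X$, perceptual SDs
the posterior mean of $\sigma$ floored at 1 deg (with few sessions
$\sigma$ can collapse below the measurement error and a degenerate prior
would pin the next session), and decision prior $N(0, \tau_D)$ with
$\tau_D$ the empirical SD of per-session decision-bias means floored at
2 deg — the decision bias is treated as session-to-session variability
around zero, not as covariate-driven.

A known limitation, measured in the drift experiment: the hypermodel
assumes a stationary linear relation, so during a sustained decay of the
true bias the refreshed session priors lag (posterior means settle a few
degrees above a truth that has fallen by a factor of 3), while the
per-session empirical-bias fits track the decay faithfully. With a
slow-learning subject this affects the reward boundary only mildly; for
strongly non-stationary biases a windowed or discounted prior update
would be the next step.

## Numerical and design choices, collected

* Tie-breaks: stimulus on the boundary → reward; percept on the
  criterion → rightward choice; equal ML likelihoods → lowest bias.
* $\theta$ clamped to $[10^{-12}, 1-10^{-12}]$; proposal log-scales
  clamped to $[-10, 5]$; Robbins–Monro adaptation rate $t^{-0.6}$.
* The decision bias is prior-driven when a data set contains no neutral
  trials; the fit warns and proceeds rather than refusing, since the
  perceptual-bias *differences* remain informative.
* Prior-width scenarios that share an empirical-bias width use
  $\tau_P^2 + \tau_D^2 = 200$ (e.g. $2\sqrt{46}$ against 4, 10 against
  10, 4 against $2\sqrt{46}$).
* Problem sizes in the shipped tests: full-scale strategy comparisons
  (10 × 50 × 990) where the claim depends on them; 60-trial instances
  for the quadrature oracle; 100 sessions for calibration; 12–20
  replicates for RMSE comparisons. These are the sizes at which the
  checked contrasts are decisive.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates everything
from scratch: ten seeded 990-trial recovery sessions (posterior means of
$P_L$, $P_R$, $D$ and the sensory noise), the veridical-reward
bias-disappearance session index, and the 100-trial shrinkage limit, and
writes them as JSON. All randomness derives from `--seed`.
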