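---
title: "Tracking latent working-memory skill in adaptive N-back training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking latent working-memory skill in adaptive N-back training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skilltrackr)
```

## The problem

Adaptive N-back training adjusts task difficulty (the n-level) from recent
performance. Classical controllers — staircases and blockwise threshold
rules — react only to the last few trials or the last block, so a lapse or a
lucky streak can throw a trainee far from an appropriate challenge.
`skilltrackr` treats the trainee's *maximal n-level skill* as a latent state
to be tracked across the whole training history, and provides three
trackers: a discrete-state input-output hidden Markov model (the central
model), a continuous-state unscented Kalman filter, and an LSTM sequence
regressor used as a deep-learning baseline. A simulator of the adaptive
training games closes the loop: every model can be trained, tested and
benchmarked on synthetic cohorts with known ground truth.

The time step throughout is the *block*: a few minutes of continuous play at
a constant presented n-level $z_t$, summarized by the trial counts TP
(collected targets), FN (missed targets) and FP (collected non-targets).
Block performance is

$$y_t = \frac{\mathrm{TP}}{\mathrm{TP} + \mathrm{FN} + \mathrm{FP}},$$

hits over hits plus misses plus false alarms; correct rejections do not
enter.

## Observation model

Given latent skill $x_t$ and presented level $z_t$, the probability of a
correct response to a single trial follows a four-parameter logistic item
characteristic curve

$$a_t = c + \frac{d - c}{1 + e^{-\rho (x_t - z_t)}},$$

with discrimination $\rho$, guessing floor $c$ and carelessness ceiling $d$.
Responses within a block are not independent given $(x_t, z_t)$: attention
and fatigue drift between blocks. The realized per-block ability is
therefore a beta draw $\hat a_t \sim \mathrm{Beta}(\alpha a_t, \alpha(1 -
a_t))$ with mean $a_t$ and concentration $\alpha$, and the block success
count is binomial in $\hat a_t$. Marginalizing $\hat a_t$ yields a
beta-binomial emission, evaluated entirely through `lchoose`/`lbeta` so
that no raw gamma function ever overflows:

```{r emission}
p <- irt_params(rho = 1.6, c = 0, d = 1, alpha = 11.56)
sum(exp(emission_log_prob(0:12, m = 12, x = 4, z = 5, p)))  # normalizes
```

Two reconciliation decisions connect this model to the raw logs:

* the emission's support is a count out of the $m_t$ targets, while the
  observed $y_t$ also penalizes false alarms. Models are fitted on the
  *effective success count* $y^{succ}_t = \mathrm{round}(y_t \cdot m_t)$,
  preserving the false-alarm penalty while respecting the binomial support;
  the raw counts stay in the data container for audit.
* with $c = 0$ or $d = 1$ the beta parameters degenerate as $a \to 0$ or
  $1$; $a$ is clamped to $[10^{-6}, 1 - 10^{-6}]$, which keeps the
  log-gamma calls finite without materially changing any likelihood.

Blocks with $\mathrm{TP}+\mathrm{FN}+\mathrm{FP} = 0$ carry no information
about skill and are dropped from fitting with a warning, as are the
(practically nonexistent) blocks with zero targets.

## Transition architectures

Skill moves by at most one level per block. **Model-1** ties all rows to
three probabilities $(q_{-1}, q_0, q_{+1})$ — down, stay, up. **Model-2**
lets the move propensity depend on the previous block's outcome: the tensor
$q_{\Delta x,\, z - x',\, B(y)}$ is indexed by the skill change $\Delta x
\in \{-1, 0, +1\}$, the gap between the previous presented level and the
new skill $z - x' \in \{-2..2\}$, and the previous accuracy decile $B(y)
\in \{1..10\}$ — $3 \times 5 \times 10 = 150$ tied parameters. Accuracy
bins are half-open $[(k-1)/10, k/10)$ with the top bin closed.

Three structural conventions complete the definition, none of which is
forced by the model statement itself:

* **Boundary states.** Rows at $x = 1$ and $x = N$ renormalize over the
  feasible neighbors, preserving the tied-parameter interpretation.
* **Row normalization (model-2).** Tensor entries are non-negative
  propensities; each realized row is masked (adjacency and $|z - x'| \le
  2$) and renormalized. Raw count-ratio M-steps are exact only without
  masking, so the M-step instead maximizes the expected complete-data
  log-likelihood of the *normalized* rows numerically (L-BFGS-B over tied
  log-propensities, warm-started at the current values). This is a
  generalized-EM step, so the likelihood never decreases — an invariant the
  test suite asserts. Model-1 boundary rows raise the same issue, so
  model-1 uses the identical machinery over three softmax logits.
* **Fully masked rows.** Under reset-style algorithms the presented level
  can jump far from any feasible new skill, zeroing every candidate of a
  model-2 row; such rows degenerate to a self-transition. This keeps the
  chain well-defined and flags model-misfit territory.

The number of states defaults to $N = 10$, matching the range of n-levels
real trajectories reach; the simulator caps presented levels at the same
value.

## Fitting

`em_fit()` adapts Baum-Welch EM to stimulus-dependent emissions and tied
transitions: the E-step pools expected transition counts across all
participants into the tied cells via scaled forward-backward recursions
with time-varying transition matrices; the M-step is the numerical update
above plus a closed-form update of the initial distribution from the pooled
first-block marginals. Iteration stops when the log-likelihood gain falls
below 0.001 (a deliberate "little imprecision") or a configurable iteration
cap is reached. Model-2 defaults to five seeded random restarts because its
likelihood surface is multimodal; model-1 is well-behaved with one.

The observation hyperparameters $(\rho, c, d, \alpha)$ are few, so they are
optimized outside EM by grid search (`grid_search_irt()`). The default grid
spans $\rho \in \{1.0, \ldots, 2.5\}$ in steps of 0.1, $c \in \{0, 0.05,
0.1\}$, $d \in \{0.9, 0.95, 1\}$ and $\alpha \in \{1, 3, 5, 8, 11.56,
20\}$. Whether the grid is scored on training or held-out likelihood is
genuinely open; both are supported (`score = "train"` is the default, and
`"holdout"` makes a seeded participant-level 80:20 split).

Filtered (not smoothed) posteriors drive the reported skill trajectories —
that is what an online controller would have — with smoothed marginals
available from `forward_backward()`. Point trajectories take the filtered
argmax with ties broken toward the lower level, a conservative placement.

## Identifiability, and what recovery experiments can show

The emission depends on skill only through $x - z$, so the latent scale is
pinned only by the boundedness of the state space and the adaptive
coupling between $z$ and performance. Two consequences matter for
simulation studies:

* With the overdispersed emission at the fitted concentration
  ($\alpha \approx 11.6$), the filtered skill is fuzzy to about one level.
  Model-1's three parameters are invariant to a level shift and recover
  cleanly under these conditions; model-2's challenge tag $z - x'$ is not,
  and neighboring contexts blur into each other. The maximum-likelihood
  tensor can then genuinely differ from the generating one while fitting
  the observable data better. Parameter-recovery experiments for model-2
  therefore use sharp emissions ($\rho = 2.5$, $\alpha = 50$) so the
  latent state is identified, and they compare realized (masked and
  renormalized) rows — the parameterization-invariant quantity — on
  contexts visited at least 100 times.
* The simulator's default false-alarm rate (0.05) deliberately injects the
  accuracy-metric mismatch described above. Recovery experiments switch it
  off so the fitted family contains the generating process exactly;
  robustness experiments leave it on.

## The continuous tracker

The UKF variant promotes the discrimination to a state component: the state
is $(x_t, \rho_t)$, with linear-Gaussian dynamics $x_t = A x_{t-1} + B u_t
+ v_t$ and the ICC (with $c = 0$, $d = 1$) as the nonlinear observation of
accuracy with additive Gaussian noise $R$. Design choices the model
statement leaves open:

* **Control vector** $u_t = (z_t, y_{t-1}, 1)$ — current challenge,
  previous performance, bias — chosen to make the $2 \times 3$ control
  matrix meaningful; $y_0 = 0.5$ for the first block.
* **Slope clamp.** The $\rho$ component is clamped at 0.05 inside the
  observation so a sign flip cannot invert the ICC; the skill component is
  unclamped and genuinely continuous — under oscillating challenges the
  filtered skill settles strictly between adjacent integer levels.
* **Unscented transform.** Merwe scaled sigma points with $\alpha_{UT} =
  0.5$, $\beta_{UT} = 2$, $\kappa = 0$. The prediction step is linear and
  handled exactly; sigma points enter only the measurement update, so with
  a linear observation substituted the filter reduces to the exact Kalman
  filter (asserted to $10^{-8}$ in the tests). Covariances are
  symmetrized and eigenvalue-floored at $10^{-9}$ if an update leaves them
  indefinite.

`ukf_em_fit()` estimates $A, B, Q, R, x_0, V_0$: the E-step is an
unscented Rauch-Tung-Striebel smoother (exact for the linear dynamics),
the M-step is generalized least squares for $[A\,B]$ jointly, residual
second moments for $Q$, pooled first-block moments for $x_0$ and $V_0$,
and sigma-point-propagated observation residuals for $R$. Because the
measurement updates are approximate, the likelihood trace is only
approximately monotone; the suite asserts monotonicity to $10^{-4}$, and
exactly (to numerical tolerance) in the linear special case, where the
package also recovers the generating $A$ to $\pm 0.05$ elementwise on a
60-sequence × 60-block cohort — a size chosen to keep the whole suite
fast on one CPU while leaving the estimate well inside the bound.

## The LSTM baseline

The comparator is one LSTM layer (32 units by default; $4u(u + 3)$
recurrent parameters, so 4,480 at $u = 32$) and a dense head ($2u + 2 =
66$) mapping to the next block's (n-level, accuracy) pair, trained with
Adam on mean squared error over sliding windows of (standardized n-level,
accuracy) pairs. Window length is nowhere specified by the architecture;
20 is the default and it is configurable. Windows are causal and never
span participant boundaries, so the prediction for block $t$ uses only
blocks before $t$, and the first `window` blocks of each participant have
no prediction. Training is deterministic given the seed (seeded
initialization and batch shuffling); the backward pass is checked against
numerical differentiation in the tests.

The baseline reproduces the known failure mode of sequence regressors on
reset-style data: when the presented level resets every session while true
skill stays put, the trained network's n-level output follows the
presented trajectory rather than the latent skill (its correlation with
the next presented level exceeds its correlation with ground-truth skill on
seeded synthetic cohorts).

## The simulator

`simulate_cohort()` emulates the training games at the block level:
40-trial blocks, 30% targets, 18 sessions of 8 blocks by default (sessions
are about 20 minutes, blocks 2-3 minutes). Seven progression algorithms are
implemented: three within-block staircases (3/2, 3/3 and 6/2 consecutive
hits up / errors down), three between-block mini-block rules on 40-trial
error totals (up below 6 / down above 8; up below 3 / down above 6; the
same with a reset to 2-back at every session start) and the blockwise
85/70 accuracy rule. "Errors" count both misses and false alarms.
Staircase counters are consecutive, reset on the opposing event and on a
level change, and a within-block level change starts a fresh stimulus
stream (the realized ability is redrawn at the new level) — standard
staircase semantics, stated here because only the thresholds are fixed by
the published rules. The blockwise rule's "consistent accuracy" is read as
a single qualifying block by default, with a configurable
consecutive-block count.

Participant archetypes mirror the performance patterns real cohorts show:
a steady learner (ramps to a plateau at a typical rate), a non-learner
(flat), an oscillator (bounces around an asymptote), and an
`hmm_generative` profile driven by an explicit transition model for
recovery studies. Block outcomes follow the observation model exactly:
targets binomial at the target rate, hits beta-binomial through the ICC,
false alarms binomial at the profile's false-alarm rate.

What the simulator does *not* emulate: stimulus identities and lure
structure, reaction times, motivation and engagement dynamics, or
session-to-session consolidation. Passing tests on synthetic cohorts
therefore demonstrate correctness of the estimators under the stated
generative assumptions, not validity of those assumptions for any real
cohort.

## Evaluation

`score_model()` computes the squared error between one-step-ahead predicted
and observed block accuracy (both fractions), reports the per-participant
MSE breakdown, and pools the RMSE over all scored blocks, expressed in
percent (RMSE × 100). Pooling over blocks rather than averaging
per-participant RMSEs is a choice; the identity "pooled RMSE² =
block-weighted mean of per-participant MSEs" is asserted in the tests.
Predictions are one-step-ahead — the belief after blocks $1..t-1$ pushed
through the transition and the ICC — because that is both the standard
filtering metric and how a deployed controller would use the model; the
first block is scored from the initial distribution (configurable
exclusion). `split_cohort()` makes seeded participant-level 80:20 splits
(a participant's blocks are never divided) or condition-based splits.

On history-dependent synthetic cohorts (promotion propensity rising
sharply with recent accuracy), fitted model-2 beats model-1 in pooled test
RMSE in the majority of seeded replicates — the direction expected when
history genuinely drives transitions. The test suite runs this at 30
participants × 60 blocks per seed over 10 seeds; the acceptance script
reports one such pair of RMSEs.

## Numerical and scale choices

* Forward recursions scale per step (log-space only inside emissions);
  degenerate all-zero likelihood rows abort with the offending block named.
* EM convergence threshold 0.001 on the absolute per-iteration
  log-likelihood increase; iteration caps are configuration.
* Parameter-recovery experiments in the tests use 200 participants × 100
  blocks (the scale at which the tied cells are comfortably populated);
  comparative-ordering experiments use 30 × 60 per seed. These sizes are
  the package's choice of a thorough-but-quick default study; larger
  cohorts only tighten the same checks.
* All stochastic procedures (simulation, splits, restarts, LSTM training)
  take explicit seeds and restore the caller's RNG state.

## Known limitations

Item parameters are universal: one $(\rho, c, d, \alpha)$ for all
participants, so individual differences in discrimination or guessing
become transition noise (the UKF variant relaxes exactly this for $\rho$).
The HMM state space is bounded at $N$; trainees pushing past it would
saturate. The LSTM baseline implements only the selected architecture, not
the cross-validation sweep that selected it. And the model-2 tensor is
only as identified as the emission is sharp — on noisy real data its
effective capacity exceeds what moderate cohorts can pin down, which is
precisely the regime where the three-parameter model-1 is preferable.
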