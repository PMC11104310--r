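---
title: "Modelling Pavlovian bias in repeated Go/No-Go testing and activity diaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Pavlovian bias in repeated Go/No-Go testing and activity diaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gonogo)
```

## The scientific problem

Behavioural-activation therapy for depression rests on reinforcement
principles: scheduling rewarding activities should re-engage approach
behaviour, and restructuring avoidance should loosen the grip of aversive
expectations. `gonogo` provides the computational machinery to test those
mechanisms quantitatively in a repeated-measures treatment study design:

1. an **orthogonalized Go/No-Go task** administered repeatedly over therapy,
   analysed with a nested family of reinforcement-learning models whose
   Pavlovian components may change when specific therapy phases begin;
2. a **symptom-trajectory regression** relating weekly depression totals to
   those fitted parameter changes;
3. **activity-diary analyses** testing whether self-reported reward and
   punishment expectations update according to prediction errors.

Because studies of this kind are small (a dozen patients) and their raw data
are rarely shareable, every input has a synthetic generator with known ground
truth, and the package's validation is organized around *recovery*: simulate
under known parameters, refit, and confirm the estimates come back.

## The task and its conditions

The task crosses required action (go / no-go) with outcome valence (win /
loss avoidance), giving four conditions: `go_win`, `nogo_win`, `go_avoid`,
`nogo_avoid`. Feedback is probabilistic: the correct action yields the better
outcome with probability 0.8. Each administration presents 60 trials per
condition (240 trials), interleaved by permuting blocks of four so that local
condition frequencies stay balanced (the block design is our choice; it
stabilizes learning-curve estimates without affecting any model quantity).

Two outcome tables are implemented because the task description and the
learning-model description imply different ones. Under `"paper_text"`, the
wrong action in a win condition delivers a *loss* with probability 0.8; under
`"conventional"`, win conditions only ever deliver reward or nothing. The
distinction matters: punishing wrong actions in win conditions makes
`nogo_win` easy (the punished go response is rapidly suppressed), whereas the
conventional table reproduces the canonical phenomenon — `nogo_win` is the
hardest condition because the reward-predictive stimulus acquires a positive
Pavlovian value that invigorates the (wrong) go response. `outcome_rule()`
defaults to `"paper_text"`, exposing the ambiguity; the synthetic-cohort
generator uses `"conventional"`, which is the regime consistent with the
model's value structure and the accuracy ordering it is meant to emulate.

Missed responses (no response before the 1.5 s deadline) are treated as nogo
choices for learning, flagged `missed`, and excluded from RT summaries. This
preserves trial counts while allowing sensitivity analyses
(`missed_learning = "none"` skips their value updates).

## The model family

Choice probabilities come from a softmax over two action propensities.
The instrumental value of action $a$ for stimulus $s$ follows
Rescorla-Wagner learning with shared learning rate $\alpha$ and reward
sensitivity $\beta$ (which scales the outcome inside the update, not the
softmax):

$$Q_t(a, s) = Q_{t-1}(a, s) + \alpha\,(\beta r_t - Q_{t-1}(a, s)).$$

The nested extensions are, in order: an irreducible-noise (lapse) parameter
$\xi$ mixing the softmax with coin-flipping,
$p \leftarrow p\,(1-\xi) + \xi/2$; a fixed go bias $b$ added to the go
propensity; and a Pavlovian stimulus value $V(s)$, learned by the same delta
rule regardless of action, whose contribution $\pi V(s)$ attaches to the go
action only. The dual-Pavlovian model splits $\pi$ into an appetitive weight
$\pi^+$ (win-valence stimuli) and an aversive weight $\pi^-$ (loss-valence
stimuli). Positive $\pi^+$ invigorates approach toward reward cues; positive
$\pi^-$ suppresses action under threat (loss cues carry negative $V$).

Design choices worth making explicit:

- **Valence gating.** $\pi^+$/$\pi^-$ apply by the *stimulus's* valence, not
  by the sign of the learned $V(s)$, which fluctuates early in learning.
  Gating by condition valence is deterministic and matches the intended
  "appetitive vs aversive stimuli" semantics.
- **Session variation.** Across five task administrations all parameters are
  fixed per subject except the Pavlovian weights: $\pi^+$ may take a new
  value from administration 3 (when the reward-focused therapy phase has
  begun) and $\pi^-$ from administration 4 (the avoidance-focused phase).
  The differences `pi_app_post - pi_app` and `pi_av_post - pi_av` are the
  parameter-change scores used downstream.
- **State resets.** $Q$ and $V$ restart at zero each administration; the
  stimuli are fresh each time, so carrying values over would be wrong.
- **Shared $\alpha, \beta$** between $Q$ and $V$, as the update equations are
  printed. Exploratory splits of the learning rate or lapse by stimulus
  valence exist behind `split_alpha`/`split_xi` flags but are off by default.
- **Transforms.** The hierarchical prior is Gaussian on an unconstrained
  scale: logit for $\alpha$ and $\xi$, log for $\beta$, identity for $b$ and
  the $\pi$'s.

The likelihood kernel is compiled (Rcpp); the exported R building blocks
(`action_values()`, `action_probabilities()`, `update_state()`) define the
same math and the test suite holds the two paths together, alongside
hand-unrolled enumeration oracles.

## Hierarchical fitting and model comparison

`em_fit()` implements empirical-Bayes expectation-maximization. Each subject
gets a MAP estimate under the current Gaussian group prior (BFGS from random
restarts drawn from the prior, warm-started across iterations) with a Laplace
approximation at the mode; the M-step updates the prior mean with the average
MAP and the prior variance with the average of (MAP² + posterior variance)
minus the squared mean, floored at 1e-6. Iterations stop when the prior mean
moves less than `tol` (default 1e-3) or the summed Laplace evidence improves
by less than `obj_tol` (default 0.02 nats) — the second rule truncates a long
flat tail during which the subject-level estimates no longer change
materially. A drop of more than 0.5 nats in the EM objective (beyond what
Laplace error produces) stops the fit with `converged = FALSE` and a warning
carrying the iteration trace.

Model comparison uses the integrated BIC: the group-level marginal likelihood
is estimated by Monte Carlo (averaging each subject's likelihood over draws
from the fitted prior, log-sum-exp stabilized) and penalized by two prior
parameters (mean, variance) per model parameter times the log of the total
number of choices. Absolute iBIC values depend on the Monte-Carlo sample
count and the penalty convention; *differences between models on the same
data* are the meaningful object, and the model-recovery study below treats
them exactly that way. `posterior_predictive()` closes the loop by simulating
sessions at the subject MAPs and overlaying per-condition learning curves on
the data.

## Symptom and diary regressions

The symptom model explains weekly depression totals with a per-subject random
intercept and four fixed effects: step improvements after the reward-focused
(week 4) and avoidance-focused (week 7) therapy phases, and improvements
proportional to each subject's appetitive and aversive Pavlovian changes
(active from their respective phases). Steps, not ramps: the phase effect is
modelled as a sustained level change. Fits use REML via `lme4`, with Wald z
tests — at a dozen subjects, small-sample exactness is unattainable and the
package's claims rest on simulation calibration instead. Null variants
substitute alternative change scores (learning-rate or lapse changes, or
permuted Pavlovian changes) through the identical machinery.

Diary entries record, per activity: predictions made at planning
(`R_pre`, `P_pre`), experienced outcomes (`r`, `p`), and fresh predictions
after completion (`R_post1`, `P_post1`), all on a 0-10 integer scale (the
scale is configurable; the analyses are invariant to affine rescaling, which
the tests assert). Derived quantities follow the defining identities
(`delta_R = r - R_pre`, `dR1 = R_post1 - R_pre`); the long-timescale change
`dR2` pairs successive plannings of the same activity in day order, each
planning used at most once, attributed to the earlier planning's prediction
error. "Repeated the next day" means the same activity identifier planned for
day + 1 — a stricter reading than same-category repetition, chosen because it
is conservative and unambiguous. Mixed models put the predictor in both fixed
and per-subject random slots (correlated intercept/slope first, falling back
to independent then intercept-only structures on convergence failure, with
the structure used recorded in the result). Anhedonia-item interactions
(IDS-SR items 19 and 21; change = end − start, so improvement is negative)
are Bonferroni-corrected for the two item hypotheses.

## What the generators emulate — and what they do not

`gen_task_cohort()` draws subjects from a Gaussian prior whose defaults
(transformed scale: $\alpha$ at logit 0.2, $\beta$ at log 3, $b = 0.3$,
$\xi$ at logit 0.05, Pavlovian weights 0.5 rising to 1.0 after their phases,
all SD 0.5) produce the canonical condition-accuracy ordering at realistic
effect sizes. `gen_goal_cohort()` equips each simulated patient with latent
activity values and an update rate near 0.7 (matching the strength of
prediction-error updating such diaries show); reported ratings add rounding
and clipping noise, and next-day repetition follows a logistic in yesterday's
reported reward and punishment. The agent's prediction error is anchored on
the *stated* prediction (`R <- R_pre + rho (r - R_pre)`): the analyses regress
reported changes on reported errors, and anchoring on the report makes the
regression estimand equal the generating update rate, so recovery is a clean
test of the machinery rather than of an errors-in-variables correction.
`gen_symptom_cohort()` composes weekly totals from the same design matrix the
regression fits, with weights (-5, -4, -2, -2), residual SD 2 and baseline
severity 34.5 ± 8.5 — a moderately depressed cohort improving over therapy.

None of the generators model dropout, missed diary days, forgetting between
administrations, RT dynamics, or serially correlated symptom noise. Passing
recovery tests therefore certifies the estimators under the stated generative
assumptions; it does not certify that real patients satisfy those
assumptions.

## Validation studies and problem sizes

The validation suite runs, at the study's own dimensions (12 subjects, five
administrations of 240 trials, 56-day diaries, 10 weekly symptom measures):

- exact agreement (1e-12) between the likelihood and brute-force enumeration
  on every dataset of up to three trials, including administration
  boundaries;
- exact nesting of every model inside its richer neighbours at neutral
  parameter values;
- parameter recovery over 10 replicate cohorts: correlations between true
  and recovered $\alpha$, $\beta$, $\pi^+$, $\pi^-$ and both session-change
  deltas all at or above 0.7;
- model recovery: the session-varying dual-Pavlovian model wins the iBIC
  comparison against its nested alternatives in at least 70% of cohorts
  (the four-model ladder from `RW+noise+bias` upward — the simpler two
  models are never competitive and add only runtime);
- symptom-regression calibration: 95% Wald intervals cover the generating
  weights in ≥90% of 50 replicates, with the Pavlovian-change effects
  significantly negative;
- diary-slope calibration at the 0.7 update-rate regime, with
  within-subject permutation nulls covering zero;
- detection of item-coupled update rates (coefficient 0.2) after Bonferroni
  correction;
- posterior-predictive learning curves within 0.08 mean absolute deviation
  of the observed curves, reproducing the qualitative ordering (congruent
  conditions best, `nogo_win` worst).

Monte-Carlo sample counts (2000 prior draws for the iBIC by default, 1000 in
the replicated comparisons; 50-100 posterior-predictive simulations per
subject) were chosen so that Monte-Carlo error is negligible relative to the
decision margins involved — model iBIC gaps are hundreds of nats.

## Known limitations

- Wald inference throughout; no small-sample degrees-of-freedom corrections
  and no MCMC posteriors. The prior covariance is diagonal.
- The iBIC penalty convention (2 parameters per model parameter, total
  choices as sample size) is one of several in use; compare models within a
  fit, not iBIC values across conventions.
- The EM objective is a Laplace surrogate; tiny non-monotonicities are
  expected and tolerated up to 0.5 nats.
- The dual-Pavlovian gating by stimulus valence is an assumption, not a
  discovery procedure; models gating by the sign of learned value would
  behave differently early in learning.
- Diary analyses treat ratings as interval-scaled; ordinal treatments are out
  of scope.

## A short worked example

```{r example, eval = FALSE}
library(gonogo)

co <- gen_task_cohort(n_subjects = 12, seed = 1)
fit <- em_fit(co$trials, co$spec, seed = 2)
glance(fit)

cmp <- compare_models(
  co$trials,
  model_set(c("RW+noise+bias+2Pav", "RW+noise+bias+2Pav+session")),
  seed = 3)
best_model(cmp)

sc <- gen_symptom_cohort(changes = parameter_changes(fit), seed = 4)
tidy(fit_symptom_model(sc$series, parameter_changes(fit)))
```
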