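---
title: "Models and methods behind riskdefaults"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind riskdefaults}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskdefaults)
```

This vignette is the package's own account of its science: the choice
model, the stimulus-inversion logic, the generative scenarios the
simulator implements, the statistical machinery, and the numerical and
design choices made where the design was genuinely open.

## The choice model

Each trial offers a *safe* lottery (amount $a$ with probability
$P > 0.5$, nothing otherwise) against a *risky* lottery (amount $A$,
$|A| > |a|$, with probability $1-P$). The probability of choosing the
safe option is a softmax on the expected-utility difference,

$$p_s = \frac{1}{1 + e^{-\beta\,\Delta EU}}, \qquad
\Delta EU = P\,u(a) - (1-P)\,u(A),$$

with power utility. Two conventions matter:

* **Sign-preserving utility.** $u(x) = \mathrm{sign}(x)\,|x|^u$. Raw
  powers of negative amounts are undefined for fractional $u$; the
  sign-preserving form makes the same curvature parameter produce risk
  aversion in gains and risk seeking in losses, and keeps the stimulus
  inversion solvable on magnitudes in both frames.
* **Choice coding.** Safe = 1, risky = 0, everywhere in the package.

Probabilities are restricted to the middle range ($P \in (0.5, 0.8]$, so
$1-P \in [0.2, 0.5)$), where probability weighting is approximately
linear; the model deliberately has no probability-distortion parameter.

The logistic is evaluated in a numerically stable branch form, so that
extreme $|\beta\,\Delta EU|$ saturates to 0/1 without ever producing
`NaN` or `Inf`.

## Estimation: MAP with a Laplace posterior

`fit_map()` maximizes the Bernoulli log-likelihood plus independent
Gaussian log-priors on the natural scale — the wide, unbiased priors
$\beta \sim N(3, 10^2)$, $u \sim N(1, 10^2)$ are the defaults — using
L-BFGS-B box-constrained to the positive quadrant from a fixed
$5 \times 5$ multi-start grid, which makes the fit deterministic for a
given data set. The posterior is summarized by the Laplace approximation
(inverse numerical Hessian at the mode). The estimates this design is
anchored to were originally obtained by variational free-energy
minimization; since only point estimates feed the downstream stimulus
generation, MAP + Laplace covariance is the approximation implemented
here, with no claim of bit-equivalence to the variational machinery. If
the Hessian is degenerate (e.g. one-sided choice data), the fit is still
returned with the covariance flagged unavailable; all-identical choices
additionally warn that the estimate rests on prior shrinkage.

## Stimulus generation by model inversion

Fixing $(P, a)$, the target probability $p_s$, and the model parameters,
the risky magnitude solves in closed form:

$$|A| = \left(\frac{P\,|a|^u - \mathrm{logit}(p_s)/\beta}{1-P}\right)^{1/u}.$$

Substituting the solution back into the forward model reproduces the
target to $10^{-10}$, which the test suite asserts on a thousand random
feasible configurations. (Note the sign: the log-odds term is
*subtracted*. A higher safe-choice target requires a *less* attractive,
i.e. smaller, risky amount; the subtracted form is the one that
round-trips through the forward model.)

Defaults chosen where the original sampling scheme was unspecified, held
fixed throughout: $P$ uniform on $\{0.55, 0.60, \dots, 0.80\}$, $|a|$
uniform on $[2, 10]$ currency units, amounts rounded to a 0.05 quantum,
risky magnitudes capped at 60, and rejected draws (rounding violating
$|A| > |a|$, or the cap) resampled with at most tenfold oversampling.
These reproduce the displayed exemplar (65% of 6.95 vs 35% of 9.15) in
scale. With a constant per-trial target — the default — the set-level mean
of the model-implied $p_s$ equals the target *exactly* before rounding,
and within 0.02 after rounding; optional truncated-Gaussian target jitter
is available for heterogeneous sets.

**Loss frame.** Sign-preserving utility makes $\Delta EU$ flip sign with
the amounts, so the generator solves magnitudes at the mirrored target
$1 - p_s$ and negates the amounts. A loss set at target $t$ therefore has
exactly the sign-flipped magnitudes of a gain set at $1-t$ from the same
seed, and its model-implied safe-choice probability equals $t$, which is
what the choice-proportion manipulation requires.

## The experiment simulator

`design_spec()` encodes the two-session design: 72 self-paced priming
trials (which establish each group's dominant option from trial one),
then 18 blocks of 18 trials in which time pressure (TP, coded −1/0/+1)
is crossed with time on task (ToT, consecutive thirds of the blocks,
coded −1/0/+1) such that every stage contains exactly two blocks of every
TP level; TP orders rotate over subjects and stages in a Latin square.
Choice proportion (CP) is between-subjects: the safe-default group gets a
0.70-target stimulus set, the risky-default group a 0.30-target set.

`scenario_spec()` selects the generative hypothesis:

* **none** — pure softmax; the null for calibration studies.
* **natural** — a single-process account: TP adds
  `natural_bias * tp * frame_sign` to the choice logit (toward safe in
  gains, risky in losses).
* **dominant** — TP-scaled bias `dominant_bias * tp` toward the subject's
  *own running-majority* option (repetition of one's own choices, not of
  stimuli).
* **learned** — a dual-process mixture: with probability
  $m(\mathrm{ToT}) = \mathrm{clip}(m_0 + m_1\,\mathrm{ToT},\,0,\,1)$ a
  fast default process emits the running-majority option; otherwise the
  deliberative softmax decides. TP never alters $m$. On trial one, or at
  a tied majority, the mechanisms fall back to the plain softmax.

**Response times.** The RT generative family is this package's own
construction — the underlying study specifies none — and was chosen to be
a minimal standard behavioral RT model: shifted lognormals per process.
Deliberative: shift 300 ms, meanlog 6.5, sdlog 0.45, with meanlog reduced
by 0.25 per TP unit (so subjects speed up under time pressure under every
scenario, which the manipulation check must find). Default process: shift
200 ms, meanlog 5.8, sdlog 0.4, TP-invariant. These put RTs in a
plausible 300–3000 ms range. Crucially, under `learned` the marginal RT
distribution at each ToT stage is a *true binary mixture* of two fixed
base distributions (the TP composition of every stage is identical by
design balance), while under `natural`/`dominant` TP shifts the single
deliberative distribution — so the fixed-point property should hold
across ToT under `learned` and fail across TP under the single-process
scenarios. That is the simulator's ground truth for sensitivity tests.

**Between-subject heterogeneity.** Subjects draw individual
$(\beta, u)$ from truncated normals around the base values with SDs 0.3
and 0.02, and an individual log-speed shift ($SD = 0.2$) applied to both
RT processes. The choice-parameter SDs are deliberately *not* the large
between-subject SDs reported for individual estimates (3.65 and 0.54):
those spread mostly along the $\beta$–$u$ identifiability ridge, and used
as independent generative SDs they destroy the choice-proportion
manipulation (simulated priming proportions collapse toward 0.5 with
spread ±0.29, contradicting the observed 67% ± .06). The implemented SDs
are instead calibrated so that simulated priming-session proportions
reproduce the empirically observed dispersion (about ±.06 for the
safe-default and ±.08 for the risky-default group at 72 trials).

**Seeding.** One master seed; stimulus-set seeds and per-subject
substream seeds are drawn from the master stream (not by arithmetic
offsets, which would correlate replicates across adjacent seeds), so a
replicate suite over seeds $s, s+1, \dots$ consists of independent
experiments and the output is invariant to subject order.

## Choice analyses

* `priming_proportion_test()` — one-sample $t$ on subject-level
  safe-choice proportions against 0.5, one-sided in the group's designed
  direction by default. One-sided is the implemented default because the
  design specifies each group's direction a priori (and the reported
  pattern of $t$/$p$ pairs this package is anchored to matches one-sided
  tails).
* `fit_mixed_logistic()` / `fit_mixed_model()` — mixed logistic
  (`lme4::glmer`, Laplace; optional `nAGQ = 0` fast mode for large
  simulation studies) or linear mixed models fitted by ML
  (`lmerTest::lmer`, Satterthwaite $p$-values). TP and ToT enter as
  cardinal −1/0/+1 codes; CP as a ±1 contrast (safe-default = +1).
  Random structure: per-subject intercepts plus TP and ToT slopes, held
  fixed across compared models (an intercept-only option exists for
  scaled-down simulation studies). ToT stages are assigned from block
  position: 1–6 / 7–12 / 13–18.
* `backward_select()` — from the full TP×ToT×CP factorial, repeatedly
  removes the least-significant removable term (largest Wald $p$;
  interactions before main effects; a main effect never leaves while a
  retained interaction contains it; ties broken by interaction order then
  lexicographically), tests each removal by a likelihood-ratio test
  against the parent model, and stops — keeping the parent — when the
  LRT is significant at $\alpha = 0.05$ (configurable). All fits are ML,
  so LRTs are valid for fixed-effect comparisons.
* `rt_manipulation_check()` — linear mixed model of RT (in seconds) on
  TP; on simulator output the TP slope is negative.

**Type-I behavior of stepwise selection.** Under the null scenario the
probability that the *final* model retains some spurious TP/ToT term is
approximately $0.26$–$0.30$, not $\alpha$: the three-way interaction
survives whenever its own test is significant (rate $\alpha$), and the
last-tested member of each term class is the class minimum-$p$ term,
retained at rate $\approx 1-(1-\alpha)^3$. This is a structural property
of backward selection, reproduced (not caused) by this implementation;
the calibration suite measures it at $\approx 0.3$ over 200 null
experiments. Per-step LRTs are individually well calibrated, and the
final model is intercept + CP only in the clear majority of null runs.

## The fixed-point test

Three steps, re-implemented from their description:

1. **Density estimation.** Per participant and condition, a Gaussian KDE
   evaluated by explicit kernel sum (no FFT binning) on one common grid
   of 512 points spanning the participant's pooled RT range extended by
   three bandwidths. The kernel SD equals the SD of the participant's
   RTs collapsed across conditions. This drastically oversmooths — but
   smoothing every condition with the *same* kernel preserves the
   fixed-point property exactly (a mixture convolved with a kernel is the
   same-weight mixture of convolved bases), so crossings remain valid;
   their common location is the smoothed base intersection. Participants
   with fewer than 5 RTs in any condition are excluded with a logged
   reason, never silently.
2. **Crossing extraction.** Sign changes of the density difference,
   refined by linear interpolation. With three conditions this yields
   exactly three pairwise crossings per participant. When kernel noise
   produces several candidates, the selected crossing is the one where
   the integrated density difference (the CDF difference) is extremal.
   Two alternatives were evaluated and rejected: restricting to the
   interval between the two conditions' medians and/or picking the
   highest-density crossing systematically drag each pair's crossing
   toward that pair's own density peak (measured pair-dependent biases of
   30–100 ms with a consistent ordering, enough to defeat the test on
   true mixtures). The CDF-difference extremum is exactly the base
   intersection for true mixtures, is far more noise-stable than any
   pointwise criterion, and uses only the pair's own data — important
   because borrowing information across pairs would bias the test toward
   finding a common crossing and invalidate the negative control.
3. **Bayes factor.** One-way repeated-measures ANOVA of crossings on the
   condition pair (participant as blocking factor), summarized by the
   BIC approximation $BF_{01} = \exp((BIC_{\mathrm{effect}} -
   BIC_{\mathrm{null}})/2)$ (unit-information prior). $BF_{01} > 1$
   favors one common crossing population — the fixed point, hence a
   mixture account. The original analysis cites a Bayesian ANOVA without
   formulas, so magnitudes are comparable in direction only; the BIC
   route is standard, and the suite verifies it against a direct
   computation from the two models' maximized likelihoods. Participants
   with any missing crossing are excluded and logged.

Validation: analytic equal-variance Gaussian mixtures cross at the known
component intersection; the KDE pipeline recovers the common crossing
with error shrinking in $n$ (checked at $n \in \{200, 1000, 5000\}$);
pure shift families produce crossings at pairwise midpoints, which
differ — the negative control. End-to-end, at the default design (19
subjects per group), the ToT test on learned-default simulations returns
$BF_{01} > 1$ in about 90% of replicate experiments, and the TP test on
natural-default simulations returns $BF_{01} < 1$ essentially always.

## Problem sizes and reproducibility

The simulation suites use sizes chosen to give stable Monte-Carlo
answers at ordinary desk runtimes: parameter recovery at 216 trials per
subject (the no-time-pressure block size) over 40 subjects for the
headline numbers and 200 subjects for the recovery property; fixed-point
discrimination over 50 replicate experiments at the default design;
selection calibration over 200 null experiments at 6 subjects per group
with intercept-only fast fits. Every stochastic quantity is reproducible
from a single master seed.

## What the synthetic results do not show

The generator emulates the *design* and the hypothesized statistical
structure, not human data: lognormal RTs with a fixed TP speed-up, exact
design balance, no lapses, fatigue, feedback effects, or learning beyond
the specified mechanisms, and heterogeneity reduced to three scalar SDs.
Passing tests therefore establish that the machinery is correct and that
the analyses recover the generative structure they were designed for —
not that any particular empirical coefficient or Bayes factor from human
experiments will reproduce. Reproducing published human-data coefficients
is explicitly out of reach (the raw behavioral data are not deposited)
and is not attempted anywhere in the package.
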