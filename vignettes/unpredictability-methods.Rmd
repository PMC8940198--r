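---
title: "Quantifying caregiver sensory-signal unpredictability: methods and design"
author: "upsens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying caregiver sensory-signal unpredictability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upsens)
```

## The construct and its statistic

During free-play interaction a caregiver emits sensory signals to the
child in three modalities: auditory (vocalisations), visual (manipulating
or presenting objects), and tactile (touching, stroking, holding).  At
any instant the signalling configuration is one of the $2^3 = 8$
presence/absence combinations of the three modalities; we index them
$s = 4a + 2v + t \in \{0, \dots, 7\}$, with state 0 the no-behaviour
state — a full member of the state space, usable as transition origin and
destination like any other.

The sequence of *distinct* combinations visited over a session is treated
as a realisation of a first-order discrete-state Markov process.  Because
a "transition" is by definition a change of combination, self-transitions
are structurally impossible: each of the 8 origin states has 7 admissible
destinations.  With $\pi_i$ the probability of observing origin state $i$
and $p_{ij}$ the conditional probability of moving to $j$, the
unpredictability statistic is the entropy rate

$$H \;=\; -\sum_i \pi_i \sum_j p_{ij} \log_2 p_{ij}
\qquad \text{bits per transition},$$

with the convention $0 \log 0 = 0$.  $H = 0$ exactly when every visited
origin has a deterministic successor (a perfectly repetitive caregiver),
and $H = \log_2 7 \approx 2.807$ when every transition is uniformly
random over the 7 admissible destinations.  Dwell times are carried
through the pipeline for bookkeeping but deliberately ignored by the
statistic, which depends only on the order of distinct states.

## From event logs to state sequences

Coded sessions arrive as interval-coded event logs (one row per behaviour
bout with onset/offset in seconds).  `read_session_log()` validates rows
(numeric times, `offset > onset`) and reports offending line numbers;
`build_state_timeline()` sweeps the union of all onsets and offsets and
evaluates the three modality flags on each elementary segment.  Two
conventions matter and are fixed here:

* **Half-open intervals.**  Bouts occupy $[\text{onset}, \text{offset})$.
  A bout ending at the instant another begins therefore produces a clean
  handover with no spurious overlap state and no zero-length gap.
* **Child attention and the visual flag.**  The coding scheme records
  both caregiver object manipulation and whether the child visually
  attends to it.  Whether the *visual signal received by the child*
  requires the conjunction of the two is a genuinely open design choice;
  we default to `attention_mode = "conjunction"` (the visual channel
  counts only while the child attends, which is what "signal to the
  child" means operationally) and expose `"mother_only"` as an
  alternative.  Under `"mother_only"`, attention events are provably
  inert: adding or removing them never changes the state sequence.

`collapse_to_state_sequence()` merges consecutive identical states,
accumulating dwell time.  No minimum-segment smoothing is applied by
default: every coded change-point counts.  Unknown behaviour codes are an
error in strict mode and skippable with a warning otherwise.

## Estimation choices

`estimate_transition_model()` tallies the $8 \times 8$ transition counts
(structurally zero diagonal) and row-normalises the maximum-likelihood
$\hat p_{ij}$.  Two estimator decisions are configurable because short
observational sessions make them non-trivial:

* **Origin weights $\pi$.**  The default is the *empirical* origin
  frequency $\hat\pi_i = n_{i\cdot}/n$, which is well defined for any
  observed chain, including short or effectively non-ergodic ones.  The
  stationary distribution of $\hat P$ is available via
  `pi = "stationary"`; on long ergodic chains the two agree, and a test
  verifies this.
* **Bias correction.**  The plug-in estimator is biased downward in short
  sessions (more strongly the shorter the session).  A Miller–Madow
  correction, adding $(K_i - 1)/(2 N_i \ln 2)$ per visited row, is
  available via `correction = "miller_madow"`; the default remains the
  uncorrected plug-in estimator, the field's standard.

Sessions with fewer than `min_transitions = 10` transitions are flagged
rather than dropped — exclusion is a cohort-level decision, not an
estimator-level one.  A session with no transitions at all has no defined
transition structure and raises an insufficient-data error naming the
session.

## The synthetic cohort generator

No deposited observational data exist for this design, so every
downstream stage is exercised against a generator whose statistical
structure is planted and therefore known exactly.

**The predictability family.**  Per-dyad unpredictability is generated
from a one-parameter mixture
$M(\lambda) = (1-\lambda)\,C + \lambda\,U$, where $C$ is the
deterministic 8-cycle and $U$ the uniform zero-diagonal matrix.  This
family was chosen because it spans the entire attainable range
$[0, \log_2 7]$ with a single knob and, both $C$ and $U$ being doubly
stochastic, has a uniform stationary distribution and hence the closed
form $H(\lambda) = -p_0\log_2 p_0 - 6q\log_2 q$ with $q = \lambda/7$,
$p_0 = 1-\lambda+q$.  $H$ is strictly increasing in $\lambda$, so
`calibrate_lambda()` can invert it by bisection to plant any target
entropy to $10^{-6}$ bits or better.

**Cohort structure.**  Latent dyad traits (entropy and sensitivity at 8
and 30 months) are drawn from a 4-variate Gaussian with the configured
means, SDs and correlations (defaults: entropy 0.87/0.16 and 0.79/0.13
bits with cross-age $r = .296$; sensitivity 5.36/1.32 and 5.27/1.05 with
cross-age $r = .293$; within-age entropy–sensitivity $r = -.279$ and
$-.146$).  The two cross pairs not pinned by a configured value are
filled by the product of the adjacent correlations — a smooth,
positive-definite completion at the defaults, checked at configuration
time.  Trajectory-class membership is Bernoulli (probabilities 68/356 and
33/356 for the elevated depressive and anxiety classes) and shifts
30-month sensitivity by the configured class contrasts
($4.66 - 5.30 = -0.64$ and $4.79 - 5.21 = -0.42$), centred so the
configured marginal mean is preserved; the latent variance of 30-month
sensitivity is deflated by the contrast variance so that the realised
marginal SD and the correlations involving it stay at their configured
values.  Demographic covariates are sampled from the configured
frequencies and have no planted effect on any outcome, so covariate
screens and adjusted models should (and do, in tests) return null
covariate effects alongside the class effect.

Two realisation modes are provided.  In `"closed_form"` (default) each
dyad's entropy is the exact entropy of its calibrated matrix — the
latent trait made observable without estimation noise.  In `"simulate"`
a Markov session of Poisson-distributed length (means 150 transitions at
8 months, 110 at 30 months — plausible magnitudes for 10-minute sessions
with dwell times of a few seconds; transition counts are not published
for real sessions, so these are assumptions) is simulated per dyad and
age, and entropy is *estimated* from the realised path, so sampling
error and plug-in bias are present exactly as in real coded sessions.
Simulated sessions can be rendered back into overlapping behaviour-bout
intervals and re-parsed; a round-trip test verifies that
parse–sweep–collapse recovers the generating sequence identically.

**What the generator does *not* emulate** — and what passing tests
therefore do not establish about real data: coder disagreement and
drift; ordinal granularity of the 1–7 sensitivity scale (continuous by
default, half-point quantisation available); non-exponential dwell
structure or diurnal/segment effects within sessions; missing data
(generated cohorts are complete); selection effects in cohort
participation; and any causal structure — all associations are planted
correlations.

Two known, deliberate approximations at the default configuration:
clipping sensitivity to $[1, 7]$ pulls the realised 8-month mean down by
about 0.03 and attenuates the realised class contrast from $-0.64$ to
about $-0.57$ (bounded instruments compress the tail where the
low-symptom class sits); the configured values are moments of the latent
process.  Where range bounds are inactive, the generator honours every
configured first and second moment within Monte-Carlo error — a property
test checks all of them at $n = 10^5$ against 3-standard-error bands.

## The growth mixture model

Repeated symptom scores (EPDS at 7 occasions, SCL-90 anxiety at 6,
from gestational week 14 to 24 months postpartum) are modelled as a
K-class mixture of linear growth curves.  Occasions are coded
$t = 0, \dots, T-1$ so the class intercept is the level at the first
assessment.  The default, `random_effects = FALSE`, is the parsimonious
model: class-specific fixed intercept and slope, shared homoscedastic
residual variance, $3K$ free parameters.  `random_effects = "diagonal"`
adds independent subject-level intercept and slope deviations (shared
variances, marginal covariance $Z\,\mathrm{diag}(\tau)Z' + \sigma^2 I$).
This is deliberately simpler than a full mixture-SEM treatment: only
class intercepts, slopes and sizes are available as reference values, so
richer covariance structures would be unidentified against them; total
scores, not item-level scores, are modelled for the same reason.

Estimation is EM from `n_starts = 20` random hard partitions, keeping
the best converged log-likelihood.  The E- and M-steps of the default
model are closed-form, and the log-likelihood is non-decreasing across
iterations — asserted, not assumed, in the test suite.  With random
effects the variance components are updated by a safeguarded numeric
ascent of the expected complete-data objective; if floating-point noise
near the $\tau \to 0$ boundary would decrease the observed
log-likelihood, the update falls back to the exact means-and-weights
step, preserving monotonicity.  Convergence is declared at a relative
log-likelihood change below `tol = 1e-8`; a start whose smallest mixing
proportion falls below $1/n$ is abandoned as degenerate and replaced by
the next start.  Classes are relabelled in order of increasing intercept,
which makes "class 2 is the elevated class" deterministic; exact
posterior ties in modal assignment break to the lower class index and
are flagged.  Missing occasions contribute nothing to a subject's
likelihood (observed-occasion likelihood, i.e. ML under
missing-at-random).

Model-selection quantities mirror standard mixture practice:
$\mathrm{BIC} = -2\ell + p\ln n_{\text{subjects}}$ (lower is better),
the mean maximum posterior within each assigned class (read against the
0.80 guideline), and the 0–1 classification entropy
$1 - \sum_{ik}(-p_{ik}\ln p_{ik})/(N\ln K)$ — crisp assignment gives 1.
The latter is a *classification* index, unrelated to the Markov entropy
rate despite the shared word.

## The analysis layer

The cohort statistics are thin, validated wrappers over the classical
base-R machinery (`t.test`, `cor.test`, `aov`, `lm`), returning uniform
records: paired t for 8-vs-30-month change, Pearson r for stability and
cross-construct association, pooled-variance t and one-way ANOVA for
group comparisons, and dummy-coded least-squares linear models with
declared reference levels (University education, highest income bracket,
girls, low-symptom class) for the covariate-adjusted class effects.
Coefficients are unstandardised contrasts — commensurate with raw group
mean differences.  Effect size is partial
$\eta^2 = SS_{\text{term}}/(SS_{\text{term}} + SS_{\text{resid}})$ from
marginal (drop-one) sums of squares; with no interactions this equals the
Type-II/Type-III value, and the generator's balanced, effect-free
covariates make the distinction immaterial in any case.  All p-values
are two-sided and unadjusted for multiplicity, and the report header says
so.  Listwise deletion is applied across analysis variables.
`run_pipeline()` orchestrates the full sequence — covariate screen, age
comparison, stability/cross-construct correlations, class comparisons,
adjusted models, and the transitions-vs-entropy diagnostic — and stamps
every report with n, the generator seed and a configuration hash.

Every statistic is verified against an independently coded brute-force
oracle (explicit sums of squares, normal equations, loop-tallied
transition counts) to $10^{-10}$ on small fixtures, and the tests check
empirical type-I error calibration of each test at $\alpha = 0.05$ over
1000 null replicates.

## Numerical and scale choices in the test-bed

Problem sizes used by the test suite and the reproduction script were
chosen to make Monte-Carlo error comfortably smaller than the property
being checked while keeping a full run in well under a minute of compute:
estimator consistency at $10^5$ transitions (5 random kernels, error
$\le 0.01$ bits), generator calibration at $10^5$ dyads (mean within
0.01 bits), 200 replicate cohorts of 103 dyads for the paired-t
self-consistency check, and 20 simulation seeds $\times$ 20 EM starts for
trajectory-class recovery (median elevated-class intercept within 0.5 of
the generating 11.24).  Trajectory noise defaults to residual SD 2 with
no random effects — modest occasion-level noise around well-separated
class lines, the regime in which a two-class solution is the clearly
preferred model, as the BIC comparison test confirms.

## Limitations

The package quantifies *patterning*, not content or quality, of
caregiver signals; the statistic is blind to what is said or shown.  The
first-order Markov assumption ignores longer-range dependence, and
dwell-time-weighted variants are deliberately out of scope.  Plug-in
entropy estimates from sessions of one or two hundred transitions carry
a downward bias of a few hundredths of a bit that varies with session
length; comparisons across conditions with systematically different
session lengths should use the Miller–Madow option.  The growth mixture
model is a simplified two-level specification; it is not a reimplementation
of any particular SEM software's estimator, and recovered parameters are
compared to generating values, not to any external fit.  Synthetic
cohorts demonstrate self-consistency of the pipeline, not validity on
real dyads.
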