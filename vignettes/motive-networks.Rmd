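---
title: "Estimating idiographic motive networks from experience-sampling data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating idiographic motive networks from experience-sampling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motivenets)
```

## The problem and the model

Experience-sampling studies prompt participants a handful of times per day
to rate, among other things, how satisfied each of their central
psychological motives currently is. `motivenets` treats one participant's
ratings as a short multivariate time series and asks how the motives
interact *within* that person: does satisfying "intimacy" tend to come with
satisfying "autonomy" (concordance), or at its expense (discordance)?

The statistical object is the **contemporaneous partial-correlation
network**. Let $x_t \in \mathbb{R}^m$ be the $m = 7$ selected motive ratings
at beep $t$. A lag-1 temporal model

$$x_t = c + B\,x_{t-1} + \varepsilon_t$$

absorbs carry-over from the previous beep; the network lives in the
innovations: with residual covariance $S$ and precision $K = S^{-1}$, the
edge between nodes $i$ and $j$ is

$$w_{ij} = -\,\frac{K_{ij}}{\sqrt{K_{ii}K_{jj}}},$$

the correlation between motives $i$ and $j$ at the same moment after
conditioning on all other motives and on the previous beep. Positive edges
are concordant, negative edges discordant. Three scalar indices summarise a
person's signed network: the conflict proportion
$\sum_{w<0}|w| \big/ \sum |w|$, the maximum conflict $\min(w)$ (0 if no edge
is negative), and the maximum concordance $\max(w)$ (0 if no edge is
positive). Between-person models then regress a depression score on mean
motive satisfaction plus one index at a time; a within-person hybrid mixed
model relates momentary mood to person-mean-centred satisfaction.

## Estimation choices

**Day boundaries.** Consecutive beeps are ~2 h apart; the overnight gap is
~12 h. Lag-1 pairs are therefore formed only within days, and the
synthetic generator likewise restarts each day from the stationary
distribution. Lagging across nights would pretend the 12-hour gap carries
the same dynamics as the 2-hour one.

**Missing slots.** Series are assembled on the full 36-slot grid with
missing rows kept in place, so a missing beep removes exactly its incoming
and outgoing lag pair (listwise per pair) and never causes spurious pairs
across the gap. No imputation is attempted.

**No standardisation.** Ratings enter on their raw 0–9 scale; residuals are
only centred. Partial correlations are scale-free, so this affects nothing
downstream (a property-based test rescales single nodes and checks
invariance), but it keeps the temporal coefficients interpretable.

**Ridge ladder.** With 7 nodes and at most 30 usable pairs, $S$ can be
ill-conditioned. Before inversion the smallest ridge from the geometric
ladder $\{0, 10^{-5}, \dots, 1\} \times \overline{\mathrm{diag}(S)}$ is
applied that brings the condition number below $10^8$. The ridge actually
used is recorded in each network object.

**Pooled shrinkage (`mode = "pooled_shrunk"`, the pipeline default).**
Multilevel VAR estimators partially pool information across persons. This
package keeps per-person fits transparent and instead shrinks each person's
residual *correlation* matrix toward the pair-count-weighted cohort average
$\bar R$ with weight $\lambda = m/(m + n_{\text{pairs}})$ before inversion —
an empirical-Bayes stand-in for the full joint likelihood, whose random-
effect machinery the estimand (per-person networks) does not require.
Shrinking on the correlation scale is exact because partial correlations are
scale-free. In simulation at the study's dimensions the pooled mode roughly
halves the mean absolute edge error relative to independent fits
(`mode = "person_wise"`), which is also asserted by a test. Forcing
$\lambda = 1$ collapses everyone onto the pooled network; $\lambda$ is
recorded per person.

**No edge pruning.** Indices consume raw signed partial correlations. An
optional absolute floor (`floor_abs`, default 0 = off) exists to probe how
sensitive the indices are to tiny estimated edges, because software that
prunes near-zero edges would report many more exact-zero-conflict persons.

**Degenerate inputs.** A node that is constant over the usable pairs is
dropped with a warning; persons with fewer than `min_pairs = 12` usable
pairs (mirroring the 12-assessment inclusion rule) are flagged and excluded
from the network stage rather than silently dropped; a residual covariance
that stays uninvertible at the top of the ridge ladder flags the person.

## Inference choices

**BCa bootstrap.** The person-level depression outcome is floor-heavy and
right-skewed, and OLS residual diagnostics (skewness, a Breusch–Pagan flag)
are reported to show it. Inference therefore uses nonparametric *case*
resampling of persons — not residual resampling, which would assume the
very homoscedasticity that is in doubt — with bias-corrected and
accelerated intervals: $z_0 = \Phi^{-1}\!\big(\#\{\hat\theta^*_b <
\hat\theta\}/B\big)$, acceleration $a$ from the jackknife skewness of
leave-one-out estimates, and adjusted percentile endpoints (quantile type
6). With $z_0 = a = 0$ the construction reproduces the raw percentile
interval exactly, which a test asserts. The bootstrap p-value is the
smallest $\alpha$ at which the $1-\alpha$ interval excludes zero, found by
bisection on the *same* resample set, so the reported interval and p-value
can never disagree. One seed drives all three models through per-model
substreams.

**Hybrid mixed model.** Momentary mood is regressed on the person's mean
satisfaction (between-person effect) and the person-mean-centred deviation
(within-person effect) with a random intercept, fitted by maximum
likelihood (not REML) via `lme4`; fixed effects get Wald z-tests. Random
slopes and autocorrelated residuals are deliberately out of scope. If the
predictor has no within-person variance the within-person slope is flagged
inestimable instead of being reported as a number.

## What the synthetic generator emulates — and what it does not

The generator reproduces the design margins a study of this kind reports:
51 participants × 6 days × 6 beeps (36 slots), prompts pseudo-random in
9:30–21:30 with ≥ 60 min spacing, ~19% missingness, ~5% manually initiated
entries, 7 motives selected per person from a 14-motive catalogue with
importance scores constructed so selection is deterministic, ratings
discretised to the 0–9 integer scale (round half-up, clipped), and a
depression score `max(1, 2.65 − 0.15·satisfaction − 1.1·concordance +
N(0, 0.6))` whose floor produces the skew that motivates the bootstrap.
Planted networks are mostly positive with a 10% chance of a negative edge
per pair; edge magnitudes are drawn right-skewed
(`lo + (hi−lo)·Beta(1,3)`), giving a planted negative edge-mass share
around 7–10%, roughly one person in ten with no negative edge, and a
minority of strong edges. A dense network of uniformly strong positive
partial correlations is mathematically impossible (the precision matrix
leaves the positive-definite cone), which is why magnitudes must be mostly
small; when a draw still lands outside the cone it is repaired by diagonal
loading, which shrinks magnitudes but never flips a planted sign.

Deliberately **not** modelled: time-of-day or weekend cycles, reactivity to
assessment, informative missingness (missingness is completely at random —
the minimal assumption, flagged here because real dropout is rarely MCAR),
avoidance motives, and any difference between prompted and manual entries.
Passing tests therefore show the estimators recover the truth *under these
conditions*; they cannot show robustness to systematic missingness or
non-stationarity in real data.

The per-person RNG is fanned out from one global seed by participant index,
so enlarging a simulated cohort never changes earlier participants, and a
fixed seed reproduces a study bit-for-bit.

## Finite-sample behaviour worth knowing

With $T = 36$ scheduled slots (~19 usable pairs after missingness) and 21
edges, per-edge sampling noise is large. Two consequences show up in every
synthetic run and would equally affect real data of this size:

* the estimated conflict proportion is biased upward (noise scatters small
  negative edges into every network: planted ~9% vs ~28% estimated at the
  default dimensions, even with pooled shrinkage), and exact-zero-conflict
  persons become rare;
* index–outcome regression coefficients are attenuated relative to the
  planted truth because estimated indices are noisy proxies.

The package's recovery tests therefore separate scales: oracle agreement
and sign recovery are asserted on long latent series (T = 500–5000), the
monotone improvement of edge error is asserted over T ∈ {36, 100, 500,
2000} (20 seeds), and study-scale assertions are limited to quantities that
are identifiable there (the within-person LMM slope, OLS calibration,
pooled-vs-independent ordering). Problem sizes in the test suite (e.g.
1000 simulated datasets × 2000 resamples for bootstrap coverage, 500
replicates for the type-I check) were chosen as the smallest that make the
Monte-Carlo error clearly smaller than the tolerance being asserted.

## Open design points resolved here

* **Tie-breaking in motive selection** is by a fixed canonical catalogue
  order (documented in `motive_catalogue()`); the original instrument's tie
  policy is unknown, and determinism beats randomness for reproducibility.
  Node order is always canonical, so networks are comparable across persons.
* **The exploratory exclusion rule** ("no depressive symptom or motive
  conflict") is ambiguous between requiring both absences or either one.
  Both readings are implemented (`rule = "both_absent"` / `"either_absent"`);
  the default is `either_absent`, which on the replica generator drops a
  subsample of the magnitude the rule intends, whereas `both_absent` drops
  almost nobody because noisy estimated networks practically never have
  exactly zero conflict.
* **Manual entries** occupy the slot of the prompt they follow and are
  analysed identically to prompted ones; the 30-minute validity window is
  measured from prompt to response start in both cases.
* **The mood covariate** at each beep is the mean of the person's seven
  selected motive ratings; no per-item mood model is attempted.
* **Whether per-person networks should come from person-specific residual
  covariances or from a joint multilevel model** cannot be settled from the
  estimand alone; both pathways are approximated by the two estimation
  modes, and every downstream artifact records which mode produced it.

## Known limitations

Networks from 36-slot series are noisy, and all study-scale conclusions
should be read through the finite-sample caveats above. The LMM Wald tests
use a normal reference (no small-sample df correction) — defensible at
~1400 observations, anticonservative for much smaller datasets. The BCa
p-value inherits the resolution of the resample set (its floor is `2 /
n_boot`). The generator's unmodelled features listed above bound what the
test suite can certify about field data.
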