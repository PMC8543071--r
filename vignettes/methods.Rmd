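---
title: "Models and methods: simulating and analysing interference in continuous-report working memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wminterference)
```

## Scope

`wminterference` implements, end to end, the analysis of a delayed-estimation
working-memory experiment in which an interfering stimulus (to be ignored or
to be answered) appears during retention at a predictable or unpredictable
moment. Because the package must be testable without any empirical dataset,
it pairs every analysis stage with a synthetic-cohort generator whose
structure mirrors the assumptions the analyses make. A green test therefore
establishes that the estimators recover what the generative model put in —
not that the generative model is a faithful account of human behaviour.

## Orientation arithmetic

Bar orientations are 180°-periodic. All angles are canonicalised to the
half-open interval (−90, 90] so every orientation has exactly one
representation; −90 normalises to +90. Positive angles denote clockwise
(rightward) tilt. The wrapped signed difference and the wrapped absolute
deviation (≤ 90°, the reproduction error kernel) are the only primitives the
rest of the package uses, plus the *doubling transform* θ → 2θ (radians),
which maps orientation space onto the full circle so that von Mises
distributions — defined on 360° — apply. The concentration κ reported by the
mixture module lives on this doubled scale and is documented as such.

A useful anchor: the wrapped absolute deviation between two independent
uniform orientations is itself uniform on [0, 90], so its expectation — the
chance level of any orientation-matching statistic — is exactly 45°. The
acceptance suite verifies this analytically and by Monte Carlo.

## The generative response model

`generative_params()` defines the per-trial response distribution,
deliberately identical in structure to the analysis mixture:

1. with probability `p_guess` (default 0.10) the report is uniform on
   (−90, 90];
2. otherwise, on interference trials, with probability `p_swap` (default
   0.05) the report is centred on the interfering orientation (a swap);
3. otherwise it is centred on the target orientation shifted by the
   attraction pull δ(Δ) = A·sin(2Δπ/180), Δ being the signed
   interference-minus-target difference.

Angular noise is von Mises on the doubled circle with concentration
`kappa_base` (default 12, i.e. an angular SD of roughly 8° in orientation
units), sampled with the Best–Fisher rejection algorithm.

Two modelling choices deserve justification:

* **Condition effects as κ deflation.** The empirical phenomena to be
  reproduced are "errors larger under interruption than distraction" and
  "errors larger under variable than fixed onset". We implement both as
  multiplicative deflations of κ (defaults 0.75 and 0.90) because mean
  absolute error is monotone decreasing in κ, so the qualitative ordering is
  guaranteed without committing to a psychological mechanism (attention
  withdrawal, encoding disruption, …) that the analyses could not
  distinguish anyway.
* **Sinusoidal bias shape.** δ(Δ) = A·sin(2Δπ/180) is zero at Δ ∈ {0, ±90}
  (nothing to be pulled toward at identity or at the self-conjugate
  perpendicular), peaks at ±45°, and is antisymmetric — the simplest smooth
  form with the right symmetries. `A` is in degrees; the default 2°
  produces a clearly detectable but small pull, comparable to published
  attraction effects in orientation memory.

Reaction times are shifted lognormal (strictly positive, right-skewed):
probe RT shift 300 ms, meanlog log(600), sdlog 0.45; dial time shift 500 ms,
meanlog log(1400), sdlog 0.30; interrupter RT shift 150 ms, meanlog
log(350), sdlog 0.25. Temporal expectation enters the interrupter RTs as
additive offsets on the lognormal location: a constant advantage in
fixed-onset blocks (−0.08) and a per-onset-position slope (−0.06) under
variable onset, reproducing the foreperiod effect (faster responses at later
onsets as the conditional probability of imminent interference grows).

Contamination rates (defaults 1–2% per type) inject trials that each violate
exactly one exclusion rule, so the preprocessing module can be tested
rule by rule. With the default mix plus the honest lognormal RT tail caught
by the 2.5-SD rule, roughly 94% of trials survive filtering — a realistic
retention rate for an online cohort.

## Design schedule

`build_schedule()` reproduces the factorial block structure: 12 blocks × 32
trials; 24 interference trials per block (75%); blocks arranged in pairs
sharing temporal predictability with both interference types inside each
pair in random order; fixed/variable pairs alternate, which kind leads being
randomised per participant; each interference type receives one fixed-onset
block per onset (500/1250/2000 ms) in random order; variable-onset blocks
split their 24 interference trials 8/8/8 across onsets. Consequently, per
interference type, each onset occurs on exactly 24 fixed-onset and 24
pooled-variable trials — the count equality the design requires.

Every encoding display contains one leftward- and one rightward-tilted bar,
magnitudes drawn independently from the 5°-grid (±5…±85; never vertical or
horizontal). The interfering item's tilt direction is counterbalanced within
block (12/12). Where the design says only "randomised", balance is enforced
within participant rather than within block (probed screen side: 192/192).
Serial positions of no-interference trials are unconstrained (uniformly
random), as nothing in the analyses depends on them.

**Seed policy.** One master seed lives in the design spec. Per-participant
streams are derived as `(master·40503 + id·65537 + 11) mod (2^31 − 1)`, with
an intermediate modulus so all products stay below 2^53 and the derivation
is exact in double precision. Schedules and simulated cohorts are therefore
reproducible piecewise: regenerating participant 7 alone gives byte-identical
trials.

## Preprocessing

Rules are evaluated in a fixed order — absolute probe-RT cut (5000 ms),
2.5-SD probe-RT cut, dial timeout (4000 ms), distractor keypress, interrupter
miss / wrong key / slow (1000 ms) — and each rejected trial carries exactly
the first triggered reason, so rejection logs are deterministic. The 2.5-SD
statistic is computed per participant across trials of *all* conditions,
after the absolute cut and one-sided (slow tail only). Whether the original
procedure applied the absolute cut before computing the statistic is not
documented anywhere we could rely on; computing it on post-cut trials makes
the two rules compose monotonically and is flagged for sensitivity analysis.
The per-participant threshold is frozen into the log, which makes filtering
exactly idempotent when the log is passed back. Participants are excluded
when strictly more than 10% of their trials were rejected.

## Swap mixture

The fitted model is the same three-component mixture the generator uses,
with component means fixed at the known (doubled) target and interfering
orientations and a single shared κ — the standard choice in this model
family, since separate concentrations are poorly identified at realistic
swap rates. Fitting is by EM:

* 10 dispersed deterministic starting points (a fixed grid over the uniform
  weight, swap weight and κ), best final likelihood wins;
* M-step: weights from mean responsibilities; κ from the Bessel-ratio
  inverse A⁻¹(Σγ·cos(x−μ)/Σγ) via Fisher's approximation refined by
  `uniroot`, clamped to [10⁻³, 500];
* convergence at relative log-likelihood change ≤ 10⁻⁸, at most 500
  iterations; the winning run's likelihood trace is attached so monotonicity
  is checkable.

Fits require at least 20 trials. Only interference-present trials enter
`swap_table()` (no non-target exists otherwise), pooled over onsets within
each interference-type × predictability cell. A caveat the tests encode
explicitly: when the true report distribution is uniform, p_uniform is
identifiable only up to leakage into near-flat von Mises components (κ at
its floor makes the components collinear), so "all guesses" should be
asserted as flatness of the fitted density, not as p_uniform = 1.

## Bias curve and equated bias

Signed errors are demeaned per participant across *all* analyzable trials
(interference and no-interference), removing stimulus-independent response
biases. The curve averages demeaned errors in windows of full width 45°
stepped every 5° along Δ, with circular wrap on the 180° period (window
centres −90, −85, …, +85; Δ = 90 is the same point as −90). Area under the
curve is trapezoidal, integrated separately over negative and positive
centres (a 0-centre bin contributes to neither); the attraction statistic
(AUC₊ − AUC₋)/2 is positive under attraction. The per-condition *equated
bias* — (mean demeaned error over Δ>0 − mean over Δ<0)/2 — uses trial means
rather than AUCs, matching "equating the average response biases"; it feeds
the 2×2 ANOVA on bias magnitude, and pooled across conditions it feeds the
one-sample attraction t test. Conditions are pooled at the trial level
before integration (both orders are possible; pooling trials first is the
default because it weights trials, not bins).

A symmetry worth stating precisely: the statistic is invariant under a full
mirror of the world (all angles negated) and changes sign when each report
is reflected about its target. Negating *only* the interference angles
negates Δ and therefore negates the statistic — a subtlety that matters when
constructing invariance tests.

## Inference

ANOVAs operate on per-participant cell means (never trial-level data), for
balanced fully within-subjects designs with 1–3 factors. Sums of squares
come from a per-observation inclusion–exclusion (Yates) decomposition; each
effect is tested against its own effect-by-subject interaction; no
sphericity correction is applied (matching the uncorrected dfs such designs
conventionally report). Generalized eta squared for a fully within design is
SS_effect / (SS_effect + SS_subject + Σ SS_effect×subject). Cohen's d for
paired contrasts is d_z = mean(diff)/sd(diff), the variant consistent with
t = d_z·√n. Bonferroni families are a caller decision (`m` is an explicit
argument) rather than guessed from context.

Power analysis is exact: two-tailed paired-t power from the noncentral t
with noncentrality d√n and df n−1, including the (tiny) opposite-tail
rejection mass that `stats::power.t.test` neglects; `required_sample_size()`
sweeps n upward and returns the first n meeting the target. With d = 0.5,
α = 0.05, power 0.95 this yields n = 54.

## Numerical and degenerate-input choices

* κ bounds [10⁻³, 500]: below the floor the von Mises is uniform to ~10⁻³;
  above the ceiling it is narrower than any 5°-grid effect. Perfect data
  (reports ≡ targets) pin κ at the ceiling rather than diverging.
* Empty condition cells are *absent* from summaries, never zero; incomplete
  designs raise classed errors (`wm_incomplete_design`) instead of silently
  dropping subjects.
* Zero-variance differences raise `wm_degenerate_variance` rather than
  returning infinite t.
* The Cousineau–Morey SEM correction √(M/(M−1)) is undefined at M = 1 and is
  refused.
* All domain errors are classed conditions under `wm_error`, so pipelines
  can distinguish data problems from bugs.

## What the generator does not emulate

Real observers drift, fatigue, and learn; the generator is exchangeable
across trials given condition. Real swap rates may vary with Δ; the
generator's are constant. Real RT distributions show sequential effects and
speed–accuracy coupling; the generator's RTs are independent of accuracy.
Feedback-driven strategy changes, stimulus colours (carried as metadata
only), dial mechanics, and browser-specific measurement noise are out of
scope. Parameter-recovery results therefore validate the estimators, not
the psychology.

## Known limitations

* The mixture assumes the single interfering item is the only non-target;
  the non-probed memory item is not a candidate swap target (it is in some
  related paradigms).
* ANOVA is restricted to complete balanced within-subject designs; there is
  no mixed-model fallback for missing cells.
* The equated bias treats Δ = 90 trials as positive-side members by the
  wrapping convention; they carry no bias information (δ(±90) = 0) but do
  add noise.
* κ is estimated on the doubled circle; converting to an orientation-space
  SD is the user's responsibility (SD ≈ (90/π)·κ^(−1/2) degrees for large κ).
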