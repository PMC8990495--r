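---
title: "Modelling eye movements in masked-face recognition with gazehmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling eye movements in masked-face recognition with gazehmm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazehmm)
```

## The problem

When people learn and recognise faces that may be partly covered by a mask,
two things can change at once: how well they recognise the faces
(signal-detection sensitivity, d′) and *where and how consistently they
look* (their scanpath strategy). gazehmm implements a complete pipeline for
studying the second and relating it to the first:

1. summarise each participant–condition's fixation sequences with a
   person-specific hidden Markov model whose hidden states are data-driven
   Gaussian regions of interest (ROIs);
2. cluster the individual models into two representative gaze patterns and
   place every participant–condition on a likelihood-based scale between
   them;
3. measure scanning consistency with marginal and conditional fixation
   entropies of the fitted models;
4. relate mask-induced changes in these gaze measures to mask-induced
   changes in recognition performance with within-subject contrasts and
   (partial) correlations.

Because raw human data are not bundled, the package ships a synthetic
experiment generator with planted ground truth so every stage can be tested
end to end.

## Individual models: Gaussian-emission HMMs fitted by variational Bayes

A model with $K$ ROIs has a prior vector $\pi$ over the ROI of the first
fixation, a row-stochastic transition matrix $\Psi$, and per-ROI bivariate
Gaussian emissions $(\mu_k, \Sigma_k)$ over fixation position (pixels in a
face-centered frame: origin midway between the eye centers, x right, y
down). Fixation durations are carried in the data model but not modelled —
the emissions are positions only, which is the convention in this family of
scanpath analyses and one of the genuinely open choices here (nothing in the
method requires durations, and adding them would change the meaning of the
ROIs).

Fitting is by variational Bayesian EM with conjugate priors: Dirichlet on
$\pi$ and on each row of $\Psi$ (concentration 1 by default), Normal–Wishart
on each $(\mu_k, \Sigma_k^{-1})$. The E-step runs forward–backward with the
exponentiated expected log parameters; the variational lower bound is the
sum of the forward log-normalisers minus the Dirichlet and Normal–Wishart
KL terms, and is non-decreasing across iterations (a property the test
suite asserts at tolerance 1e-8). Because the bound penalises complexity,
it also selects the number of ROIs: `select_n_rois()` fits each candidate
$K$ (1–10 by default) and keeps the best bound, breaking ties toward the
smaller $K$.

Default hyperparameters are weakly informative: the ROI-mean prior sits at
the face center with strength 0.01 pseudo-observations; the covariance
prior's typical scale is a quarter of the 256-pixel face box (i.e. prior
ROI standard deviations of ~64 px), with 5 degrees of freedom. These keep
ROI centers data-driven while regularising covariances enough that
single-fixation ROIs cannot degenerate. Convergence is declared when the
bound moves by less than 1e-6 nats (300-iteration cap); 5 random restarts
by default, seeded and fully reproducible. ROIs whose expected occupancy
falls below 1e-3 fixations are pruned from the reported model, so the
effective $K$ can be below the requested one.

Numerical notes: all likelihood work is done in log space with per-fixation
rescaling; decoding (`decode_rois()`) is the max-product recursion with
deterministic ties toward the lower ROI index; a singular ROI covariance
raises an explicit model-degeneracy error rather than propagating NaNs.

## Representative patterns: hierarchical EM over virtual samples

To find shared strategies, the individual HMMs are clustered into two group
HMMs ("Pattern A" and "Pattern B"). The objective is the expected
log-likelihood of virtual samples from the input models; the implementation
draws a fixed, seeded set of virtual sequences per input model (length 10,
1000 per model by default; the tests use 40, which already recovers planted
archetypes with ≥ 97% accuracy) and runs EM for a mixture of HMMs with the
constraint that all of one model's samples move together. An inverse-Wishart
stabiliser on the group covariances makes the M-step MAP; the monitored
objective includes that penalty, so it is exactly monotone. Restarts are
initialised from randomly chosen exemplar models — one per cluster — which
is markedly more reliable than random partitions. Virtual-sample seeds are
keyed to a canonical ordering of the models' parameter signatures, so the
clustering result does not depend on input order.

Hard assignments take the responsibility arg-max (ties to the first
cluster). Two degeneracies are handled explicitly: an empty cluster
triggers one re-initialisation and, if it persists, a `degenerate` flag;
and if all input models are identical (or responsibilities end up uniform),
a single group model is fitted and duplicated, flagged degenerate, since
there is no partition to find.

In the pipeline, the pair is oriented after clustering: the group HMM with
the **higher** conditional transition entropy becomes Pattern A (broad,
exploratory) and the lower-entropy one Pattern B (consistent,
eyes-focused), matching the convention that more negative A–B values mean
more eyes-focused scanning.

`pattern_separation()` quantifies how well the two patterns separate the
participants: each participant's mean per-sequence log-likelihood under
both patterns, and a one-way two-group comparison of the signed difference
(A minus B) between the assigned groups, reported as F with partial
eta-squared and a 90% CI. The exact test layout behind this kind of
published separation statistic is not standardised; this layout is the
package's documented choice, and with a single participant in a group the
statistic is flagged unstable rather than reported.

## Gaze metrics

**A–B scale.** For a set of sequences with mean per-sequence
log-likelihoods $A$ and $B$ under the two patterns, the scale is
$(A - B) / (|A| + |B|)$, in $[-1, 1]$, positive toward Pattern A. Means
(not sums) are used so participants with unequal trial counts are
comparable — the underlying quantity is a per-trial likelihood contrast.
Swapping the patterns negates the value exactly; the degenerate case
$A = B = 0$ is defined as 0 and flagged.

**Fixation entropies.** Consistency is measured on the fitted model
parameters, not on decoded labels (decoded-label frequencies confound model
uncertainty with strategy variability): marginal entropy of the first
fixation $H(\pi)$, conditional entropy of the second given the first
$\sum_i \pi_i H(\Psi_{i\cdot})$, and of the third given the second
$\sum_j (\pi\Psi)_j H(\Psi_{j\cdot})$, in bits by default (configurable to
nats), with $0 \log 0 := 0$. Each is bounded by $\log_2 K$. Lower entropy
means more predictable, more consistent scanning.

## Behavioral statistics

`dprime()` computes $d' = z(H) - z(F)$ and criterion $-(z(H)+z(F))/2$ with
the 1/(2n) correction for perfect rates by default (exact 0/1 rates with
`correction = "none"` raise an error rather than returning infinities).
RT summaries are means of correct trials, untrimmed by default.
`paired_contrast()` gives the within-subject t with Cohen's
$d = \bar{d}/s_d$ and a noncentral-t 95% CI. `rm_anova_2x2()` computes the
two main effects and the interaction of the 2×2 within design from their
difference-score contrasts — for this design each effect's F is exactly the
square of the corresponding paired t (asserted at machine precision) — with
$\eta_p^2 = F/(F + \mathrm{df}_e)$ and a 90% noncentral-F CI (90% matching
the one-sided nature of the F test). `correlation()` is Pearson r, or the
partial correlation via residualisation on covariates with
$\mathrm{df} = n - 2 - k$; with no covariates it equals Pearson r exactly.
`flanker_effect()` is $(I - C)/(I + C)$. `required_n_regression()` scans N
for the smallest fixed-effects regression F test (numerator df = number of
predictors, noncentrality $f^2 N$) reaching the requested power; at
$f^2 = .15$, 4 predictors, power .80, $\alpha = .05$ it returns 85. No
multiple-testing correction is applied anywhere, deliberately; report
consumers should treat the correlation table as exploratory.

## The synthetic experiment

The generator emulates a 2×2 within-subject masked-face design: 88
participants × 8 blocks; per block 16 learning faces (4 per condition:
unmasked–unmasked, unmasked–masked, masked–unmasked, masked–masked,
learning condition first) and 32 recognition trials (the 16 targets plus 16
condition-matched foils); 256 unique face identities in total,
Latin-square-rotated through conditions across participants;
light/mask-color labels carried as metadata only. Learning exposure is
5 s; fixation counts per trial are truncated-at-1 Poisson with mean 15
(learning) and 6 (recognition) — exposure time is known but fixation-count
distributions are not, so these are conventions, as are the log-normal RTs
(median ~900 ms, condition shifts on the log scale).

Two prototype gaze patterns anchor the population (`make_prototypes()`,
four ROIs: broad center, eye band, nose, forehead). Pattern A starts at the
broad region and explores; Pattern B concentrates on the eye band with
self-transition ≥ .9. Each participant is a perturbed copy of their
archetype's prototype (Dirichlet-perturbed rows, jittered means, log-scaled
covariances). Condition structure is planted as:

- masked recognition (um, mm): the model is blended halfway toward
  Pattern B and its transition rows sharpened by the participant's
  `consistency_gain` trait (power transform, entropy strictly decreases);
- unmasked recognition of masked-learned faces (mu): blended toward
  Pattern B by the participant's `strategy_shift` trait;
- learning phase: the base model in both mask conditions, so the
  learning-phase null is exactly null.

Responses come from an equal-variance signal-detection model with
per-condition sensitivity `base_dprime + offset + coupling × realized
adjustment`. Offsets (uu 0, um −0.45, mu −0.55, mm −0.35) produce both
main effects, the mismatch interaction, and all three planned contrasts
below baseline at effect sizes comparable to a well-powered recognition
study. The couplings act on the *realized* adjustments — the
parameter-space shift of the mu model toward Pattern B, and the closed-form
entropy reduction of the um model — rather than on the propensity traits,
because a participant already near Pattern B has no room to shift: coupling
to the trait would reward adjustments that never show up in the data. With
strategy 3.5 d′ per unit adjustment and consistency 0.6 d′ per bit, larger
measured strategy adjustment predicts smaller impairment and the planted
change–change correlations sit near −0.3, the scale typical of
individual-difference effects in recognition studies. Cognitive covariates (an
intelligence proxy, working memory, planning, attention) load on the traits
with configurable strength so partial-correlation analyses have testable
ground truth.

What the generator does **not** emulate: real fixation spatial statistics
(saccade dynamics, center bias beyond the ROI layout), duration structure,
learning across blocks, identity-level memorability, or any effect of the
light/mask-color nuisance labels. Passing tests therefore demonstrate that
the pipeline recovers structure of this planted kind at realistic sizes —
not that any particular empirical dataset contains such structure.

## The pipeline and its problem sizes

`run_pipeline()` fits per participant two learning-phase and four
recognition-phase HMMs, clusters each phase separately (the two phases are
different tasks and get their own representative patterns), computes the
metrics and d′/RT summaries, the three planned contrasts (um, mu, mm
against the uu baseline) for all six dependent variables, and the
change–change correlations with and without covariate partialling.
Participant-cells with fewer than 10 sequences are excluded from
eye-movement (not behavioral) analyses, with a logged reason; input trial
counts always reconcile as analyzed + excluded. Reports are byte-identical
under a fixed seed: provenance records the seed and settings, never
timestamps.

Validation suites run at deliberately chosen problem sizes: individual-model
recovery uses 60 trials × 10 fixations from a well-separated 3-ROI
generator (centers ≥ 6 posterior SDs apart; means recovered within 5 px);
clustering recovery uses 40 models around the two prototypes with 40
virtual samples per model; the end-to-end check runs the full default
design once with ROI range 1–3, 2 restarts and 40 virtual samples —
analysis settings, not design changes — and verifies sign stability over
100 fresh simulations of the full design scored against the ground-truth
pattern templates (refitting ~53k HMMs across replicates would add nothing
to the sign question). All seeds are fixed in the suite.

## Known limitations

- VBEM selects ROI counts conservatively on short sequences; with very few
  trials per cell (≪ the default 64) it tends to K = 1, which makes
  entropies degenerate at 0. The per-cell minimum (10 sequences) guards the
  worst of this but does not remove it.
- The A–B scale depends on the orientation rule (higher transition entropy
  = Pattern A); populations whose true patterns do not differ in transition
  entropy would need a different orientation convention.
- The separation F statistic's df layout is a package convention (two-group
  comparison over participants); published analyses of this kind have used
  other layouts, so absolute F values are not comparable across
  implementations.
- Partial correlations assume linear covariate effects; no robust or rank
  alternatives are provided.
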