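---
title: "Models and methods behind actionrsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind actionrsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`actionrsa` implements a representational-similarity pipeline for studying
how visual, action-related, and social-affective features organize
behavioral and neural representations of observed actions. This vignette is
the package's account of the science: the models, the defaults and why they
were chosen, what the synthetic generator does and does not emulate, and the
numerical choices that matter.

## Representational dissimilarity matrices

Everything downstream operates on condensed RDMs: the
$n(n-1)/2$ upper-triangle of a symmetric dissimilarity matrix, ordered as
`stats::dist()` orders it. Each pair also carries an *evidence* weight — the
number (or weight) of independent estimates behind that pair's value. Full
designs carry unit evidence; partial designs (subjects who only saw a
subset of items) carry heterogeneous evidence, and `average_rdms()` always
averages with evidence weights so partial and full designs flow through the
same code path. For full designs this reduces to the plain mean.

Feature RDMs are Euclidean distances between item feature vectors
(multi-dimensional features are vectorized and used raw; a `standardize`
switch exists but is off by default, since distances on rating scales are
meaningful as-is), except for the activity-category model, which is a
binary same/different RDM.

## Kendall's tau-a

All RDM comparisons use Kendall's $\tau_A$:

$$\tau_A = \frac{C - D}{m(m-1)/2}$$

with $C$ and $D$ the concordant and discordant entry-pair counts and the
*full* pair count in the denominator; tied pairs count as neither. This is
deliberately not $\tau_B$ (the `stats::cor` variant): with tied model
predictions — ubiquitous for categorical RDMs — $\tau_A$ penalizes the tie
rather than renormalizing it away, which makes it the conservative choice
when models with different tie structure are compared against the same data.
The implementation is an $O(m^2)$ exact count in C++; the test suite pins it
against an independently coded brute-force oracle and against the
tau-b-plus-tie-counts identity.

## Multiple arrangement and inverse MDS

The behavioral paradigm places item subsets inside a unit disk; on-screen
distances between items express dissimilarity. A session is a sequence of
trials, each a subset (3–8 items) with 2D coordinates, and ends when every
pair's accumulated evidence reaches 0.5 or a trial budget (the time-out) is
exhausted.

**Evidence model.** Each pair shown in a trial gains per-trial weight
$w = (d/\text{diameter})^2$, and evidence accumulates multiplicatively as
$1 - \prod_t (1 - w_t)$. The squared-distance utility reflects that a pair
crowded into a corner of the arena is barely informative about its relative
dissimilarity, while a pair spread across the disk is measured well. The
exact weighting used by the original adaptive platform is unpublished; this
formula is a documented stand-in validated by recovery properties, not an
assertion about the platform's internals.

**Lift-the-weakest sampling.** The next trial is seeded with the
minimum-evidence pair (preferring rarely shown items, random tie-break) and
grown by *zooming in*: unseen items join first — so a fresh session covers
every item before any repeats — after which the items most similar to the
seed pair under the arranger's dissimilarity estimate are added. Zooming is
what makes the adaptive design efficient: re-arranging a subset of mutually
similar items spreads their on-screen distances over the whole disk,
magnifying exactly the distances that were measured poorly. With this rule,
simulated full-set sessions on the 65-item set reach the 0.5 criterion in
roughly 800 trials and partial subset sessions are realistically truncated
by the trial budget, which is the package's stand-in for the task's
wall-clock time-out (defaults: 1200 trials for the full design, 160 for the
30-item subset design, chosen once to mirror the reported session lengths
of the two designs).

**Synthetic arranger.** A simulated subject embeds the subset's true
sub-RDM into the plane by classical (Torgerson) MDS, rescales isotropically
to fit the disk, and jitters each coordinate with Gaussian placement noise
(default $\sigma = 0.05$ disk units). The 2D projection is itself a
realistic distortion: humans also cannot express high-dimensional structure
in a single arrangement, and recovery of non-planar structure relies on
many partial arrangements, exactly as in the real task.

**Inverse MDS.** Reconstruction alternates between (a) fitting one positive
least-squares scale per trial that aligns its on-screen distances with the
current global estimate, and (b) re-averaging the scaled distances with
evidence weights, starting from the evidence-weighted mean and iterating to
a relative change below $10^{-6}$ (at most 100 iterations). The final
condensed vector is normalized to unit root-mean-square. The normalization
of the published dissimilarities is not defined precisely anywhere we could
follow; unit RMS is the package's choice because it makes estimates
comparable across subjects while leaving rank structure — and therefore
every $\tau_A$-based analysis — untouched.

## Time-resolved decoding

Epoched recordings (trials × channels × time) are decoded pairwise:

1. per repeat, each condition's trials are split into random halves;
2. within each half, trials are averaged into pseudotrials (never more than
   5 trials per pseudotrial, so 10 presentations yield one pseudotrial of 5
   per half);
3. a whitening transform $\Sigma^{-1/2}$ — multivariate noise
   normalization — is estimated from the *training half's raw trials only*
   (per-condition, per-bin residuals pooled over bins) with Ledoit–Wolf
   shrinkage toward a scaled identity, and applied to both halves;
4. a linear maximum-margin classifier (L1-loss SVM, cost 1, solved by dual
   coordinate descent with a regularized bias) is trained per time bin and
   scored on the test half; both fold directions are scored;
5. accuracies (%) are averaged over directions and repeats; 50% is chance.

Pooling the covariance over bins (rather than per bin) stabilizes the
estimate at realistic trial counts; per-bin covariance would be estimated
from as few as ten residual vectors per condition. The cost parameter is
fixed at 1 and not tuned. Accuracy entries form a time-resolved RDM —
higher accuracy meaning greater pattern dissimilarity — which can be
averaged over sliding windows (10 ms wide, 6 ms overlap → 4 ms stride,
window stamped at its center).

## Inference

Group inference is nonparametric throughout. The null for subject-level
scores (e.g., $\tau_A$ values) flips the sign of each subject's values at
random (5000 iterations by default; the test statistic is the group mean;
when $2^{\text{subjects}}$ does not exceed the iteration count the flips
are enumerated exhaustively). Monte-Carlo p-values use the
$(1 + \#\{null \ge obs\})/(1 + N)$ convention so no p is exactly zero.
Multiple comparisons are handled two ways:

- **omnibus max**: observed means are compared to the permutation
  distribution of the maximum mean across models (used for model batteries);
- **cluster sum**: per-window permutation p-values are thresholded at the
  cluster-forming alpha (0.05), contiguous clusters are scored by the sum of
  the group-mean statistic, and compared to the permutation distribution of
  the maximum cluster sum (used across time). The cluster-forming threshold
  is applied to p-values (each permutation's map is thresholded against the
  same permutation distribution), and the summed quantity is the group-mean
  statistic itself — the quantity under test.

Noise ceilings correlate each subject's RDM with the grand average
(upper bound, self-inclusion biased by construction) and the leave-one-out
average (lower bound). Onset uncertainty is quantified by resampling
subjects with replacement (1000 replicates, 90% central CI); replicates with
no significant cluster are reported as missing and excluded from the CI,
which is flagged unreliable if more than half are missing.

## Cross-validated variance partitioning

Seven regressions — every non-empty subset of the three predictor groups —
are fit by OLS (with intercept, predictor columns z-scored for
conditioning) on the average training RDM, and each model's prediction is
scored against the average test RDM by squared $\tau_A$. Commonality
analysis (inclusion–exclusion over the three groups) then yields three
unique, three pairwise-shared, and one triple-shared component that sum to
the full model's $\tau_A^2$ exactly, per iteration — an algebraic identity
the tests verify to $10^{-12}$. Components can be negative (suppression),
which is standard for commonality analysis and left visible rather than
clipped; $\tau^2$ of an anti-predicting model still enters positively.

Three cross-validation schemes match the three data situations: split half
of the subjects (full designs), split half of the individual similarity
estimates of every pair independently (partial designs, where different
subjects saw different items), and split half of the subjects per time
window (time-resolved RDMs). Significance is one-tailed sign permutation
over iterations, omnibus-corrected across components (behavior) or
cluster-corrected across windows per component (neural).

**Onset ordering.** For time-resolved partitions, each component's
group-significant windows are determined once (cluster-corrected over
iterations); an iteration's onset is the earliest group-significant window
at which that iteration's component value is positive. This
operationalization keeps per-iteration onsets on the window grid and
anchored to group-level evidence; it is the package's choice where the
alternatives (per-iteration inference on a single time course) are not
well-defined.

## The synthetic world

The generator emulates the study conditions with known ground truth: a
152-item set (18 activity categories × 8 exemplars + 8 agent-free
controls) and a 65-item set (3–4 exemplars per category); per-rater 5-point
ratings produced by discretizing latent Gaussian features plus rater noise
(planted "bad" raters use ≤ 2 unique values; planted catch-failers fail
catch trials); annotations (category, indoors/outdoors, binary effector
5-vectors, agents on the 0–3 scale with controls at 0); arrangement
cohorts driven by a ground-truth RDM built as a nonnegative weighted
combination of unit-RMS feature RDMs; and epoched recordings in which each
feature's RDM geometry (embedded in 5 MDS dimensions) projects onto random
orthonormal channel patterns — idiosyncratic per subject — inside a boxcar
latency window, under compound-symmetric channel noise (correlation 0.3, so
noise normalization is exercised nontrivially), 10 presentations per
condition. The one-back session design generator emits 10 pseudorandom
blocks of all 152 videos with no immediate repetitions plus 25 catch pairs
× 4 repetitions (half in each order) at random positions: 1720 trials.

What passing tests on this world do *not* show: real raters are not
Gaussian discretizers; real arrangement strategies shift criteria between
trials in ways placement jitter does not capture; and real EEG has temporal
autocorrelation, alpha rhythms, eye artifacts, and non-boxcar response
dynamics. Recovery results here validate the *machinery* — that the
pipeline finds what is planted, at the planted time, and is calibrated
under the null — not claims about any particular empirical dataset.

## Problem sizes and numerical choices

The shipped analyses and tests run the world at reduced but structurally
faithful sizes, chosen once: behavioral cohorts of 30–50 subjects on the
65-item set; recording simulations with 16 conditions, 32 channels, 10
subjects, and a 100 Hz bin grid (the sliding-window arithmetic is exercised
separately at 500 Hz); 100 split iterations for the shipped analyses and
25–50 inside parameterized tests; permutation counts of 1000–5000.
Degenerate inputs are handled explicitly: all-zero sub-RDMs place items at
the disk center with a warning; zero training covariance disables whitening
with a warning; rank-deficient regressions fall back to minimum-norm
solutions with a warning; all-tied score vectors give $\tau_A = 0$.

## Known limitations

- The evidence weight and the arranger model are stand-ins; only the 0.5
  criterion and the trial-size caps are anchored.
- The paired Wilcoxon comparison of variance components across split
  iterations inherits the field's practice of treating iterations as
  samples; iterations are correlated, so these p-values are descriptive
  rather than strictly calibrated (the package's calibration guarantees
  apply to the subject-level sign permutation machinery).
- Image-computable features beyond luminance/hue/saturation and
  Horn–Schunck flow (scene descriptors, network activations, motion
  energy, lexical similarity) enter as precomputed embeddings; the package
  does not compute them.
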