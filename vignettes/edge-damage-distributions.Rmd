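---
title: "Assemblage-scale edge damage distributions: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assemblage-scale edge damage distributions: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lithicedd)
```

## The method

Use-wear on flaked stone tools is informative less through any single scar
than through where damage accumulates along tool edges across a whole
assemblage. `lithicedd` implements the assemblage-scale edge damage
distribution (EDD) workflow:

1. **Standardize geometry.** Each digitized face outline is split at the
   platform anchor and at the distal maximum (the outline vertex farthest
   from the platform) into a left and a right platform-to-tip edge. Each
   edge is rescaled to arc-length percent, so position 1 is
   platform-adjacent and position 100 tip-adjacent regardless of tool size.
   A tool contributes one 400-position presence/absence vector
   (dorsal-left 1–100, dorsal-right 101–200, ventral-left 201–300,
   ventral-right 301–400).
2. **Aggregate.** Position-wise counts over the tools of an assemblage form
   its damage distribution; with `n` tools the ceiling is `n * 400`
   (100 tools fully damaged on all four edges give 40000). Proportions
   (counts normalized to sum 1) are the canonical comparison scale because
   assemblage sizes differ.
3. **Smooth.** Each 100-position edge block of the proportion series is
   smoothed by loess (tricube-weighted local-linear regression, span
   `alpha = 0.15`, i.e. the 15 nearest positions) to damp isolated extreme
   positions. Blocks are smoothed independently so no value borrows across
   the platform/tip boundaries of different edges.
4. **Test.** Distributions are compared by two-sample Kolmogorov–Smirnov
   tests on the damage-position multisets, by a one-sample KS test against
   the discrete uniform, and by chi-square goodness-of-fit balance tests
   (left vs right, dorsal vs ventral) without continuity correction.
5. **Fit.** An archaeological distribution is regressed on experimental
   process distributions by ordinary least squares. Reported first is the
   single best-fitting process; then a forward-stepwise model: the
   candidate with the lowest partial-F p-value enters while entry lowers
   AICc, included terms whose removal lowers AICc are dropped, and finally
   any nested sub-model within ΔAICc < 2 of the best is considered
   equivalent and the most parsimonious one is returned. Each term's share
   of the explained (model) sum of squares is attributed sequentially in
   entry order.

AICc is computed as `n log(rss / n) + 2k + 2k(k + 1)/(n - k - 1)` with `k`
counting the regression coefficients (intercept plus terms) plus one for
the error variance. `n` is the number of positions entering the regression
(400, or 100 for single-edge fits): positions, not tools, are the
regression observations, mirroring distribution-on-distribution fitting.

## Position bins and the worked example

Standardized positions are nearest-percent labels: position `i` covers
arc-length percents `[i - 0.5, i + 0.5)` (position 1 extends to 0,
position 100 to 100), and a scar marks every position whose bin its
projected arc-length span overlaps with positive length. This is the only
binning under which a 3%-of-edge scar centered at the exact midpoint marks
positions 49, 50, 51 — with 50 containing the midpoint — and nothing else;
an edge-aligned convention such as `((i-1), i]` would smear the same scar
into a fourth position. The convention is scale-free, so damage vectors
are invariant under uniform scaling and rigid motion of the digitization.

Scar projection is an exact polygon/polyline intersection (segment
crossings plus even-odd midpoint classification). A distance tolerance of
0.5% of the face perimeter is applied only as a fallback for scars that do
not touch the edge polyline at all: applying a tolerance band along the
whole polyline would stretch every span by the tolerance at each end and
break the worked example above. Degenerate inputs (self-intersecting or
zero-area outlines, anchors farther than 2% of the perimeter from the
boundary) are rejected; ties for the distal maximum are broken toward the
smaller counterclockwise arc distance from the platform, with a warning.

## Fitting scale

The package fits the **raw** proportion series of the response against the
**smoothed** proportion curves of the candidates (both switchable via
`candidates_from_distributions()`). The reason is visible in the null
behavior: when the response is a random uniform distribution (10000 draws
over 400 positions), regressing its raw proportions on one shaped
candidate yields R² of order `1/(n - 1) ≈ 0.0025` — random patterning is
attributed to nothing, and `validate_random_uniform()` reproduces exactly
that. Smoothing the response first would autocorrelate its noise, shrink
the effective degrees of freedom to the smoother's (~15-point windows),
and inflate the null R² to 0.03–0.08; a procedure with that null would
"explain" several percent of pure noise. Smoothed candidates, by contrast,
only stabilize the predictor curves.

## The synthetic generator

`process_profile()` describes a damage-formation process by a scar-center
density on [0, 100] (a uniform component plus truncated-normal bumps),
relative per-edge rate multipliers (face/side asymmetry), an expected
number of scars per tool (Poisson by default; a negative-binomial
overdispersion knob is provided), and a lognormal scar-length law in
percent of edge length. Sampling a tool draws a scar count, assigns each
scar an edge, a center and a length, and marks the covered positions;
`profile_expected_distribution()` gives the same model's noiseless curve
in closed form (center density convolved with the length law, with the
Poisson per-tool presence probability `1 - exp(-lambda * q)`).

The six default profiles emulate the qualitative shapes of the
experimental processes the method is calibrated against:

* **Armatures** (quartzite, ironstone): damage concentrated at the tip
  with a small basal bump from hafting bindings; symmetric sides.
* **Butchery** (field dressing, defleshing, and their pooled combination):
  mid-edge damage, higher on the field-dressing curve than defleshing,
  with a left-edge excess (strong for field dressing, mild for
  defleshing — a right-handed butcher). Scar rates (~14 per tool) are set
  so a ten-tool stage produces several hundred damage occurrences,
  matching the scale of reported butchery damage counts.
* **Trampling**: mostly uniform with a broad mid-edge bump — trampled
  points are non-uniform because edge angle is unevenly distributed along
  a point's edge.
* **Tumbling** (fluvial saltation analogue): shallow damage with a
  proximal concentration over a large uniform component.

Default assemblage sizes (64, 32, 10/20/10, 61, 22 tools) follow the
experimental samples being emulated. At those sizes every pair of the five
stage-level distributions differs by the two-sample KS test at p ≤ 0.05,
as the corresponding experiments do. The generator is seed-deterministic:
a fixed seed reproduces vectors bit-identically.

What the generator does **not** emulate: raw-material-specific fracture
behavior, retouch, edge-angle profiles of real points, correlated scar
clusters from single impacts, or zero-inflation from unused tools. Passing
validation on synthetic assemblages therefore demonstrates the pipeline's
statistical behavior under known truth, not field performance on any
particular archaeological collection.

## Validation experiments and what they show

Three experiments (exported, and recomputed by `scripts/acceptance.R`):

* `validate_single_recovery()`: held-out replicates of one process (the
  armature profile by default, the same design used when the method was
  introduced: an independently generated armature sample should be fitted
  by the armature model) are single-best-fitted against the four general
  process curves. Recovery is essentially total; cycling all four
  processes instead yields high but imperfect recovery because the
  trampling and pooled-butchery curves genuinely overlap.
* `validate_random_uniform()`: random uniform distributions of 10000 draws
  are fitted against all candidates; the single-best-fit R² stays well
  under 1%.
* `validate_mixture_recovery()`: assemblages generated from known one-,
  two- and three-process mixtures (weights 1; 0.6/0.4; 0.5/0.3/0.2; 150
  tools) are fitted by the stepwise procedure and scored for exact support
  recovery and weight-ranking agreement.

The third experiment exposes a real limitation of the selection rule
rather than an implementation artifact. Position-level sampling noise of
an aggregated assemblage is heteroskedastic (variance tracks the curve
height) and locally correlated (one scar marks two to three adjacent
positions), so partial-F statistics are inflated roughly threefold
relative to their nominal null distribution. The entry rule (add while
AICc falls, F ≳ 2) and the ΔAICc < 2 parsimony rule (a term survives when
its removal costs at least 2 AICc, F ≳ 4) then admit spurious terms in a
third to a half of replicates, and weak (weight 0.2) components of
flattish processes are sometimes dropped. Even under ideal independent
noise, an AICc entry rule admits each irrelevant candidate with
probability near 5%, so some over-selection is inherent to the procedure;
full stepwise models on real assemblages should be read with that in
mind, and the per-term contribution shares — not mere term presence —
carry the interpretive weight. Single-best-fit reporting is unaffected, as
it involves no entry decision.

## Numerical choices and problem sizes

* Loess windows use `ceiling(alpha * n)` nearest positions, tricube
  weights, degree 1; `alpha` below a 3-point window is rejected. Constant
  and exactly linear series are reproduced exactly.
* One-sample KS against the discrete uniform evaluates the sup over the
  `m` support points and uses the asymptotic Kolmogorov tail, slightly
  conservative on a lattice. Two-sample KS uses the standard tied-ECDF
  statistic with the asymptotic p-value; exact small-n p-values are not
  attempted at assemblage scale. Note that damage occurrences are not
  independent draws (a scar contributes a run of adjacent positions), so
  occurrence-level KS tests over-reject slightly between same-process
  samples.
* Candidates correlated above |r| = 0.999 with an included term are barred
  from entering a stepwise model, with a warning; entry-order p-value ties
  break alphabetically, making selection deterministic and independent of
  predictor input order.
* Coefficients are unconstrained; negative process loadings are legal but
  flagged (`negative_terms`), since a damage distribution cannot
  physically subtract damage.
* Default experiment sizes — 100 seeds for single recovery, 20 replicates
  of 10000 draws for the null, 200 mixtures of 150 tools — keep the full
  validation suite under a minute on one core while holding Monte-Carlo
  error on the reported rates to a few percent.

## Known limitations

Adjacent positions are treated as independent observations in both the KS
tests and the regressions; no spatial autocorrelation model is fitted.
Damage classes are taken as input labels (no morphology-based inference),
georeferencing is assumed done upstream, and the ventral mirroring of
digitizations is handled at ingestion (`read_tool_geojson(mirror_ventral=)`),
with vectors always stored in photograph-apparent coordinates.
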