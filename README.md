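# lithicedd

Assemblage-scale **edge damage distribution (EDD)** analysis for flaked
stone tools.

Individual use-wear scars on stone tools are rarely diagnostic; the
*distribution* of damage along standardized tool edges, aggregated over an
assemblage, is. `lithicedd` is for lithic analysts and taphonomists who
digitize tool outlines and damage scars (GeoJSON polygon tracings of the
dorsal and ventral faces) and want to ask: which damage-formation
processes — spear armature use, butchery, trampling, fluvial tumbling —
best explain the damage patterning on an archaeological assemblage of
points?

## The method in brief

1. Each face outline is split at the platform and at the distal maximum
   into left and right platform-to-tip edges; each edge is rescaled to
   arc-length percent. Damage scars are projected onto 1% intervals,
   giving one binary 400-position vector per tool (dorsal-left 1–100,
   dorsal-right 101–200, ventral-left 201–300, ventral-right 301–400). A
   scar 3% of edge length centered mid-edge marks positions 49, 50, 51.
2. Position-wise counts over tools form the assemblage distribution
   (100 tools × 4 edges × 100 positions = 40 000 possible); proportions
   are smoothed per edge block by loess (tricube local-linear, span
   α = 0.15).
3. Distributions are compared with Kolmogorov–Smirnov tests (two-sample,
   and one-sample against the discrete uniform) and χ² balance tests
   (left/right, dorsal/ventral; no continuity correction).
4. Experimental process distributions are treated as models for an
   archaeological distribution: ordinary least squares, forward-stepwise
   selection under AICc

   AICc = n·ln(RSS/n) + 2k + 2k(k+1)/(n−k−1)

   (k = coefficients + error variance; n = positions), entering the
   lowest-partial-F-p candidate while AICc falls, with a ΔAICc < 2
   parsimony rule, and sequential (entry-order) decomposition of the
   explained sum of squares into per-term percentage contributions.

A seed-deterministic synthetic generator (pointed outlines, process
profiles with tip/mid/proximal damage signatures and left-right
asymmetries, random uniform null distributions, known mixtures) makes the
whole pipeline testable without any field data.

## Worked example

```r
library(lithicedd)

# a synthetic pointed tool with one 3%-of-edge scar centered mid-edge
tool <- generate_synthetic_tool(
  scars = data.frame(face = "dorsal", side = "left", center = 50, length = 3))
which(build_damage_vector(tool) == 1)
#> [1] 49 50 51

# the printed defleshing left/right damage balance
chi_square_balance(170, 155)
#> <edd_test> chi_square = 0.6923, df = 1, p = 0.4054

# simulate an armature assemblage and ask which process explains it
profs <- default_process_profiles()
sim <- sample_process_distribution(profs$armature_quartzite, n_tools = 64, seed = 42)
sim$distribution
#> <edd_distribution> armature_quartzite: 400 positions, n_tools = 64, total damage = 1232

refs <- lapply(profs[general_process_names()], profile_expected_distribution)
fit_single_best(candidates_from_distributions(sim$distribution, refs))
#> <edd_fit> armature_quartzite [single]
#>   terms: armature_quartzite (100%)
#>   R^2 = 0.818, AICc = -5301.51, n = 400
```

The marked positions are the scar's percent interval on the dorsal-left
edge; the χ² of 0.692 (p = 0.405) says 170 vs 155 occurrences is
consistent with left/right balance; and the single-best-fit table names
the armature curve as the process explaining ~82% of the positional
variance in the simulated assemblage.

`forward_stepwise()` extends the last step to multi-process models with
per-term contribution percentages, and `run_pipeline()` /
the `exec/edd` command line (`vectorize`, `aggregate`, `fit`, `simulate`,
`compare`) chain the stages on files.

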