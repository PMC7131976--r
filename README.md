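# mazepoint

Analysis of directional pointing judgments in hedge-corridor mazes:
where do pointing errors come from, and which of them are *systematic* —
explained by a distorted mental representation of the environment rather
than by noise?

The package is for researchers in spatial cognition working with
onsite pointing tasks in (virtual) environmental spaces. It provides:

* **Maze geometry** — an intrinsic route description (leg lengths +
  signed turns) deterministically realized as planar coordinates with
  hedge walls, plus a packaged nine-location maze reconstruction;
* **2.5-D visibility** — line-of-sight tests, visible/non-visible
  classification of all ordered pointing pairs, and isovists
  (visible-area polygons) as a measure of *geographic scale*;
* **Circular statistics** — von Mises mixture fitting by EM with
  BIC-based unimodal/bimodal selection, bootstrap confidence sectors
  for mode directions, and systematic-mode labeling;
* **Alternative-representation modeling** — composable route edits
  (forget a segment, rescale a leg, rotate a sub-route), a packaged
  distorted representation, and per-participant model-fit comparison;
* **Cohort rules** — Raw TLX scoring, visible-error outlier exclusion
  (Q3 + 1.5 IQR), sense-of-direction median split;
* **A synthetic cohort generator** and an orchestrated
  `run_pipeline()` so the whole chain runs end-to-end reproducibly.

## The model

A pointing error is the absolute angular difference between the judged
and true azimuth, `e = min(|θ̂ − θ| mod 360, 360 − |θ̂ − θ| mod 360) ∈
[0, 180]`. For each ordered trial (origin → target), pooled judged
directions are modeled as a von Mises mixture

    f(θ) = Σₖ wₖ · exp(κₖ cos(θ − μₖ)) / (2π I₀(κₖ)),   K ∈ {1, 2},

fitted by maximum likelihood with BIC model selection. A trial is
declared **bimodal** only if K = 2 wins on BIC, both weights are ≥ 0.15,
and the modes separate by ≥ 30°. The mode deviating more from the true
direction carries the systematic errors; a single edited "alternative"
route (delete leg 5–6, compress leg 6–7 to the length of leg 8–9, rotate
the final sub-route a quarter turn) is then tested per participant and
session against the correct layout by smaller mean pointing error over
the bimodal trials.

See the methods vignette (`vignettes/pointing-error-analysis.Rmd`) for
assumptions, parameter defaults, and design rationale.

## Worked example

```r
library(mazepoint)

correct <- packaged_maze_layout()
correct
#> <maze_layout> 9 locations, 18 walls, 9 landmarks
#>   bounds: [-1.5, 45.5] x [-1.5, 23.5] m
#>   eye heights (m): ground = 1.4, elevated = 5.3

# the pointing-task design: 72 ordered trials, 16 intervisible
pairs <- classify_pointing_pairs(correct)
table(pairs$visible)
#> FALSE  TRUE
#>    56    16

# geographic scale at location 3: hedges confine the ground view to a
# sliver of the environment; the elevated view clears them entirely
isovist(correct, 3, eye_height = 1.4)$scale_ratio  # 0.055
isovist(correct, 3, eye_height = 5.3)$scale_ratio  # 1.000

# simulate a reference cohort and test one non-visible trial (3 -> 6)
alternative <- realize_layout(alternative_route(maze_route()))
cohort <- simulate_cohort(reference_config(), correct, alternative,
                          seed = 42)
ang <- subset(cohort$records, origin == 3 & target == 6)$judged
fit <- select_modality(ang, mixture_control(seed = 1))
fit
#> <vm_mixture> K = 2, n = 144, logLik = -187.38, BIC = 399.60
#>   component 1: weight 0.523, mean 34.5 deg, kappa 4.79
#>   component 2: weight 0.477, mean 140.9 deg, kappa 5.17
#>   modality: bimodal
label_systematic_mode(fit, true_direction(correct, 3, 6))
#> [1] 2
```

The trial is bimodal: about half the simulated judgments aim near the
true direction to location 6 (34.5° ≈ the correct 33.7°), the other
half near 140.9° — the direction location 6 would lie in if the leg
between locations 5 and 6 had been forgotten. Component 2 is labeled
the systematic mode. `mode_confidence_sector(ang, fit, B = 1000)` adds
95% bootstrap arcs (~15° wide here) around both mode directions.

The full chain — classification, exclusion, median split, per-target
summaries, mixture fits, model comparison, aggregation, with CSV/JSON
outputs and a manifest — runs from one configuration:

```r
run_pipeline(system.file("extdata", "example-config.yaml",
                         package = "mazepoint"))
```

A thin command-line wrapper is included at `inst/cli/mazepoint.R`
(subcommands `run`, `visibility`, `isovist`, `simulate`).

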