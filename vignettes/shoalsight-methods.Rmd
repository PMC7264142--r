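---
title: "shoalsight: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{shoalsight: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`shoalsight` analyses multi-animal 2D trajectories from group-foraging
experiments: groups of fish in an oval arena, a food-mimicking stimulus
presented at a wall port, and the question of how the group's collective
order shapes who detects the stimulus (private information, through the
visual field) and how quickly the rest follow (social information,
through responding neighbours). This vignette documents the models, the
tunable parameters, the synthetic-data generator, and the choices made
where the design was genuinely open. It states no empirical result that
the test suite does not itself compute.

## Coordinates, units and smoothing

All positions are Cartesian millimetres with the origin at the arena
centre, long axis along x and y up; pixel input (image y down) is
converted and flipped on ingestion (`readTrajectories()`, defaults
2.7 px/mm and 25 fps). Speeds are mm/frame internally; multiply by the
frame rate for mm/s. Angles are degrees at the interfaces and radians
internally.

Trajectories are smoothed with a Savitzky–Golay filter
(`smoothSavGol()`, window 13 frames ≈ 0.5 s at 25 fps, cubic
polynomial). The filter is exact on locally cubic paths and
rotation-equivariant, both asserted in the tests. Missing tracking
frames are flagged `NA` and **never interpolated**; any analysis window
containing a gap is dropped. Dropping is conservative: it costs
presentations rather than inventing positions.

The arena is an oval modelled as a **stadium** (rectangle with
semicircular caps; default 1335 × 720 mm) because ovals built from flat
sheet walls have straight long sides; an ellipse variant is available.
The four stimulus ports sit on the wall, two per long side at ±25% of
the long axis — a layout consistent with the protocol's requirement that
all fish can be ≥ 430 mm from a port while on the opposite half. Port
positions are configurable (`readArenaConfig()`) because the exact
hardware layout is a property of the rig, not of the method.

## Individual and group parameters

Headings come from **displacement** (unit central differences of the
smoothed path), not body orientation: centre-of-mass tracking carries no
body axis. Below a speed floor (default 0.3 mm/frame) direction is
undefined and the frame is excluded from heading-based quantities.

Per presentation, every parameter is summarised over the 13 frames
before onset by its **median** (robust to the skew of speed and distance
distributions); the hull-edge parameter — a membership indicator — is
instead the proportion of window frames on the hull boundary, the one
parameter for which a median makes no sense. Individual values are also
returned **relative to the group mean** (so relatives average to 1),
because being first is a within-group contest.

Group-level quantities per frame: convex hull area (shoelace on the
`chull` vertices; collinear groups have area 0 and everyone on the
edge), centroid position/speed, polarization `|Σ uᵢ|/N`, and the group
bearing to the stimulus measured from the direction of the summed unit
headings — chosen over centroid velocity for consistency with the
polarization vector; at very low polarization that direction is noisy,
which is a property of the quantity itself, not of the estimator. Across
fish we also report the **sample SD and minimum of the unsigned
bearings**. Unsigned bearings live on the segment [0°, 180°], so a
linear SD (not a circular statistic) is the right dispersion measure.
One non-implication is asserted in the tests: zero bearing SD does not
imply polarization 1 — two fish mirrored about the line to the stimulus
have identical unsigned bearings but different headings.

## Visual fields

Each fish is a **cyclopean viewer**: one eye point advanced 0.4 body
lengths along the heading (2D tracking cannot resolve two eyes).
Two sectors are modelled: a binocular sector of ±15° about the heading
and a full field of 300° total. These angles are stand-ins — the
defaults are config-exposed (`visionConfig()`), and every directional
claim the package makes is insensitive to the exact values within the
plausible range (the tests exercise the geometry, not a specific
constant). Neighbour bodies are ellipses, major axis = body length along
the heading, aspect ratio 0.2: the simplest convex, analytically
intersectable occluder.

`castField()` shoots 720 rays across the chosen sector; each stops at
the nearest of a neighbour ellipse, the arena wall (analytic
intersection with the stadium's lines and cap circles), or the maximum
range (arena diagonal). The visible region is the star-shaped polygon of
ray endpoints; coverage is its shoelace area over the arena area;
`occlusionIndex()` is the fraction of full-field rays stopped by a
neighbour. 720 rays (0.5°/ray at 360°) keep the polygon within 2%
absolute of a 2-mm grid point-visibility oracle (asserted per scene in
the acceptance tests). `collectiveCoverage()` evaluates the union of the
per-fish polygons on a grid (default 10–15 mm spacing; the union of star
polygons is not star-shaped, so a grid is the honest route;
`mgcv::in.out` does the point-in-polygon work in C).

## Events

A presentation is **valid** when every fish is ≥ 430 mm from the port,
on the opposite half of the arena, and fully tracked in the pre-window.
**Arrival** is the first frame within 500 frames (20 s) of onset at
which a fish comes within two body lengths of the port (per-fish
measured length; 27 mm cohort mean as fallback); arrivals are ranked
into arrival order with deterministic tie-breaking (distance at the
shared frame, then fish index).

**First response** has no universal operational definition from
centre-of-mass tracks, so the package declares one and treats it as a
reconstruction to be validated rather than hidden: a response begins at
the first frame where the fish's bearing to the port is < 30° *and* its
speed exceeds 1.5 × its own pre-stimulus median, both sustained for
5 consecutive frames. All four thresholds are config-exposed
(`responseCriteria()`). The arbiter of adequacy is the simulator's
ground truth: at defaults the detected first responder matches the true
first detector in ≈ 97% of generated presentations (tested at ≥ 90%).

## The synthetic shoal generator

The generator exists so that every pipeline stage can be tested, end to
end, on data whose mechanism is known. Agents follow a metric **zonal
model**: repulsion inside 60 mm (highest priority), alignment with
neighbours inside 220 mm, attraction to neighbours inside 450 mm, wall
avoidance ramping up within 80 mm, and per-frame Gaussian heading noise
(3°/frame) with a 30°/frame turn limit. Speeds and body lengths are
per-fish constants (2.2 ± 0.35 mm/frame ≈ 2 body lengths/s;
27 ± 2.4 mm), matching the study animals' scale. Twelve groups of eight
at 25 fps is the default design.

Two departures from the textbook zonal scheme were necessary:

1. **A wander term.** With purely angular noise, mean polarization
   cannot fall below the independent-headings floor (≈ 0.31 for n = 8),
   and the alignment weight saturates once it dominates the other
   steering terms — the order parameter becomes uncontrollable. Each
   agent therefore also steers toward a fresh uniformly random direction
   with fixed weight (`wWander`, default 1). The ratio
   `wAlign / wWander` then controls polarization smoothly, and
   **negative** alignment weights (active anti-alignment) reach the
   disordered regime below the independence floor. Calibration
   (`calibratePolarization()`, bisection on `wAlign` over [−1, 12];
   `wAlignForPolarization()` for batch inversion) spans mean
   polarization ≈ 0.15–0.97.
2. **Low angular noise.** 3°/frame keeps individual courses persistent
   over seconds, as cruising fish are; with fast angular diffusion a
   polarized group facing away from the stimulus would sweep its heading
   past the port within a second and the order-dependence of detection
   would vanish.

The **detection model** (`detectionModel()`) is a two-channel per-frame
hazard. *Private*: only when the stimulus is inside the binocular sector
with an unoccluded line of sight, with hazard `h0·exp(−d/λ)`
(h0 = 0.6/frame, λ = 1000 mm): detection is nearly immediate once the
stimulus is seen, so first-response latency is dominated by *when the
stimulus enters someone's binocular field* — the quantity that depends
on collective order. *Social*: hazard `s0·k·(1 + γP)` with k the number
of visible already-responding neighbours, P the pre-stimulus
polarization, s0 = 0.03 and γ = 4: transmission is faster in ordered
groups. γ = 4 rather than a smaller slope was a design-phase
calibration: with γ = 2 the transmission contrast was real but too weak
to detect reliably at feasible experiment sizes; γ = 4 makes the
generated crossover (below) stable without changing its direction.
Responders steer straight to the port at 1.8 × their base speed and stop
on arrival; responses are resimulated over each 500-frame window from
the state at onset, and the patched trajectory rejoins the original
afterwards (the positional seam sits ≥ 3 min from any analysis window
under the presentation protocol's spacing).

At these defaults the generated data carry the structure the analysis is
meant to recover, verified in the acceptance tests at these problem
sizes:

- binocular collective coverage higher in disordered (P ≈ 0.2) than
  polarized (P ≈ 0.9) groups — 200 windows per level;
- Spearman(polarization, bearing SD) < 0 and
  Spearman(polarization, minimum bearing) > 0 over 400 mixed-order
  windows;
- the fitted polarization × arrival-order interaction on log10 arrival
  latency negative in ≥ 95 of 100 seeded replicates, each replicate
  3 groups × 30 presentations spanning polarization 0.12–0.95, fitted
  with group bearing and centroid distance as covariates and
  fish-within-group random intercepts.

What the generator does **not** emulate: hydrodynamics, 3D structure,
body-axis orientation distinct from movement direction, individual
personalities (no per-fish detection or speed biases beyond the drawn
base speed), learning within or across trials, and feeding competition
at the port. Passing tests on generated data therefore demonstrate that
the *pipeline* recovers a known mechanism, not that real fish obey this
mechanism. One known shortfall: in real data the relative importance of
polarization for first-response latency is near 1; the simulated
mechanism at realistic sizes yields a consistently positive but less
dominant averaged coefficient (RI ≈ 0.5–0.9 across seeds), because the
group-bearing covariate absorbs most of the visibility signal the
generator produces.

## Statistical layer

All predictors are standardized (mean 0, SD 1) before model fitting.
Candidate sets are **all subsets of main effects**
(`fitCandidateSet()`), fitted by maximum likelihood (`lme4`; gaussian
fits use ML, not REML, so likelihoods are comparable across fixed
structures), ranked by AICc (`aicc()`:
`−2ℓ + 2k + 2k(k+1)/(n−k−1)`). Akaike weights are computed on the
complete set; **relative importance** of a parameter is the summed
weight of the models containing it. **Full model averaging**
(`fullModelAverage()`) keeps the smallest weight-ordered prefix reaching
95% cumulative weight, renormalizes, and averages with **zero
substituted** where a parameter is absent — shrinking weakly supported
effects. The averaged SE is unconditional,
`√(Σ wₘ (seₘ² + (βₘ − β̄)²))`, including between-model variance; the
conditional (within-model) variant is available by argument. The choice
of unconditional intervals is the standard full-averaging practice; the
alternative is exposed because printed intervals in the literature
rarely say which was used.

**Cook's-distance filtering** removes observations above 6 × the mean
distance. For `lm`/`glm` fits the standard influence measures are used;
for mixed models the distances come from the fixed-effects hat values
and conditional residuals (the lm-formula analogue), which is the
appropriate screening tool at this scale without refitting n times.

**Repeatability** is the variance ratio
`R = σ²_id / (σ²_id + σ²_group + σ²_res)` from a model with individual
nested in group; the group component is included in the denominator by
default (toggleable — conventions differ and printed values rarely state
the denominator). The p-value is a boundary-corrected LRT of the
identity intercept (χ²₁, halved); the CI is a seeded parametric
bootstrap (default 1000 draws; binomial models use the latent-scale
residual π²/3). Recovery of generative ratios {0.1, 0.25, 0.4} at the
design size (96 individuals, 12 groups, 20 observations) is tested to
±0.08.

## Numerical choices and degenerate inputs

- Polarization of < 2 valid headings is undefined (`NA` + warning), and
  the window is dropped.
- `bearingToTarget()` errors when target and position coincide.
- Nearest-neighbour ties resolve to the lower fish index; arrival ties
  by distance-then-index — all deterministic.
- Ray casting uses 1e−9 positive-root guards; the eye point is pulled
  just inside the wall when a fish noses the boundary.
- The stadium inside-test is exact (distance to the spine segment); the
  ellipse uses a scaled-radial approximation adequate for wall logic.
- Zero group means make relative values undefined (`NA` + warning)
  rather than infinite.
- All simulations draw from R's RNG (including inside the C++ core), so
  `set.seed()` governs every result; the acceptance script takes its
  seed on the command line.

## Limitations

The package does not do video tracking, 3D reconstruction, retinal or
contrast modelling, refraction, leadership inference, or
feeding-outcome scoring (consumption is accepted only as an optional
annotation). Kenward–Roger/LRT significance machinery for mixed models
is delegated to the established tools behind the `fitModel()` contract;
the package's own contribution is the metric, visual-field, event and
model-averaging layer around them.
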