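---
title: "Localising howling canids by time-difference-of-arrival multilateration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localising howling canids by time-difference-of-arrival multilateration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(howloc)
```

## The problem

Passive acoustic monitoring of vocal carnivores — golden jackals, wolves,
coyotes — deploys autonomous recorders that capture spontaneous howling.
With GPS-time-synchronised recorders, the same howl arrives at different
recorders at slightly different times, and those time differences of
arrival (TDOAs) constrain where the animal was: each pairwise delay puts
the source on one branch of a hyperbola whose foci are the two
recorders. With three or more recorders the hyperbolae intersect and the
source can be estimated — *multilateration*. Localised howls turn a bare
"species detected" into positions, counts of simultaneously vocalising
groups, and distances usable in density estimation.

`howloc` implements that analysis chain: reading deployment and
salient-point annotation tables, TDOA computation, hyperbolic
least-squares positioning, classification against the local convex hull
of the contributing recorders, accuracy evaluation against known
(howl-survey) positions, detection-distance summaries, and a synthetic
survey generator so the whole chain is testable without field
recordings.

## The measurement model

A source at unknown planar position $s$ emits at unknown time $t_0$; the
arrival time at recorder $i$ at position $r_i$ is

$$t_i = t_0 + \lVert s - r_i \rVert / c + \varepsilon_i,$$

with $c$ the speed of sound and $\varepsilon_i$ the error of manually
marking the same *salient point* (a distinctive instant within the howl)
on each recorder's spectrogram — about 50 ms in practice for low
signal-to-noise howls, i.e. roughly 15–17 m of path length. Differencing
against the earliest-arriving recorder (the reference) eliminates $t_0$:
with $\Delta t_i$ the observed delay of recorder $i$, the estimate
minimises

$$\mathrm{SSE}(s) \;=\; \sum_{i \ne \mathrm{ref}}
  \left[ \frac{\lVert s - r_i \rVert - \lVert s - r_\mathrm{ref} \rVert}{c}
  - \Delta t_i \right]^2 .$$

The fit is reported with its RMS residual in seconds
(`sqrt(SSE / n_deltas)`); residuals far above the marking accuracy
indicate mismatched salient points or a bad geometry.

### Why grid-then-refine rather than a closed form

Closed-form TDOA solvers exist, but with exactly three recorders the
problem is exactly determined and two hyperbola branches can intersect
at *two* points, both with near-zero residual. The objective is
multimodal, so `multilaterate()` first evaluates a coarse grid (default
cell 50 m) over the recorder bounding box padded by `max_range` (default
4 km — comfortably past the farthest non-detections seen in field use of
this array design, ~3.7 km), then refines the best three mutually
distinct cells with Nelder–Mead (restarted once; simplexes can collapse
early). Ties within the residual tolerance are broken toward the
recorder centroid, and if a near-tie survives more than 100 m away the
result is flagged `ambiguous` rather than silently picked.

Degenerate inputs are refused or flagged rather than guessed at:
collinear recorder subsets (smallest singular value of the centred
coordinates below 1 m) are not identifiable and error out; howls seen on
fewer than `min_recorders` (default 3) recorders come back as
not-localisable rows; arrival spreads above `max_tdoa_window` (default
15 s, ~5 km of path difference) are rejected as mismatched annotations.

### Coordinates

All field data are WGS84 latitude/longitude; the solver works in a local
equirectangular frame: $y = \Delta\mathrm{lat} \times 111320$ m, $x =
\Delta\mathrm{lon} \times 111320\cos(\mathrm{lat_0})$ m, with scale
factors frozen at the array centroid. Study areas for this method are a
few kilometres across; over 10 km the planar error is under 0.1% (the
test suite checks this against a spherical haversine oracle), and the
111320 m/degree constant is fixed so distance checks reproduce
bit-for-bit. Ground distances likewise use this planar model with the
longitude scale taken at each pair's midpoint latitude; applied to the
16 published howl-survey coordinate pairs it reproduces every printed
distance within the ~1 m rounding limit of 5-decimal coordinates.
Altitude is ignored (floodplain study areas are flat at this scale), and
no ellipsoidal model is used — 5-decimal coordinates quantise at ~1.1 m,
which already dominates.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `speed_of_sound` | 343 | m/s | dry air at ~20 °C; `speed_of_sound_at(T)` gives 331.3 + 0.606 T. Field reports sometimes imply ~300 m/s when equating 50 ms to 15 m; since the working value is rarely stated, it is configurable, bounded to the plausible 300–360 band, and never guessed from data. |
| `grid_cell` | 50 | m | coarse enough to be fast, fine enough that every residual basin of realistic arrays contains a grid point. |
| `max_range` | 4000 | m | search padding beyond the array; covers the farthest observed non-detections (~3.7 km). |
| `max_tdoa_window` | 15 | s | ~5 km of path difference; larger spreads mean the annotation joined different howls. |
| `gap_s` (event grouping) | 60 | s | a howling event ends after one minute or more of silence. Gaps are measured start-to-start because howl end times are rarely annotated; with howls of a few seconds and a 60 s threshold the assignment matches the end-to-start reading. |
| `jitter_sd` (simulation) | 0.05 | s | the accuracy of manual salient-point marking. |
| `separation_m` (multi-source flag) | 500 | m | single-linkage cut; howls in one event further apart than this are called distinct howling locations. |

## The synthetic generator

`generate_array()` places recorders by sequential rejection sampling so
every nearest-neighbour spacing lands in [800, 1200] m — the spacing
band used in real deployments of this recorder type. `make_scenario()`
spreads howls over events with within-event gaps below 60 s and
between-event gaps above it, so the event-grouping rule is exercised.
`simulate_howls()` draws, for every source–recorder pair, a detection
from a distance-dependent curve, then gives detected pairs an arrival
time from the forward model plus independent Gaussian marking jitter.

The detection curve is $p(d) = p_\mathrm{max} / (1 + (d/d_{50})^k)$ with
defaults $p_\mathrm{max} = 0.95$, $d_{50} = 1200$ m, $k = 4$. This form
hits its anchors exactly ($p(0) = p_\mathrm{max}$, $p(d_{50}) =
p_\mathrm{max}/2$, monotone decreasing). No field-fitted detection
function is published for this design; the defaults were chosen once so
that detections out to ~2.5 km and non-detections from ~0.9 km both
occur with non-trivial probability — the qualitative overlap seen in the
field — and are a labelled stand-in, not an estimate. Consequences:
passing tests show the *pipeline* is correct under this model, not that
the model predicts real detectability, which also depends on weather,
vegetation and season that the generator deliberately omits (as does the
analysis it feeds). No waveform synthesis, propagation physics or
sound-speed heterogeneity is modelled.

Everything is reproducible: each generator takes an explicit integer
seed and identical seeds give byte-identical tables.

## What the tests establish

The suite (and `scripts/acceptance.R`) checks, at sizes chosen to keep a
full run under a minute: reproduction of the 16 published howl-survey
errors to ±2 m with mean 41 m; sub-metre end-to-end recovery of 8
noise-free in-hull sources on a 10-recorder array; solver objective at
or below an exhaustive 1 m grid search on 20 small jittered scenarios
(4 recorders, 250–400 m spacing — small enough that a 1 m exhaustive
grid is an affordable oracle); median error non-decreasing over marking
jitter of 0/10/50/100 ms with 25 common-random-number sources, and a few
tens of metres at 50 ms; the one-minute event rule at its boundary; and
hull classification agreeing with an independent ray-casting oracle on
1000 random cases.

## A worked example

```{r}
dep <- generate_array(10, seed = 20210831)
src <- sample_sources_in_hull(5, dep, seed = 20210832)
sim <- simulate_howls(make_scenario(dep, src, jitter_sd = 0.05,
                                    seed = 20210833))
res <- localise_howls(sim$salient, dep)
res[, c("howl_id", "event_id", "lat", "lon", "rms_residual_s",
        "n_recorders", "in_local_hull")]
evaluate_localisations(res, sim$truth)$summary
```

## Known limitations

- 2-D only; sources and recorders are assumed coplanar.
- Point estimates without error ellipses; the RMS residual and the hull
  flag are the only fit diagnostics. Outside the local hull, accuracy
  degrades in ways the residual does not fully capture.
- Detection status is an *input* (a howl counts as detected on a
  recorder only if a salient point could be marked); the package does
  not process audio or infer detectability.
- The evaluation convention is asymmetric by necessity: distances for
  ground-truthed howls are measured from the true position, distances
  for wild animals from the estimated one, which inflates the latter by
  the localisation error.
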