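# howloc

Acoustic localisation of howling canids from arrays of
GPS-time-synchronised autonomous recorders, by time-difference-of-arrival
(TDOA) multilateration.

Passive acoustic monitoring of vocal species such as the golden jackal
(*Canis aureus*) usually yields only presence. With synchronised
recorders, the same howl arrives at each recorder at a slightly
different time, and the delays pinpoint the animal: a source at position
$s$ emitting at time $t_0$ reaches recorder $i$ at
$t_i = t_0 + \lVert s - r_i\rVert/c$. Differencing against the
earliest-arriving recorder removes $t_0$, and the position is estimated
by minimising the hyperbolic least-squares objective

$$\mathrm{SSE}(s) = \sum_{i \ne \mathrm{ref}}
  \Big[ \tfrac{\lVert s - r_i\rVert - \lVert s - r_\mathrm{ref}\rVert}{c}
  - \Delta t_i \Big]^2$$

over a local planar frame — coarse grid search over the padded array
bounding box, then Nelder–Mead refinement of the best cells, because
three-recorder geometries can have two hyperbola-intersection solutions.

The package is aimed at ecologists running recorder arrays for jackals,
wolves and similar long-range vocalisers. It covers the full analysis
chain: deployment and salient-point tables (CSV or Raven-style selection
tables), grouping howls into events by the one-minute-silence rule, the
solver, classification of each estimate against the local convex hull of
the recorders that produced it, accuracy evaluation against known
howl-survey positions, detection-distance summaries, and a seeded
synthetic-survey generator (recorder placement, distance-dependent
detection, 50 ms marking jitter) for testing array designs end to end.

## Worked example

```r
library(howloc)

dep <- generate_array(10, spacing_min = 800, spacing_max = 1200, seed = 20210831)
src <- sample_sources_in_hull(5, dep, seed = 20210832)
sim <- simulate_howls(make_scenario(dep, src, jitter_sd = 0.05, seed = 20210833))

res <- localise_howls(sim$salient, dep)
evaluate_localisations(res, sim$truth)$summary
#> $mean
#> [1] 31
#> $min
#> [1] 3
#> $max
#> [1] 74
#> $n
#> [1] 3
```

Of the five simulated howls, three land on at least three recorders
under the default detection model and can be localised; at the ~50 ms
accuracy of manual salient-point marking they come out a mean of 31 m
(range 3–74 m) from their true positions — with ~1 km recorder spacing,
marking error of tens of milliseconds translates to position error of
tens of metres. The two howls detected on fewer recorders are reported
as not localisable rather than dropped. Each result
row also carries the RMS residual of the fit (seconds), the recorder
subset used, and whether the estimate fell inside that subset's convex
hull — estimates outside the local hull are typically less reliable.

The package ships the published accuracy table of 16 ground-truthed
human howls (`howl_survey_reference()`); recomputing the
estimate-to-truth distances with `geo_distance()` reproduces every
printed value within the ~1 m precision of 5-decimal coordinates
(mean 41 m, range 2–115 m).

The numbered scripts under `analysis/` run the complete workflow —
reference-table accuracy, synthetic survey simulation, localisation,
evaluation, and a Monte-Carlo recorder-spacing design curve — writing
tables under `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

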