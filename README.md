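# phototox

Quantitative phototoxicity assessment from label-free live-cell imaging.

Illumination in fluorescence microscopy damages living samples, and the
damage is usually sub-lethal: cells divide late, arrest in the cell cycle,
or quiet down, long before they die. **phototox** measures these effects
from brightfield time lapses of adherent, cell-cycle-synchronised
populations that received a controlled light dose, using the cell cycle as a
biological clock. It is aimed at imaging scientists who want numeric
phototoxicity thresholds — "how much light can this protocol deposit before
biology changes?" — rather than post-hoc visual judgement.

## What it computes

For a field of view with `N` cells and round-cell detections per frame, the
package derives:

* **Mitotic-timing distribution** — `C(t) = (round detections at t) / N`,
  and its peak `t_p : C(t_p) = max_t C(t)`. Photodamage shifts `t_p`
  rightwards (control populations peak near 50 min after synchronisation
  release); extreme doses flatten the peak entirely, reported as a no-peak
  result.
* **Cell-size dynamics** — each instance's area `S` becomes an equivalent
  diameter via `S = pi R^2`, `D = 2R`; detections above 18 um are mother
  cells (~20 um), the rest daughters (~15 um). Population curves and the
  fraction of cells completing the mother-to-daughter transition by 50 min
  quantify division delays and arrest.
* **Cellular activity** — `activity(t) = mean((eIm(t) - eIm(t-1))^2)` over
  pixels of normalised, bleach-corrected, CLAHE-enhanced, smoothed frames
  `eIm`, with its cumulative sum reported at 420 min (7 h).
* **Event outcomes** — tracked rounding events classify as divided or
  cell-cycle arrested (no two daughters by the end of the window), compared
  across conditions with two-sided two-sample Kolmogorov–Smirnov tests and
  bootstrap confidence intervals.
* **Light doses** — areal dose `J/cm^2 = n_repeats x power x time / area`
  for widefield exposures and per-pixel dwell regimes of scanning systems,
  with inverse calculations and percent-of-maximum reporting.

A synthetic time-lapse generator (`synthetic_scenario()`, `render_video()`)
emulates the whole acquisition — ~126 adherent cells per 512 x 512 field at
0.55 um/px, 4-min frames, synchronised rounding peaking near 50 min, mothers
dividing into two daughters, illumination gradient and drift, sensor noise —
with exact ground-truth masks, counts and event schedules, so the entire
pipeline is testable without microscope data.

## Worked example

```r
library(phototox)

# a control field and one exposed to a damaging dose (20-min delay + arrest)
control <- synthetic_scenario(n_cells = 200, field = c(800, 800), seed = 1)
exposed <- synthetic_scenario(n_cells = 200, field = c(800, 800),
                              extra_delay = 20, arrest_prob = 0.3, seed = 2)

peak_of <- function(sc) {
  curve <- rounding_curve(ground_truth_detections(sc), sc$n_cells)
  peak_time(curve)
}
peak_of(control)
#> [1] 52
peak_of(exposed)
#> [1] 68

ks <- ks_two_sided(sample_events(control)$t_round_start,
                   sample_events(exposed)$t_round_start)
ks
#> <ks_comparison> D = 0.7000, p = 0 (****), n = 200 vs 200

transition_fraction(sample_events(control), by_time = 50)
#> [1] 0.605
transition_fraction(sample_events(exposed), by_time = 50)
#> [1] 0.035
```

The control rounding wave peaks at 52 min (the 50-min target falls between
two 4-min frames); a 20-min photodamage delay moves the peak to 68 min, the
pooled rounding-onset distributions differ at four stars (the asymptotic
p value underflows to zero at this separation), and the fraction of cells
completing division by 50 min collapses from 0.605 to 0.035.

Doses for typical exposure protocols:

```r
areal_dose(illumination_regime("widefield", power_w = 84.9e-3,
                               duration_s = 0.1, area_cm2 = 0.014))
#> [1] 0.6064286    # reported as 0.6 J/cm^2

px <- pixel_area_from_dimension(0.42)   # 0.1764 um^2 = 1.764e-9 cm^2
areal_dose(illumination_regime("scanning", power_w = 0.3e-3,
                               duration_s = 3.528e-6,
                               area_cm2 = px$area_cm2))
#> [1] 0.6          # fast high-power scan
```

An end-to-end multi-condition run — simulate, preprocess, activity,
detections, rounding curves, comparisons, reproducibility manifest — is one
call:

```r
cfg <- pipeline_config(
  conditions = list(
    list(label = "control", dose_j_cm2 = 0),
    list(label = "uv-6", dose_j_cm2 = 6, extra_delay = 20, arrest_prob = 0.2)
  ),
  control = "control", n_fov = 2, seed = 42,
  defaults = list(n_cells = 60, field = c(384, 384), duration = 200)
)
res <- run_pipeline(cfg, out_dir = "results")
res$comparisons[, c("condition", "peak_shift_min", "p_value",
                    "significance_stars")]
```

A thin command-line front end over the same functions ships in
`inst/cli/phototox` (subcommands `simulate`, `activity`, `detect`,
`quantify`, `dose`, `viability`, `compare`, `run`).

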