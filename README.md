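# synaptrack

Quantitative live-cell imaging analysis of MTOC repositioning and
microtubule-motor cluster dynamics at the immunological synapse.

When a T cell engages antigen, its microtubule-organising centre
(MTOC) translocates to the cell–substrate contact, pulled by
synapse-anchored cytoplasmic dynein whose localisation is regulated by
the plus-end tracking protein CLIP-170. synaptrack re-implements, as a
tested and reusable R package, the measurement pipeline behind that
kind of study. It is aimed at cell biologists and imaging analysts
working with TIRF/HILO movies of punctate, moving fluorescent
structures who want the individual measurement steps as composable,
tibble-returning functions.

## What it computes

- **Channel registration** — a similarity transform (scale `s`,
  rotation `θ`, shift `t`) between two camera channels, fitted by
  least squares from sub-pixel intersections of a 10 µm square
  calibration lattice and applied with bicubic interpolation
  (`detect_lattice_nodes()`, `fit_channel_transform()`,
  `apply_channel_transform()`).
- **Kymograph comet analysis** — kymographs along traced microtubule
  paths at 80 nm/pixel × 1 s/row; comet velocity as the slope of the
  straight kymograph lines, *v* = Δx·pitch/Δt; comet length by the
  rapid-rise-to-baseline rule (`build_kymograph()`, `detect_traces()`,
  `trace_velocity()`, `comet_length()`).
- **MTOC positioning** — the refraction-corrected axial distance
  *z* = *z*₀ · n_specimen / n_glass (1.37/1.52 defaults), and the
  centring fraction: the proportion of cells whose MTOC lies inside
  the concentric half-diameter ellipse of the fitted cell outline,
  with Wilson 95% CI (`correct_axial_distance()`,
  `fit_cell_geometry()`, `classify_region()`, `centring_fraction()`).
- **Cluster dynamics** — detection of protein clusters by the two
  selection criteria (FWHM diameter > 240 nm, i.e. 3 pixels, and
  contrast above 1 sd of the surrounding annulus),
  nearest-neighbour tracking, and classification of each track as
  plus-end-directed, minus-end-directed, or immobile
  (`detect_clusters()`, `link_tracks()`, `classify_motion()`).
- **Colocalisation statistics** — dual-channel track pairs that stay
  within 2 px in the same movement category for ≥ 3 consecutive
  frames, tabulated as region × motion × status fractions that total
  100% over both regions, plus velocity/lifetime summaries with the
  exact 1/60 µm/min↔µm/s conversion (`match_tracks()`,
  `build_fraction_table()`, `velocity_summary()`).
- **Comparative C_T** — relative expression 2^(−ΔΔC_T) with triplicate
  averaging and reference-gene normalisation
  (`relative_expression()`).
- **Synthetic data with ground truth** — comet movies, dual-channel
  cluster movies with programmable colocalisation, MTOC through-focus
  stacks, calibration lattice pairs and qPCR tables, all
  seed-deterministic (`sim_comet_movie()`, `sim_cluster_movie()`,
  `sim_mtoc_stack()`, `sim_lattice_pair()`, `sim_qpcr_table()`).
- **Orchestration** — `run_pipeline(run_config(...))` executes
  registration → detection → tracking → classification →
  colocalisation (plus kymograph, MTOC and qPCR stages) on a file
  manifest and writes CSV/JSON outputs reproducibly.

See `vignettes/methods.Rmd` for the models, parameter defaults and
their rationale, and the limits of what the synthetic validation
shows.

## A worked example

Simulate one synthetic cell with 100 cluster sets whose
plus-end-directed population moves at 16.8 µm/min (= 0.28 µm/s, the
reported microtubule growth rate) and whose minus-end population moves
at 0.054 µm/s (the weakly processive dynein rate), then run the full
chain on channel A:

```r
library(synaptrack)

spec <- acquisition_spec(frame_shape = c(384, 384), n_frames = 50)
geom <- cell_geometry(c(192.5, 192.5), c(170, 150))
sim  <- sim_cluster_movie(100, spec, geom, snr = 8, seed = 7,
                          coloc_fraction = 0,
                          speeds_um_per_s = c(plus = 16.8 / 60,
                                              minus = 0.054,
                                              immobile = 0))
tracks  <- detect_clusters_movie(sim$movie_a) |> link_tracks()
classes <- classify_motion(tracks, geom)
classes |>
  dplyr::group_by(motion_class) |>
  dplyr::summarise(n = dplyr::n(), mean_speed_um_per_s = mean(speed_um_per_s))
#> # A tibble: 3 × 3
#>   motion_class     n mean_speed_um_per_s
#>   <chr>        <int>               <dbl>
#> 1 immobile        19             0.00168
#> 2 minus           11             0.0529
#> 3 plus            22             0.271
```

The programmed speeds come back within a few percent: plus-end tracks
at 0.27 vs 0.28 µm/s programmed, minus-end at 0.053 vs 0.054 µm/s;
immobile clusters sit at the localisation-noise floor. The axial
correction is a one-liner —

```r
correct_axial_distance(1.0)   # 1 um mechanical stage shift
#> [1] 0.9013158                # true distance in um (x 1.37/1.52)
```

— and a noisy triplicate C_T table with a programmed 4-fold induction
recovers it:

```r
tab <- sim_qpcr_table(3, c(stimulated = 4), ct_noise_sd = 0.1, seed = 2)
relative_expression(tab, "calibrator") |>
  dplyr::group_by(condition) |>
  dplyr::summarise(mean_fold = mean(fold_change))
#> # A tibble: 2 × 2
#>   condition  mean_fold
#>   <chr>          <dbl>
#> 1 calibrator      1.00
#> 2 stimulated      4.08
```

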