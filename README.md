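# oocytemt

Track analytics and transport simulation for microtubule-dependent mRNA
localisation in the *Drosophila* oocyte.

## The problem

At stage 9 of oogenesis, kinesin 1 carries *oskar* mRNA along a weakly
polarised microtubule network to the posterior cortex of the oocyte, where
the mRNA is anchored and defines the future abdomen and germline.
Microtubules nucleate only on the anterior/lateral cortex, giving growing
plus ends a ~60/40 posterior orientation bias, and dynactin — itself a
kinesin-1 cargo — acts as an anti-catastrophe factor at the posterior,
extending plus-end growth all the way to the posterior pole.  Quantifying
this system means measuring particle-track statistics (speeds, directions,
posterior bias, comet lifespans, mobile fractions), measuring how long
growing plus ends dwell at the cortex, and simulating how microtubule
length and plus-end protection shape cargo delivery.

`oocytemt` packages that whole workflow for R:

* **Geometry** — the oocyte cross-section as a labelled polygon with a
  posterior pole and AP axis; all distance/region queries.
* **Synthetic tracks** — a generator for EB1-comet and oskar-mRNP track
  tables with the statistical structure the analyses assume, so the whole
  pipeline runs and is testable with no imaging data.
* **Track analytics** — per-track speed (mean of step velocities), net
  direction relative to the posterior (with 10° circular histograms),
  posterior bias per distance band with binomial SEs, 5 µm distance-binned
  frequencies, comet lifespans, region-stratified speeds, mobile fraction,
  a pinned-mean Gaussian-mixture subpopulation test with bootstrap LRT,
  and the normality-screened Student/Welch/rank-sum comparison rule.
* **Cortical dwell times** — selection of cortex-contacting tracks (1 µm
  contact rule, ≥ 20° approach angle), dwell = contact to disappearance,
  maximum-likelihood location-scale t fits, posterior-vs-lateral
  comparison, and kymograph rendering for QC.
* **Transport simulators** — (a) a static-rod model where microtubule
  lengths are exponential with mean ε·L_AP and diffusing cargo walks rods
  plus-end-ward, scored by a posterior "crescent score"; (b) a dynamic
  microtubule model with catastrophe hazard k_cat0/(1 + α·c(x)), where
  the dynactin field c(x) is built by kinesin-driven walker agents — the
  positive feedback loop that concentrates protection posteriorly.

## A worked example

```r
library(oocytemt)

geom <- ellipse_geometry()          # 50 x 40 um cross-section
print(geom$L_AP)
#> [1] 50

# synthetic oskar mRNP tracks under the default study conditions
tracks <- generate_oskar_tracks(oskar_params(n_particles = 2000), geom,
                                seed = 1)
st <- track_stats(tracks, geom, min_frames = 2L)

mobile_fraction(st, min_net_displacement = 0.05)
#> $percent
#> [1] 12.05
#> $se
#> [1] 0.7279414
#> $n
#> [1] 2000

# direction statistics are per moving track: measure them on an
# all-mobile set for per-band power
dir_tracks <- generate_oskar_tracks(
  oskar_params(n_particles = 2000, mobile_fraction = 1), geom, seed = 2)
posterior_fraction(track_stats(dir_tracks, geom, min_frames = 2L),
                   band = c(0, 10))
#> $percent
#> [1] 70.65217
#> $se
#> [1] 3.356926
#> $n
#> [1] 184
```

The mobile fraction (12.05 ± 0.73 %) recovers the generator's 12 %
setting, and among moving particles starting within 10 µm of the pole,
70.7 ± 3.4 % head toward the posterior, recovering the 71 % directional
bias the generator embeds in that band.

Cortical dwell times, from comets simulated with catastrophe switched off
so that many reach the cortex:

```r
eb1 <- generate_eb1_tracks(
  eb1_params(n_comets = 2000, hazard_far = 0, hazard_near = 0,
             max_frames = 500), geom, seed = 2)
events <- select_cortex_tracks(eb1, geom)
cmp <- compare_regions(events[events$cortex_region == "posterior", ],
                       events[events$cortex_region == "lateral", ])
print(cmp)
#> Cortical dwell-time comparison
#>   posterior: n = 122, mean = 13.45 s, max = 56.10 s
#>   lateral  : n = 1320, mean = 7.32 s, max = 59.50 s
#>   Wilcoxon rank-sum p = 1.34e-07
```

Plus ends dwell roughly twice as long at the posterior cortex (the
generator's 15 s vs 8 s conditions), and the rank-sum test resolves the
difference decisively.

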