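---
title: "Models and methods behind oocytemt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oocytemt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oocytemt)
```

# The biological problem

At stage 9 of *Drosophila* oogenesis, *oskar* mRNA must be delivered to the
posterior cortex of the oocyte, where it defines the site of abdomen and
germline formation.  The microtubule network that guides this kinesin-1
transport grows from non-centrosomal organising centres (ncMTOCs) on the
anterior/lateral cortex — never the posterior — producing a weak (~60/40)
posterior orientation bias of growing plus ends.  Because oocyte
microtubules are highly dynamic, delivery also depends on how long growing
plus ends survive, and in particular on how long they persist once they
touch the posterior cortex.  Dynactin, itself transported posteriorly by
kinesin 1, protects growing plus ends from catastrophe, creating a
positive feedback loop that extends microtubules all the way to the
posterior pole.

`oocytemt` implements the quantitative pipeline around this biology:

1. a 2D **geometry** model of the oocyte cross-section,
2. a **synthetic track generator** for EB1 comets and *oskar* mRNPs,
3. **track analytics** (speeds, directions, posterior bias, distance
   frequencies, lifespans, mobile fraction, subpopulation tests),
4. the **cortical dwell-time** procedure with location-scale t fitting,
5. two stochastic **transport simulators** (static rods; dynamic
   microtubules with the dynactin feedback loop),
6. CSV/JSON **I/O** and an end-to-end pipeline.

All analysis is 2D, in the imaging plane: every quantity the pipeline
computes is defined on single-plane time-lapse movies.  Coordinates are in
micrometres, time in seconds, frames 0-based, and all distance bins are
half-open and lower-inclusive.

# Geometry

An `oocyte_geometry` is a simple closed polygon (the hand-drawn cortex
outline of real data; an ellipse by default), a posterior pole lying on
the cortex, a unit anterior-to-posterior (AP) axis, and a per-vertex
region label (`anterior`, `lateral`, `posterior`).  Edges inherit the
label of their first vertex.  `ellipse_geometry()` provides the standard
50 x 40 um cross-section with the posterior arc defined as the cortex
within 15 degrees of the pole as seen from the centroid — real outlines
are hand-drawn, so the geometry is always an input, and the 15-degree
default is a configurable convention, not a measurement.

Distances to the pole are Euclidean; distances to the cortex are minima
over polygon edges.  `distance_band()` implements the half-open 5 um
binning used for distance-frequency summaries.

# Synthetic tracks

The generator exists so that every downstream stage can be exercised, and
its estimators validated by parameter recovery, without any real movie.
Its defaults are the study conditions of the measured data:

* **EB1 comets** are sampled at 1.7 s per frame.  Each comet nucleates on
  the anterior/lateral cortex (uniform by arc length), takes a fixed
  heading into the interior plus 2 degrees/frame of angular noise, and
  advances at a position-dependent growth speed: 0.23 um/s far from the
  pole, 0.18 um/s within 15 um of it, joined by a logistic ramp of width
  2 um (the data give only the two regional summaries, so the ramp shape
  is a smoothness choice).  Catastrophe is a position-dependent hazard
  (default 1/11.3 s^-1, the measured mean comet persistence) and
  out-of-plane censoring an age-proportional hazard, matching the stated
  direction of the imaging bias; its magnitude is free.
* **Cortical contact**: a comet that comes within 1 um of the cortex
  *after first having grown at least 1 um away from it* pauses there and
  disappears with a region-dependent hazard (defaults 1/15 s^-1 posterior,
  1/8 s^-1 lateral, the measured mean dwell times).  The "entry from
  outside" qualifier matters: comets nucleate *on* the cortex, so a naive
  "first frame within 1 um" rule would date every comet's contact to its
  nucleation.  For tracks that start in the interior the rule reduces to
  the plain first-frame-within-1-um definition.
* **oskar mRNPs**: a fraction (default 12%) of particles is mobile; a
  mobile particle performs one straight run with per-step speeds drawn
  from a truncated normal (default mean 0.36 um/s, SD 0.10 um/s), in a
  direction that points into the posterior half-plane with a probability
  depending on the starting distance band (defaults 0.71 / 0.66 / 0.63
  for 0-10 / 10-20 / 20-30 um).  Run lengths are exponential (mean 3 um);
  runs stop at the cortex *before* taking a step that would leave the
  cell, so per-step speeds remain unbiased.  The mRNP frame interval,
  run/pause kinetics and localisation error are not constrained by the
  source data and are free parameters (defaults: 1 s frames, no
  localisation noise).

What the generator deliberately does **not** emulate: photophysics,
detection noise, tracking errors, 3D excursions, or correlated motion of
neighbouring particles.  Passing parameter-recovery tests therefore shows
the estimators are correct and unbiased under the stated statistical
structure — not that they are robust to detection artefacts in real
movies.

# Track analytics

* **Speed** is the mean of instantaneous step velocities (displacement per
  frame interval), matching the per-comet definition used by plus-end
  trackers.
* **Net direction** uses the single first-to-last displacement per track,
  measured against the direction from the track's first point to the
  posterior pole (0 degrees = straight at the pole); a per-step variant
  was considered and rejected because the circular histograms being
  reproduced assign one angle per track.  "Posterior-directed" means
  |angle| < 90 degrees — the half-plane rule; the source analyses never
  state their cutoff, and the half-plane is the only symmetric choice.
* A track's **distance band** is taken at its first point.
* **Mobile fraction** uses a net-displacement threshold, default 1 um
  (the underlying tracking literature does not restate its criterion;
  the threshold is configurable).
* Minimum track length for summary statistics is 3 frames, the
  conventional comet-tracker minimum.
* **Lifespans** are right-censored by track end and no censoring
  correction is applied, because the measured quantity ("apparent
  lifespan") is itself uncorrected.
* The **subpopulation test** asks whether mRNP speeds contain a component
  moving at the plus-end growth speed: a two-component Gaussian mixture
  with one mean pinned to the EB1 mean is fitted by EM against a single
  Gaussian, and the likelihood-ratio statistic is calibrated by
  parametric bootstrap under the single-Gaussian null (the pinned weight
  sits on the boundary of the parameter space, so the chi-square
  approximation would be wrong).
* **Group comparisons** follow the test-selection rule of the source
  analyses: Shapiro-Wilk normality screen at alpha = 0.05 on both groups
  (subsampled to 5000 for large samples), then an F-test variance screen
  choosing the Student or Welch t-test; non-normal data fall back to the
  Wilcoxon rank-sum test.  All three tests are always reported.

# Cortical dwell times

`select_cortex_tracks()` implements the dwell procedure: a track
qualifies if it comes within 1 um of the cortex (first entry from
outside, as above) and approaches at >= 20 degrees to the local cortex
tangent.  The approach heading is averaged over the last k = 3 pre-contact
steps — the angle's averaging window is not defined by the source
procedure, so it is a documented, configurable choice.  Contact time is
the first sampled frame inside the band (no sub-frame interpolation,
matching a frame-based tracker); dwell is contact-to-disappearance; only
the first contact of a track is used (multiple-contact handling is not
specified upstream; re-contacts are rare and logged).  Events are pooled
across oocytes before fitting, with per-oocyte means also available.

The pooled dwell samples are summarised by a maximum-likelihood
location-scale t fit, with the degrees of freedom bounded to [0.5, 100]
to keep the optimiser away from the normal-limit ridge; fits at the bound
are flagged rather than hidden (an upper-bound fit simply means the
sample is effectively normal).  Raw means and medians are always reported
beside the fit.

Kymograph rendering is provided for visual QC only; the dwell statistics
come from the track-based procedure, not from kymograph line lengths.

# The static-rod transport model

Microtubules are fixed rods: anchors uniform on the anterior + lateral
cortex, directions uniform over the inward half-plane, lengths
exponential with mean epsilon x L_AP, truncated at the cortex.  The mean
target length epsilon is interpreted as the *pre-truncation* exponential
mean (whether the published value is pre- or post-truncation is not
stated; pre-truncation keeps the parameter independent of the geometry).
Cargo alternates diffusion (default D = 0.05 um^2/s, a typical large-mRNP
scale; the reference hydrodynamic model's exact constants are not
restated in our sources) and plus-end-directed walking at 0.47 um/s (the
measured mRNP transport speed), detaching stochastically (0.05 s^-1) or
at the plus end; cargo delivered to a plus end within 1 um of the
posterior cortex anchors irreversibly.  Binding uses a 0.5 um capture
radius, nearest rod first and lowest index on ties; the time step must
keep one walking step inside the capture radius (checked at
construction).  An optional prescribed two-vortex circulation stands in
for cytoplasmic flows (default off); reproducing the full 3D
hydrodynamics is out of scope.

For the transport simulations the geometry uses the broad posterior
exclusion domain (`ellipse_geometry(posterior_halfangle = 45)`), which
reproduces the observed ~60/40 posterior orientation bias of the plus
ends.  Because the posterior anchor is absorbing, the model eventually
delivers nearly all cargo at any epsilon; the crescent-vs-cloud
comparison is therefore read at a 10-minute simulated window
(80 rods, 400 cargo), where the contrast between epsilon = 0.5 and 0.35
is strong and stable across seeds.

The **crescent score** quantifies the crescent-vs-cloud contrast: mean
cargo density within a 2 um shell of the posterior cortex arc divided by
mean density in the posterior third of the cytoplasm outside the shell.
Uniform cargo scores 1; a tight cortical crescent scores far above 1; a
diffuse posterior cloud stays near 1.  With epsilon = 0.5 most rods reach
the posterior and cargo is handed to the cortex (score >> 1); at
epsilon = 0.35 rods stop short, cargo accumulates in the posterior
cytoplasm, and the score collapses — the simulated analogue of the
mutant's posterior cloud.

# The dynamic feedback model

Microtubules nucleate on the anterior/lateral cortex (rate r_nuc per um
of arc), grow at v_g = 0.23 um/s, undergo catastrophe with hazard
k_cat0 / (1 + alpha c(x)) at the plus end, shrink at v_s = 0.4 um/s, and
pause at the cortex with hazard cortex_pause / (1 + alpha c(x)).  The
protection law 1/(1 + alpha c) was chosen for boundedness and for giving
a clean alpha = 0 control; no functional form is prescribed by the
biology.  Growth speed is optionally damped the same way
(v_g / (1 + alpha_v c)), which reproduces the measured posterior
slow-down of plus ends.

c(x) is the dynactin concentration on a 1 um grid with explicit-Euler
diffusion and exponential decay (stability checked at construction).
Dynactin is carried by walker agents that diffuse when free, bind the
nearest microtubule within 0.5 um, ride to the plus end at 0.47 um/s and
track the tip.  Spatial locality of the walkers is essential: because
plus-end-directed transport on the 60/40-biased network is a biased
random walk — and because near the pole every local microtubule points
back into the posterior corner — walkers ratchet posteriorly over
repeated bind-ride-release cycles.  Deposition into c(x) happens where
the ratchet ends: at walkers sitting on cortex-paused plus ends, from
which the field spreads into the nearby cytoplasm by diffusion.  The
diffusion/decay pair (0.25 um^2/s, 0.005 s^-1) gives the field a
~7 um cytoplasmic range, matching the observed scale of the posterior
dynactin accumulation (a band one to two tens of um from the posterior
cortex).  The couplings (alpha = 1, alpha_v = 0.3) and walker pool
(n = 100) are set so that the loop ignites reliably within the default
20-minute window on every seed; the run passes through the measured
regime (posterior/lateral dwell ratio about 2, near-posterior growth
slowed by roughly a fifth) partway through and then saturates deeper —
an unbounded positive feedback has no intrinsic ceiling, so
contrasts extracted from it are qualitative orderings, not calibrated
magnitudes.  Sensitivity sweeps vary the anti-catastrophe coupling alpha
with the growth damping alpha_v held at its default, isolating the
protection effect from the slow-down confound.  k_cat0 = 0.02 s^-1 sets
the baseline mean growth excursion (v_g/k_cat0 = 11.5 um) at the desk
scale of the 50 um cross-section.

Comet-equivalent tracks record *growing* plus ends only, sampled at
1.7 s, with a per-frame track-break probability (default 0.08) standing
in for detection turnover — real trackers lose and re-acquire comets, so
track starts sample the whole growth path rather than only nucleation
sites.  Cortex-paused (static) plus ends are deliberately not exported as
comet tracks; they are the vertical lines of cortical kymographs and are
reported through the simulator's dwell log.  `mutant_scenario()` runs
wild-type and feedback-free (alpha = alpha_v = 0) configurations on a
shared seed; the exported tracks feed the ordinary analytics, reproducing
the wild-type-vs-mutant contrasts in region speed, posterior comet
frequency and posterior persistence.

# Numerical and testing choices

* All randomness flows from explicit integer seeds; identical seeds give
  byte-identical track tables.
* Frame discretisation biases means of exponentially distributed
  durations downward by just under half a frame; tests compare against
  the discretised expectation (geometric law) or allow one frame interval
  of slack, and distributional checks use a randomised
  probability-integral transform against the geometric law rather than a
  naive KS test against the continuous exponential.
* Brute-force oracles (segment scans, step loops, tally loops, a
  re-implementation of the dwell pipeline) arbitrate the fast vectorised
  code at 1e-9 tolerance in the test suite.
* Simulation test sizes (hundreds of microtubules/cargo, runs of
  600-1800 simulated seconds, 6-20 seeds) were chosen as the smallest
  scales at which the qualitative contrasts are statistically stable;
  they are the package's reference problem sizes throughout tests,
  examples and the acceptance script.
* The location-scale t likelihood is optimised in (mu, log sigma,
  log nu) with L-BFGS-B; degenerate inputs (constant samples, < 10
  values) are rejected with informative errors.

# Known limitations

* 2D only; no automatic cortex segmentation; tracks and outlines are
  inputs.
* The dwell procedure measures apparent persistence: it inherits the
  out-of-plane censoring of the imaging and applies no survival
  correction, by design.
* Loaders for the published source-data spreadsheets are not bundled:
  their column layouts are not documented in our sources, and the
  package's analytics operate on the track CSV format instead.
* The static-rod model's diffusion constant, nucleation density and flow
  field are free parameters; conclusions drawn from it here are
  order-of-magnitude contrasts (crescent vs cloud), not calibrated
  predictions.
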