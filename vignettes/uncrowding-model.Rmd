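---
title: "A two-layer recurrent-segmentation account of crowding and uncrowding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-layer recurrent-segmentation account of crowding and uncrowding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uncrowdr)
```

## The problem

In peripheral vision, a vernier target (two nearly collinear vertical
lines with a small horizontal offset) becomes hard to judge when flanking
elements are placed beside it — crowding. When the flankers form coherent
objects (rectangles, cubes) and enough processing time is available, they
perceptually group away from the target and crowding is released —
uncrowding. `uncrowdr` implements a deliberately small rate-based model of
this spatiotemporal grouping process, together with the exact stimulus
geometry and the adaptive psychophysics used to measure vernier thresholds,
so that the model's qualitative predictions can be regenerated and probed
end to end.

The pipeline has three stages:

1. **Stimuli** (`make_vernier()`, `make_flankers()`, `build_sequence()`,
   `rasterize()`): line-drawing stimuli in arcmin coordinates, rasterized
   into four binary orientation channels (vertical, horizontal, two
   diagonals) on a 201 x 101 pixel canvas at 0.5 px/arcmin.
2. **Segmentation model** (`step_segmentation()` and friends): two
   segmentation layers of leaky per-pixel rate units, top-down selection
   signals that spread along connected contours and transfer the selected
   contours from Layer 0 (the readout layer) to Layer 1.
3. **Readout and behaviour** (`template_scores()`, `contrast_score()`,
   `model_evidence()`, plus the `psychophysics` functions): template
   contrast per 20-ms step, summed over a readout window, and an adaptive
   staircase (PEST) + cumulative-Gaussian fit that turns condition-level
   evidence into predicted thresholds via a monotone link.

## The model

### Contour fields

Each layer holds activity $a \in [0,1]$ per pixel per orientation channel.
Per 20-ms step every unit decays by $\exp(-\Delta t/\tau)$ with
$\tau = 180$ ms, and stimulus input drives Layer 0 to saturation at 1.
The decay constant is the package's single most consequential free choice:
it is set once so that a contour persists at $\ge 50\%$ through a 120-ms
blank (preview information survives a typical interstimulus interval) but
fades below 4% by 600 ms (long gaps destroy it). Everything the full
spiking model contributes here — a time scale and a fading rate — is
captured by $(\Delta t, \tau)$.

### Selection and segmentation

A trial plants one top-down selection signal per flanker side at a fixed,
configuration-specific anchor plus Gaussian jitter (SD 4 arcmin), the only
stochastic element of a model trial apart from the ScrambledCubes shuffle.
For large closed flankers the anchor sits at the outer-top corner of the
front face, far from the target; for the flanking Lines (and the
Central-Rectangle, whose vertical edges sit at the same positions) the only
structure available is 23 arcmin from the target, so a signal wide enough
to cover a flanking line (radius 50 arcmin) unavoidably also covers the
region where the vernier appears. That geometric fact *is* the model's
explanation of why Lines always crowd: segmenting target and flankers
together helps nothing.

The signal's disc is held for the whole trial (it is a top-down commitment
to a region, not a retinal trace). From it, a selection mask spreads along
contour-bearing pixels in breadth-first rings (8-connected, one-pixel gap
tolerance, i.e. Chebyshev radius 2 per ring). The per-step ring budget is

$$ v \cdot \bar a^{\,p}, $$

with speed $v = 6$ rings/step and exponent $p = 6.5$ over the mean activity
of the contour pixels just ahead of the front. Spreading is therefore fast
along driven contours and grinds to a near-halt along fading ones — the
mechanism that separates "160 ms of stimulus" (segmentation completes
inside the readout window) from "20-ms preview plus blank" (segmentation
only partially spreads). Where a supporting contour has decayed below the
activity threshold (0.3), the spread mask collapses quickly
($\tau_{sel} = 8$ ms); the seed discs persist.

Selected contours are transferred to Layer 1: per step, a fraction
`transfer_rate * mask` of Layer-0 activity moves to the same pixel of
Layer 1 (default rate 1: a selected contour shifts at once). Stimulus
drive arriving at an already-selected pixel is routed into Layer 1
directly — once a location belongs to the segmented object, new input
there belongs to its layer. This routing is what makes the transfer
operation exactly conservative: per pixel, Layer 0 + Layer 1 activity
changes only through decay and bottom-up drive, never through transfer
(the only exception is a Layer-1 unit already at saturation, which
absorbs input exactly as a saturated Layer-0 unit does).

### Readout

Two binary templates on the vertical channel are built from the vernier
rasterized at the reference offset ($\pm 4$ arcmin), dilated by 15 px
(30 arcmin) so they also cover nearby flanker contours, with the pixels
diagnostic for the opposite offset excluded. Per step the model computes

$$ C = \frac{S_R - S_L}{100 + S_R + S_L}, $$

where $S_L, S_R$ sum Layer-0 vertical activity under each template. The
additive constant 100 is a printed constant of the contrast rule, not a
tunable. Model evidence is the sum of $C$ over 20–100 ms after vernier
onset (endpoints inclusive; five steps at 20 ms). Two consequences follow
directly from the formula and drive every prediction:

* symmetric flanker activity inside the templates cancels in the numerator
  and inflates the denominator — crowding;
* scaling Layer-0 activity down scales $|C|$ down — a target that has
  faded before its flankers are segmented cannot be rescued (the postview
  conditions).

Templates read Layer 0 only. Reading the vernier-bearing layer instead
gives the same qualitative outcomes (co-selected flankers interfere in
Layer 1 exactly as they would in Layer 0); the single-layer readout is the
simpler convention and is fixed throughout.

## Experiments and the pattern suite

`experiment_conditions()` enumerates the four designs: flanker type x
duration (7 conditions), preview/postview (6), preview with variable ISI
(8), and an intermediate frame between a Cubes preview and the flanked
target (7). `run_pattern_suite()` runs 100 Monte-Carlo trials per
condition and scores the qualitative predictions as z-statistics on
condition means (pooled SE); "greater" requires $z \ge 3$, "approximately
equal" $|z| < 2$. The z conventions are package conventions for turning
qualitative orderings into machine-checkable assertions, not empirical
claims about effect sizes.

```{r patterns, eval = FALSE}
suite <- run_pattern_suite(1:4, n_trials = 100, seed = 1)
suite$report
```

The suite reproduces: uncrowding with duration for Cubes/Rectangles but
not Lines; the configuration-specific preview effect and the absence of
any postview effect; preview benefits at 20- and 120-ms ISIs that vanish
from 260 ms on (the model's stated failure — human observers keep the
benefit up to a second); and the intermediate-frame pattern, where
Cubes/Rectangles/Triangles sustain the grouping process but Lines and
ScrambledCubes interrupt it. The Central-Rectangle is predicted at or
below the intermediate-Lines level — the model's second documented
failure, since observers show a modest benefit there.

## Calibration

The spreading speed $v$, exponent $p$, seed radius $R$, jitter $\sigma$,
transfer rate and selection decay form the calibration vector.
`calibrate_model()` runs a coarse grid search scoring candidates against
the pattern suite at reduced trial counts; the shipped defaults are the
grid point that passes the full suite. The decisive trade-offs:

* $R = 50$ arcmin: large enough that a Lines-condition signal covers a
  full flanking line *and* the target zone; small enough that Cubes
  signals exclude the target.
* $v = 6$, $p = 6.5$: fast enough that a continuously driven cube is
  segmented within the readout window; slow enough that during a
  preview-plus-blank the front has not yet reached the inner flanker
  edges when an intermediate frame appears.
* $\sigma = 4$ arcmin: placement noise produces trial-to-trial variance
  (and the occasional mis-segmented trial) without ever letting a
  Lines-condition signal miss the target zone.

## The psychophysics stage

The staircase is classical PEST: a Wald sequential test at target
probability 0.75 (deviation limit 1 trial) decides level changes; steps
halve on reversals, repeat once in the same direction, then double (with
the post-reversal doubling exception); offsets start at 800 arcsec and are
hard-capped at 1,600 arcsec, twice the start. Directions are randomized
with runs capped at four. Blocks hold 80 trials; every condition is
measured twice (160 trials). Thresholds come from a post-hoc binomial
maximum-likelihood fit of a cumulative Gaussian in log offset with guess
rate 0.5 and a fixed 0.02 lapse; the threshold is the 75%-correct point.
Degenerate data (chance-level responding, all-correct tables, fitted
thresholds beyond the cap) are flagged non-converged and censored at the
cap. PEST's own step parameters (initial step 400 arcsec, minimum step
5 arcsec) are documented defaults, exposed in `pest_init()`.

The simulated observer answers correctly with probability
$0.5 + (0.5 - \lambda/2)\,\Phi((\log d - \mu)/\sigma_{\log})$, and
`evidence_to_threshold()` links condition evidence to behaviour through
$\mu(E) = \alpha - \beta E$ with $\beta > 0$ — the package's way of making
"higher evidence means lower threshold" concrete. $\alpha = \log 800$
pins a zero-evidence condition near the staircase start; $\beta = 4$
spreads the observed evidence range (about 0 to 0.55) over roughly one
log-unit of threshold, comparable to the spread between unflanked and
strongly crowded performance. The link is a convenience for producing
threshold-scale figures; all pattern-level claims are made on evidence.

## What the synthetic data do and do not capture

The generator reproduces the stimulus geometry exactly (all dimensions in
arcmin, offsets in arcsec), the frame timings on a 20-ms grid, and
binomial observers whose accuracy rises monotonically with offset. It does
not emulate luminance, anti-aliasing, display timing jitter, eccentricity
scaling (the 9 degrees eccentricity is carried as metadata only), lapses of
attention beyond a constant rate, or learning across blocks. Passing tests
therefore demonstrate internal consistency of the model and procedure, not
agreement with any individual human data set; behavioural threshold
magnitudes are produced only through the explicit evidence-threshold link.

## Numerical choices and degenerate inputs

* Rasterization uses a deterministic integer midpoint rule (half-open
  spans sampled at pixel centres, stroke width 1 px), so an axis-aligned
  segment of length $L$ occupies exactly $L \cdot$ ppa pixels and rasters
  are bit-reproducible. The default canvas is 201 x 101 px so that x = 0
  lies on the centre pixel column and mirror-image stimuli rasterize to
  mirror-image rasters away from cell boundaries.
* Segments that would leave the canvas raise an error naming the segment;
  unknown configurations, invalid experiment/condition pairings and
  out-of-range offsets (beyond 1,600 arcsec) are rejected at the door.
* A ScrambledCubes frame requires an explicit seed: the shuffle is part of
  the stimulus definition, and irreproducible stimuli are treated as an
  error rather than a warning. Shuffled segments keep their length and
  orientation, stay inside the per-side cube bounding box, and are redrawn
  if they would intrude into the central 30-arcmin target zone.
* A selection signal that overlaps no contour selects nothing (and Layer 1
  then stays exactly zero all trial) — this is a modelled outcome, not an
  error.
* Fractional ring budgets carry over between steps, so slow spreading
  accumulates rather than stalling at floor-zero.
* In `fit_psychometric()`, $\sigma$ is optimized on the log scale to keep
  it positive; fits are flagged non-converged rather than extrapolated
  when the data cannot identify a threshold below the staircase cap.

## Known limitations

* The model's preview benefit dies with the contour trace (no benefit
  from 260 ms ISI onward), while human uncrowding survives to about 1 s;
  and the Central-Rectangle intermediate is predicted at or below the
  Lines level, while observers show a modest benefit. Both mismatches are
  properties of the mechanism, reproduced deliberately.
* One selection signal per side is a simplification; the underlying
  account allows several, and the signal count interacts with the seed
  radius.
* Problem sizes are chosen for a desk-scale run: 100 trials per condition
  for the pattern suite, 200 replicates for threshold recovery, 201 x 101
  px rasters. All are parameters, not constants.
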