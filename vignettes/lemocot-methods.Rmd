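---
title: "Automated scoring of the lower-extremity motor coordination test: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated scoring of the lower-extremity motor coordination test: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lemocot)
```

## The measurement problem

The lower-extremity motor coordination test (LEMOCOT) asks a seated
participant to tap two floor targets 30 cm apart with the big toe,
alternating between them as fast and as accurately as possible for
20 s. The traditional score is a single number — how many taps landed
inside a target — counted live by a clinician. That score conflates
speed with accuracy, discards every miss, and depends on a human
counter under load.

Performing the test on a pressure-sensitive mat (the reference device
is a grid of 0.80 × 0.80 cm force sensors sampled at 60 Hz) turns each
tap into a short force movie. From that movie this package recovers the
traditional score automatically and extracts refined motor-performance
parameters per touch:

* **contact surface** — area of the contact at the time of touch;
* **endpoint** — where the big toe landed, the controlled point of the
  reach;
* **centre of pressure (COP)** — the force-weighted mean contact
  location;
* **endpoint–COP distance** — congruent in a controlled toe placement,
  separated when the whole foot slaps down;
* **absolute error** — Euclidean distance of endpoint (or COP) from
  the target centre, per touch:
  $\sqrt{(X_i - X_{target})^2 + (Y_i - Y_{target})^2}$;
* **variable error** — distance from the mean position of all
  repetitions with the same leg and target:
  $\sqrt{(X_i - \bar X)^2 + (Y_i - \bar Y)^2}$.

## Coordinates, zones and classification

All positions are continuous millimetres with the origin at the
proximal target centre and +y pointing at the distal target (default
centre (0, 300)). Sensor indices are 0-based `(row, col)`; a cell's
coordinate is its centre; the `origin_cell`/`y_axis` header fields of
the file formats externalise how the physical mat was oriented, which
the test protocol itself does not fix.

The tested surface is divided into three zones by y alone: a 100 mm
band around each target centre and the *between* region. A touch whose
endpoint falls in a target band is classified **in** or **out** by a
closed disc of radius `target_radius` around that target's centre; a
touch in the middle band is a **between**-target touch (typically a
drag on the way to a target) and is counted but carries no error
parameters. Two boundary conventions are deliberate and documented:
zone bands and the target disc are closed (a point exactly on a
boundary favours the participant), and extreme x positions stay in
their y-zone but fail the disc test. The physical diameter of the
painted target is not standardised, so `target_radius` (default 25 mm)
is explicit configuration echoed into every output header.

## Touch detection

Detection is deliberately simple and fully deterministic:

1. **Activation.** A cell is active when its force reaches
   `force_threshold` (default 1 device unit). A frame is a contact
   frame when its summed above-threshold force reaches
   `min_total_force` (default 3).
2. **Episodes.** Maximal runs of at least `min_duration` (default 2)
   consecutive contact frames form contact episodes; a single silent
   frame separates episodes. The 2-frame minimum rejects single-frame
   noise bursts.
3. **Region.** Within each frame, the active region is the largest
   connected component (8-connectivity by default) of active cells;
   ties go to the component with more force, then the lower row index.
   Stray isolated cells are discarded and counted. Only one foot is
   assumed on the mat — the protocol is single-leg.
4. **Intended target.** Each episode yields exactly one touch. If the
   final-frame contact lies in a target zone, that target is the
   intended one; otherwise the alternation protocol decides (opposite
   of the previous scored touch; proximal to start). The zone decision
   uses the final-frame COP: the endpoint rule itself needs an intended
   target, so using it here would be circular, and inside a 100 mm zone
   the COP and the endpoint of any plausible foot agree on the zone.
5. **Time of touch.** The first frame of the episode at which the
   endpoint is closest to the intended target's centre; exact ties go
   to the earlier frame.
6. **Endpoint.** The original analysis locates the big toe "from the
   distribution of the force data" without publishing the exact rule,
   so this package defines its own: the force-weighted centroid of
   active cells within `toe_radius` (default 20 mm, a big toe being
   2–3 cells wide) of the *extremal* cell — the active cell nearest
   the intended target. For a compact toe-only contact this is simply
   the region's COP; for a whole-foot contact it isolates the toe from
   the heel. COP and surface are computed over the whole contact
   region, the endpoint over the toe neighbourhood only; if the
   alternative (toe-only COP/surface) is ever wanted it is a config
   switch away, since both come from the same region structure.

Surface is `cells × pitch²` (one 8 mm cell = 0.64 cm²). An open
question in the source analysis — whether surface/COP covered the whole
contact or only the toe — is resolved here as *whole contact*, matching
the phrase "the surface contacting the ground".

## Scoring and summaries

Counts satisfy `in + out + between = number of episodes` by
construction. Parameter means are taken over the in **and** out touches
(`params_scope = "in_out"`, switchable to `in_only`): between-touches
are drags, not aimed reaches. Variable error is computed within each
leg-and-target group and needs at least two scored touches; with fewer
it is `NA` — never an exception and never imputed, matching the
clinical reality of a participant who manages a single touch per
target. The per-leg summary averages the within-target variable errors
across all of the leg's scored touches; pooling the targets *before*
averaging would mix two different means and is intentionally not the
default.

## The statistical layer

All error parameters are modelled on the natural-log scale
(`log_transform()` refuses non-positive values loudly rather than
offsetting silently).

**Count validation.** `validate_counts()` fits
`manual ~ script + (1 | subject)` with lme4, because each participant
contributes two legs. It reports slope and intercept with 95% Wald
CIs, the conditional pseudo-R² in the Nakagawa form
$(\sigma^2_{fixed} + \sigma^2_{subject}) / (\sigma^2_{fixed} +
\sigma^2_{subject} + \sigma^2_{resid})$ computed directly from the
variance components, the median manual−script difference with
empirical 2.5/97.5 percentile limits of agreement, and the slope of
the difference on the manual count (the tester-load bias trend). A
singular fit falls back to OLS with a warning — which is also exactly
what perfect agreement produces (no subject variance left), making the
slope-1/intercept-0/R²-1 fixed point exact.

**Speed–accuracy control.** Error rises with tap rate, so slower
patients would look spuriously accurate. The control group defines the
expected relation; the functional form is not stated by the source
analysis, so the simplest model consistent with a positive
relation is used: a least-squares line of `Ln(parameter)` on the raw
in-target count (a log–log variant would be a one-line change and is
noted, not implemented, as the default). Every row's residual —
observed minus predicted log parameter — becomes the speed-controlled
value. Control residuals are mean-zero by construction; an injected
group offset survives residualization undistorted.

**Group × leg models.** `fit_group_leg_model()` fits
`dv ~ group * leg + (1 | subject)` with lmerTest, `leg` recoded to the
two-level within-subject factor pairing paretic with dominant (both
tested first). Type-III F tests use Satterthwaite denominator degrees
of freedom, and the df method is recorded in the output rather than
promising to replicate any particular software's df arithmetic —
published touch-level df values cannot be reproduced from leg-level
aggregates anyway, so the model runs at whatever granularity the input
table provides and says so. Marginal means come from emmeans; all
pairwise cell comparisons are Holm-adjusted (Holm *is* sequential
Bonferroni, stated in the output metadata). A constant dv returns an
all-zero F table instead of crashing.

**Associations.** `spearman_assoc()` wraps the rank correlation with
the conventional effect bands (0.10 / 0.30 / 0.50) and flags constant
input as undefined.

## The simulator

The generator exists so every claim above is testable without clinical
recordings. It emulates — by construction, not by fitting — the
behaviours the analysis must detect:

* alternating touches at `touch_rate` for `trial_duration` (defaults
  1.5 /s and 20 s; healthy adults reach ≈1.8 /s, stroke ≈1.0 /s);
* each touch is an isotropic 2-D Gaussian force blob sampled at cell
  centres and truncated at the activation threshold; the default
  (peak 100, SD 3.5 mm) gives a contact ≈21 mm across — a big-toe pad
  of 2–3 cells;
* a 1-frame half-force approach ramp placed 12 mm radially *outward*
  from the target precedes an 8-frame dwell (150 ms total), so the
  time-of-touch rule must genuinely skip a frame;
* endpoint scatter (`endpoint_scatter_sd`) and aiming bias per target;
* a COP offset: a light ball-of-foot blob rendered at the anatomical
  distance (`ball_offset`, default 70 mm behind the toe, connected
  through a low-force flesh band) with its force scaled so the contact's
  lever balance puts the true COP near a draw from
  `N(cop_offset_mean, cop_offset_sd)` below the toe — keeping the toe,
  not the ball, the part of the contact nearest the target;
* optionally a heel blob connected through a low-force arch band (a
  whole-foot contact), between-target drags with probability
  `p_between` per reach, and i.i.d. truncated-Gaussian sensor noise
  kept sub-threshold by default (`noise_sd` 0.2 vs threshold 1).

The truth record stores the true endpoint, the force-weighted mean of
the rendered contact frame as the true COP, and zone/hit labels from
applying the layout to true endpoints. `simulate_cohort()` generates
subject-leg observation tables analytically (no frames) for
statistical studies: per-subject log-normal rate and error scales
shared across legs induce exactly the random-intercept structure the
models assume. The study profile's cell parameters were chosen once to
land the in/out/between count pattern in the clinically reported range
(paretic ≈13 in-target, controls ≈35) and are not tuned thereafter.

What the simulator does **not** emulate: foot rollover and sliding
within a contact, anatomical toe shapes, bilateral contacts, mat
calibration drift. Passing tests therefore demonstrate correctness of
the algorithmic pipeline under its stated assumptions, not robustness
to every artefact of real clinical recordings.

## Numerical choices and degenerate inputs

* Timestamps must be strictly increasing with spacing within 10% of
  the nominal frame period; worse jitter is treated as file corruption.
* Forces round-trip text formats exactly (shortest round-trip decimal
  representation); timestamps to 1e-6 s.
* Component ties: size, then total force, then lowest row index —
  fully deterministic.
* Zero total force in a region is a degenerate-input error, not NaN.
* Empty recordings score to zero counts and undefined (NA) means.
* Every stochastic routine takes an explicit seed; result artifacts
  record it.

## Problem sizes used in the shipped checks

The test-suite simulations run at the protocol's native 20 s / 60 Hz
scale where the property needs it (count exactness over 51 trials,
Rayleigh recovery of the variable error over 20 trials of ~60 touches)
and at 1000 replicates of 20 + 20-subject analytic cohorts for the
type-I calibration of the mixed-model F tests; rendered-frame power
checks use 10-subject cohorts and 10 s trials, sizes at which the
within-subject effect (doubled paretic scatter) is overwhelmingly
detectable. These sizes are the package's own choices balancing
statistical resolution against a test suite that stays pleasant to run.

## Known limitations

* The endpoint rule is this package's own definition (the published
  analysis did not specify one); with `toe_radius` close to the
  contact diameter it mildly shrinks far-from-target endpoints toward
  the target — visible as a variable-error recovery ratio of ≈0.95
  rather than 1.00 at scatter 15 mm.
* Between-target touches are single events; a slide crossing zones is
  never split into multiple touches.
* The vendor's proprietary binary export is not parsed; recordings
  must be exported/converted to the two documented text dialects.
* Exact replication of published clinical F/p values is out of scope —
  the underlying recordings are not public; the statistics layer is
  validated by simulation calibration instead.
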