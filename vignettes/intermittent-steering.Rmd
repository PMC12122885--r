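---
title: "Intermittent steering control: models, methods and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intermittent steering control: models, methods and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steerflow)
```

## The problem

Human lateral control of a vehicle is intermittent: rather than a continuous
feedback signal, drivers emit discrete ballistic steering corrections —
rapid aimed hand movements — when an accumulated perception of error crosses
a decision threshold. Two questions drive the package's design: *which
visual quantities act as the stimulus* (gaze-stabilized retinal optic flow
over the drivable lane, versus vehicle heading relative to the road), and
*how long after the stimulus a correction begins* (the response time).
Answering either requires decomposing a steering-rate recording into its
constituent corrections, reconstructing the visual quantities, and relating
the two with a lag scan. Because ground truth for any of this is
unobtainable in human data, the package ships a closed-loop synthetic
driving world in which every quantity is known exactly.

## The ballistic correction model

One correction has a symmetric Gaussian velocity profile with strength
$a_I$ (rad/s, signed), mode $\mu_I$ (s) and rate parameter $\sigma_I$ (s):
$\dot\delta_b(t) = a_I \exp(-(t-\mu_I)^2 / 2\sigma_I^2)$. Position is its
erf primitive, the net travel is $a_I \sigma_I \sqrt{2\pi}$, and onset and
offset are defined as $\mu_I \mp 2\sigma_I$, enclosing
`r round(100 * coverage_fraction(2), 1)` % of the theoretical movement.
Overlapping corrections superpose linearly. The steering-wheel rate
parameter lies empirically in $[0.0707, 0.1732]$ s, i.e. single corrections
last 0.28–0.69 s. Asymmetric (heavy-tailed) velocity profiles and
minimum-jerk polynomials are deliberately out of scope; the symmetric
Gaussian is the working approximation throughout.

## Decomposition by penalized particle swarm optimization

`decompose()` identifies the corrections in an observed rate signal $z$ by
minimizing, per analysis window $(t_0, t_1)$,
$$\frac{\max(N,1)^\alpha}{t_1-t_0}\int_{t_0}^{t_1}
\Big|z(t)-\sum_{i=1}^{N}\dot\delta_{b,i}(t)\Big|\,dt,$$
with the integral taken by trapezoid on the signal's own grid. Two details
deserve comment:

* **The $\max(N,1)$ guard.** Taken literally, an $N^\alpha$ prefactor gives
  every empty model fitness zero regardless of residual, making "no
  corrections" a global optimum. The guard scores the empty model by its
  raw residual while leaving the penalty untouched for $N \ge 1$.
* **Exhaustive model order.** The penalized fitness is *not* monotone in
  $N$ on dense trains: with a large unexplained residual, adding one
  correction of area $A$ pays only if $(N{+}1)(R-A) < NR$, so the fitness
  rises through intermediate orders before collapsing near the true one.
  An early-stopping order search strands below the true order; the default
  therefore evaluates every $N \in \{0..n_{max}\}$ and keeps the minimum
  (`order_patience` re-enables early stopping for quick exploratory fits).

The optimizer is a global-best PSO with reflecting bounds, standard
constriction-style coefficients (inertia 0.729, cognitive and social
1.49445), swarm 60 and 400 iterations by default, implemented in C++ with
its own `std::mt19937` stream (explicit integer-to-double conversion, so
identical seeds give bit-identical results on any platform — the C++
standard fixes the engine but not the distributions). Each order is
warm-started from the previous order's optimum plus one component placed at
the peak of its residual — a greedy matching-pursuit seed that converts the
order search into an incremental refinement — and each PSO optimum is
polished by a deterministic Nelder–Mead pass on the same fitness.
Search bounds: $\sigma$ within the empirical interval, $\mu$ within the
window extended by $2\sigma_{max}$ (boundary-straddling corrections stay
representable), $|a|$ within 4x the window's peak rate. Corrections with
travel below `prune_threshold` (default 0.005 rad) are dropped as numerical
ghosts.

**Windowing.** `segment_signal()` splits the record at quiet runs
($|z| <$ 0.05 rad/s for at least $4\sigma_{min}$), pads each window by
$2\sigma_{min}$ and bisects windows longer than `max_window` (default 4 s)
at their quietest interior sample. Windows are then fitted in time order
against the *residual* of everything already modelled, so a correction
straddling a split is fitted once rather than twice.

**Identifiability.** On isolated corrections (modes at least
$2\sigma_{max}$ apart) the decomposition recovers parameters to the
acceptance tolerances (5 % in $a$, 0.01 s in $\mu$ and $\sigma$) in
$\ge$ 90 % of seeded runs. In closed-loop trains this cannot extend to
onset times at $\pm 0.02$ s: the simulated driver's 0.3 s decision
refractory combined with movement durations up to 0.69 s means every
correction overlaps its neighbours, consecutive modes can be separated by
less than $2\sigma$, and in that regime $(a, \mu, \sigma)$ trade off along
a near-degenerate manifold at the noise floor — onset $= \mu - 2\sigma$
doubles any $\sigma$ error. The end-to-end test therefore asserts what is
physically attainable: correction *count* within 20 % and $\ge$ 80 % of
true modes matched within 0.1 s (one correction timescale). This is a
statement about the signal class, not about the optimizer.

## Retinal optic flow and its lane angle

Retinal optic flow is reconstructed as $v_r(p) = v(p) - v(p_g)$: the dense
image flow minus the flow at the gaze point, which emulates the retinal
image stabilization of a fixation/smooth pursuit with gain 1.0 — the flow
at the fovea is then the zero vector by construction. The gaze-point flow
is bilinearly interpolated (gaze coordinates are sub-pixel), and the
nearest raster pixel is zeroed exactly. The per-frame summary statistic is
the circular mean direction $\arg \sum \exp(i\theta)$ of the retinal-flow
directions over the drivable-lane pixels, equally weighted; zero-magnitude
vectors carry no direction and are excluded rather than assigned angle 0.
Image convention: origin top-left, first component rightward, second
downward, so "downward" flow is $+\pi/2$; the two-argument arctangent keeps
the full quadrant. The stereographic projection to the spherical retina is
omitted throughout. Degenerate circular means (resultant below
$10^{-9} n$, e.g. perfectly antipodal directions) raise an error at the
statistic level and mark the frame invalid at the series level.

Gaze samples are filtered before use: confidence at least 0.6, normalized
screen position strictly inside the central 60 % (outside the extreme 20 %
border perimeter), and no blink flag. A constant head/headset tilt shows up
as a constant bias in the flow angle; `detilt()` subtracts the circular
median of the straight-section samples (the circular median is the sample
angle minimizing summed absolute circular deviation — the natural cyclic
"median", computed exhaustively since n is desk-scale).

## Vehicle-relative road metrics

Heading deviation is the wrapped difference between road tangent and
vehicle heading, in $(-\pi, \pi]$; lateral displacement is lane-midline
minus vehicle position in the road-normal frame (left-positive); lateral
velocity is $\|v\|\sin\theta_h$ with the small-angle form reported
alongside. Trial failure means fully exiting the designated lane
($|y_l| >$ half lane width + vehicle half-width, default 0.75 m — the exit
criterion is not stated geometrically anywhere, so the footprint is a
configurable stand-in) or loss of control, operationalized as
$|v_y|/v_x > 1$. Regions of interest are the middle portions of each curve
bend, excluding 15 % of the arc at each end (entry/exit transients); both
numbers are configurable because the source defines the regions only
graphically.

## Response-time estimation

For each correction the response is its travel angle and the stimulus is
the cue signal linearly interpolated at $t_{on} - \tau$; pairs whose lagged
sample is unavailable are dropped. The zero-normalized cross-correlation of
the pairs (the Pearson coefficient) is scanned over $\tau \in [0, 2]$ s at
one sample period (1/90 s) by default, and the response time is the argmax
(ties to the smallest lag; undefined lags excluded). Spearman and Kendall
variants are provided; on monotone relations they share the Pearson argmax.
The onset definition defaults to $\mu - 2\sigma$ with $\mu - \sigma$ and
$\mu$ selectable, since where one places "movement onset" trades timing
consistency against tail sensitivity. Corrections may be pooled across
trials (lists of correction sets and cues); pooling is the default in the
pipeline. A pseudo-Huber linear regression
($\delta^2(\sqrt{1+(r/\delta)^2}-1)$, BFGS from the least-squares start)
summarizes the response-stimulus relation at the best lag robustly.

## The synthetic world

The generator's defaults are the stated experimental world: an S-track
whose two semicircular bends have 60 m diameter (curvature 1/30 m$^{-1}$),
a 3.5 m lane, a vehicle at 13 m/s sampled at 90 Hz, eye height 1.1 m,
correction rate parameters uniform in $[0.0707, 0.1732]$ s, gaze fixations
on the lane at 4–25 m headway with pursuit gain 1.0, and an injected
response latency (default 0.15 s) between perceived stimulus and movement
onset. At 13 m/s the bends demand 5.63 m/s² (0.57 g) of lateral
acceleration. Defaults produce on the order of 20 corrections per trial
inside the curve-bend ROIs, comparable to the ~26 per trial reported for
human drivers on this task.

The **vehicle** is a kinematic single-track model (wheelbase 2.5 m,
steering ratio 13): tire physics contributes nothing to latency or
decomposition validity and the reference vehicle model is unpublished.
Consequently $v_y \equiv 0$ in the synthetic states and the slip-based
failure mode never triggers synthetically — it is exercised by constructed
fixtures instead.

The **driver** perceives a weighted error of heading deviation, lateral
displacement and a flow-angle proxy (the mismatch between the path
curvature the road demands a look-ahead time up the lane — default 1 s,
consistent with the observed 0.4–2.5 s gaze time headway — and the yaw rate
being produced; this term is the time derivative of heading deviation and
supplies the anticipatory damping real drivers obtain from visual flow).
The error integrates in a leaky accumulator; on threshold crossing a
correction is scheduled with onset delayed by the injected latency, travel
proportional to the error at the trigger, and $\sigma$ drawn from the
empirical interval. Decisions respect a 0.3 s refractory period, while the
movements themselves freely overlap. Critically, the driver carries an
internal forward model: the perceived error discounts the travel still to
come from corrections already in flight (an efference copy) and
extrapolates the heading state across its own response latency. Without
this the loop delay (latency + movement duration) makes the closed loop
unstable at exactly the latencies of interest — a finding that mirrors why
biological controllers with long delays must rely on prediction. Failure
rates grow with the injected latency (all trials succeed at 0.10–0.15 s;
a substantial fraction fail at 0.45 s), which is the qualitatively correct
behaviour.

A **causality note**: a scheduled correction's theoretical Gaussian tail
extends before its own trigger; the simulator cannot emit it, so the
recorded rate equals the superposition of all ground-truth corrections
plus the injected noise only up to that tail mass
($a\exp(-((\tau_d+2\sigma)/\sigma)^2/2)$, at most ~1e-2 rad/s here).

The **renderer** computes ground-plane optic flow in closed form: each
below-horizon pixel is back-projected to the plane and the exact time
derivative of its pinhole projection under the vehicle's rigid motion
(translation + yaw) is evaluated — instantaneous flow in px/s, frame-rate
independent. The independent oracle in the tests is a central finite
difference of projected points at one tenth of a frame, which agrees to
~1e-3 px/s over lane pixels in the 4–25 m gaze-headway range; very
near-field pixels (flow of order 10³ px/s) are excluded from the bound
because any finite-difference secant departs from the instantaneous value
there by more than the tolerance — a property of the geometry, not of the
implementation. The lane mask is the exact projection of the designated
lane. The default raster is a quarter-linear-scale stand-in for an HMD eye
(360x400 px, ~98° horizontal field at focal length 160 px); the pipeline
uses a further-reduced raster and frame stride for desk-scale runtime.
Camera tilt (head/headset misalignment) is injected as a full image
rotation about the principal point: rasters are nearest-neighbour
resampled with vectors rotated, the gaze pixel rotates exactly, and the
accumulated tilt composes exactly.

**What the generator does not emulate** — and hence what a green test does
not establish: tire slip and force feedback, photorealistic texture (the
analytic flow is noise-free; a video-based estimator adds structured
errors), saccade kinematics and post-saccadic oscillation (saccades are
plain validity gaps), eye-model/calibration error beyond the confidence
channel, and any between-participant variability. Green tests establish
that the *estimators* recover what this idealized world injected, not that
human data would behave identically.

## Numerical choices

* Angles are radians everywhere, wrapped to $(-\pi, \pi]$ with the odd
  boundary mapped to $+\pi$; times in seconds, lengths in meters.
* erf is evaluated through `pnorm`; quadrature oracles in the tests use
  composite Simpson on $\pm 8\sigma$.
* The L1 fitness integral is a trapezoid on the samples inside the window;
  windows are half-open $[t_0, t_1)$ in the segmentation and inclusive at
  the sample level in the integral.
* All RNG streams are derived deterministically: R-side draws via
  `set.seed` on the stage seed, C++ PSO streams from a per-(window, order)
  hash of the configuration seed; reruns are bit-identical.
* Ordering ties in correction sets break by larger $|a|$ first, making
  serialization deterministic.
* Latency scans exclude undefined lags (too few pairs, constant sides)
  from the argmax rather than failing.

## Known limitations

* Onset-level timing of individual corrections inside dense trains is
  limited by identifiability, not optimization (see above).
* The circular median is $O(n^2)$; adequate at desk scale, not for
  millions of samples.
* `track_project` assumes section-wise straight/arc geometry; clothoid
  transitions would need a denser projection.
* The pipeline's retinal-flow cue is rendered at a reduced rate and raster
  and interpolated; its latency scan is correspondingly coarser than the
  perceived-error or heading cues.
* The PSO gives no global-optimality guarantee; the acceptance statistics
  quantify how often that matters on the target signal class.
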