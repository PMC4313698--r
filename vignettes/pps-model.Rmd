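---
title: "An audio-tactile network model of peripersonal space and its boundary analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An audio-tactile network model of peripersonal space and its boundary analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Peripersonal space (PPS) is the multisensory-coded region immediately
surrounding the body: stimuli from another modality (here, audition)
interact with touch only when they occur within a limited distance of a
body part. `ppsnet` implements a rate-based network that captures this for
the space around one hand, and the plasticity by which that region can
expand when tactile stimulation of the hand is repeatedly paired with
synchronous sounds from far space — the sensory signature of using a long
tool.

The network has three parts:

* **A tactile map**: 41 x 21 neurons tiling a 20 x 10 cm hand surface
  (0.5 cm spacing), each with a Gaussian receptive field (sd 0.5 cm) in
  hand-centered coordinates.
* **An auditory map**: 101 x 16 neurons tiling a 200 x 30 cm sheet of
  space containing the hand (2 cm spacing), with deliberately coarse
  receptive fields (sd 6 cm) reflecting the poor spatial resolution of
  hearing. The hand occupies `[0, 20] x [0, 10]` cm of this frame, so a
  sound at `(x, y)` lies at the Euclidean distance from the nearest point
  of that rectangle (a sound at `x = 50, y = 5` is 30 cm from the hand;
  at `x = 100`, 80 cm).
* **One multisensory unit** receiving excitatory feedforward synapses
  from every neuron of both maps and returning excitatory feedback with
  the same spatial arrangement.

Every neuron is a leaky integrator with a logistic activation,

$$\tau \frac{dz}{dt} = -z + u, \qquad y = \frac{1}{1 + e^{-s (z - \theta)}},$$

so activities are bounded in `[0, 1]`. Within each unisensory map,
lateral connections follow a Mexican-hat (difference-of-Gaussians)
profile — near excitation, far inhibition — with the self-connection
excluded. The multisensory input is
$u_m = \sum_j W^t_j y^t_j + \sum_j W^a_j y^a_j$; the feedback adds
$B_j\, y_m$ to each unisensory neuron.

Tactile feedforward weights $W^t$ are uniform at the saturation value
$W_{max}$: the hand itself is always "inside" PPS. Auditory weights
$W^a$ are maximal for neurons whose receptive fields lie on or near the
hand and fall off with hand distance along a logistic edge centered at
`wa_center = 57` cm (width 6 cm). This profile is the package's own
choice where only "decreasing with distance" is constrained: a plateau
with a sharp falloff is what gives the model its defining behavior —
clear responses to sounds 30 cm from the hand, silence at 80 cm, and a
flat reaction-time plateau for far sounds. Long-tailed profiles
(exponential or Gaussian decay) leave enough residual drive at 80-140 cm
to blur the far plateau and displace the fitted boundary well beyond the
observed range; we document this because it is the main lesson of the
calibration.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `tactile$rf_sigma` / `auditory$rf_sigma` | 0.5 / 6 | cm | modality spatial resolution |
| `tau` (unisensory) | 20 | ms | settling time scale |
| `ms$tau` | 40 | ms | multisensory integration time |
| `ms$theta`, `ms$slope` | 2, 3 | input units | multisensory threshold / gain |
| `synapses$W_max` | 0.1 | — | feedforward saturation |
| `synapses$wa_center`, `wa_width` | 57, 6 | cm | basal auditory weight falloff |
| `synapses$feedback_t`, `feedback_a` | 1.5 | input units | feedback gain |
| `stimulus$intensity`, `sigma` | 10, 1.5 | units, cm | canonical test stimulus |
| `noise$intensity_frac` | 0.2 | — | per-presentation intensity jitter |
| `integration$dt` | 0.5 | ms | Euler step (guard: `dt <= tau/5`) |

The multisensory unit integrates twice as slowly as the unisensory maps
(`ms$tau = 40` ms). This is a deliberate design choice: the network
reaction time is read out as the moment the summed tactile activity
reaches 90% of its final value, and the speeding conferred by an
in-field sound is carried by the earlier rise of the multisensory unit's
feedback. With all time constants equal, that head start is only a few
milliseconds and is drowned by intensity noise; a slower multisensory
unit amplifies the same mechanism into a measurable, stable contrast
without altering any steady state.

Intensity noise is multiplicative and uniform, `I ~ I0 U(1 - a, 1 + a)`
with `a = 0.2`, drawn once per stimulus presentation. It is the only
stochastic element of the simulations.

## Training

Tool use is emulated purely at the sensory level: 30 presentations of a
300 ms tactile stimulus at the hand center paired with a 300 ms auditory
stimulus at `x = 100` cm (80 cm from the hand). During presentations the
feedforward synapses follow a Hebbian rule with saturation and
forgetting,

$$\Delta W_j = dt\, y_m \left[\gamma_{pot}\, y_j (W_{max} - W_j) -
\gamma_{forget}\, W_j (1 - y_j)\right],$$

applied to both synapse sets; feedback weights stay fixed. Each
presentation starts from rest (no carry-over across the
inter-presentation gap). In the synchronous protocol the two stimuli are
simultaneous; in the asynchronous control each presentation draws a
signed onset asynchrony with magnitude uniform on `[280, 880]` ms, so
the stimuli are sometimes partially superimposed and usually fully
separated.

Two calibration facts shape the defaults, both consequences of the
20 ms persistence of activity after stimulus offset:

1. **Asynchrony must out-run the persistence.** A pairing whose gap is
   shorter than the decay tail still produces tens of milliseconds of
   genuine pre/post co-activity. Worse, once the far-space weights
   accumulate to the point where the far sound alone can trigger the
   multisensory unit, every subsequent sound presentation potentiates
   further — a runaway that converts the asynchronous control into a de
   facto synchronous training. The default SOA range keeps effective
   co-activity rare enough that the maximal asynchronous weight change
   stays well below 10% of the synchronous one while partial overlaps
   still occur.
2. **Forgetting must be slow.** During any training, all off-stimulus
   neurons are silent while the multisensory unit is active; a forgetting
   rate strong enough to erase asynchronous potentiation within the
   session would equally erode the basal hand map, which the data say is
   untouched. Forgetting is therefore kept three orders of magnitude
   below potentiation (`1e-6` vs `4e-4` per ms) and acts as a slow decay
   channel, while the asynchronous null result rests on the scarcity of
   correlated activity.

`gamma_pot = 4e-4`/ms was fixed so that 30 synchronous pairings drive the
trained patch of auditory weights essentially to saturation, with a
tapered edge wide enough that the post-training receptive field reaches
(and stops at) 90 cm.

## Test batteries and the boundary fit

Two read-outs mirror the experimental protocols:

* **Receptive-field mapping** (`map_auditory_rf`): a unimodal sound at
  each distance, 30 repetitions with independent intensity noise, from
  rest each time; the receptive-field *extent* is the largest tested
  distance whose mean multisensory activation is at least half the
  maximum mean.
* **Reaction-time battery** (`rt_vs_distance`): simultaneous touch (hand
  center) and sound at one of 15 distances (140 down to 0 cm, 10 cm
  steps), 30 repetitions; the network RT is the first time the summed
  tactile activity reaches 90% of its final value (linear interpolation
  between Euler steps). The sum over all tactile neurons is used as the
  aggregate because it is smooth and robust; the final state is the same
  with or without an effective sound, so RT differences are purely
  temporal.

The RT-distance relation is summarized by the sigmoid

$$y(x) = y_{min} + y_{max}\, \frac{e^{(x - x_c)/b}}{1 + e^{(x - x_c)/b}},$$

fitted by Levenberg-Marquardt least squares on the pooled
repetition-level points, and the central point `xc` is the operational
PPS boundary. Numerical safeguards, all visible in `fit_sigmoid()`:

* data-driven initialization (steepest local slope of a 3-point moving
  average) plus deterministic tempered restarts and up to five jittered
  restarts;
* the slope magnitude `|b|` is bounded below at a quarter of the x-grid
  step — a transition sharper than the sampling cannot be resolved, and
  letting `b` collapse to zero destroys the Jacobian;
* the 95% CI of `xc` is t-based from the asymptotic covariance; when the
  `b` direction degenerates anyway (SE larger than the x-range), the
  interval falls back to a stratified bootstrap over repetitions. A
  bootstrap interval can also be requested explicitly.
* There are two circulating conventions for the sigmoid midpoint —
  `ymin + ymax/2` (this parameterization) versus the mean of the two
  saturation levels when `ymax` is read as the upper level. They
  coincide in `xc`; the fit records the midpoint level explicitly so
  the convention is unambiguous.

Degenerate inputs (flat response, no x-range, fewer than four points)
raise errors rather than returning a meaningless boundary.

## Behavioral pipeline

The same boundary analysis applies to human tactile reaction times from
the audio-tactile interaction task: a touch delivered at one of five
delays (300-2700 ms) after onset of a looming (IN) or receding (OUT)
sound. Delays are recoded to perceived-distance bins (D1 farthest to D5
closest; reversed for OUT), trials beyond two standard deviations of
their subject-by-condition cell are trimmed in a single pass, summaries
average subjects (not trials), and the per-session sigmoid is fitted on
RT versus touch-delivery time for IN sounds. The trimming cell
granularity is configurable because "each condition" is ambiguous in the
source description; subject x training-condition is the default. The two
post-training blocks are pooled into one "after" session by default,
matching the single after-training curve that is reported.

The package bundles the published group means (`reference_rt_means()`),
including the explicitly missing after-training D1 IN cell, and a
synthetic trial generator (`generate_rt_dataset()`) whose structure is a
true sigmoid on touch-delivery time plus an additive subject intercept
(SD 20 ms), Gaussian trial noise (SD 40 ms), a 2% rate of late outliers
and 23% catch trials. The generator exists so the full trim-and-fit
pipeline can be validated by parameter recovery; it deliberately omits
features of real RT data (right-skewed tails, sequential effects,
fatigue drifts), so recovery results say nothing about those.

A caution from the worked example: the four-parameter least-squares fit
of the five published before-training IN means yields a central point of
913 ms (global optimum, verified by a profile scan of the residual
surface), not the 1055 ms quoted alongside those means, which was
presumably estimated from subject-level data that are not published. The
package reports what it computes.

## Known limitations

* One multisensory unit: no population of PPS neurons, no head/trunk
  maps, no visual modality.
* The trained expansion is a patch anchored at the training location.
  Between the basal boundary (~57 cm) and the inner edge of the trained
  patch (~70 cm) the multisensory response shows a shallow notch, and
  the post-training RT transition is consequently steep: the fitted
  central point after synchronous training lands just above 90 cm, at
  the upper edge of the plausible range, whereas its receptive-field
  extent is exactly 90 cm. A broader training stimulus set (several far
  locations) would smooth this; it is outside the reproduced protocol.
* The asynchronous null depends on the SOA distribution out-running the
  network's activity persistence, as described above.
* Euler integration with `dt = 0.5` ms (tau/40); the trajectory agrees
  with a ten-fold finer step to well under integration noise, and a
  stability guard rejects `dt > tau/5`.

## Problem sizes used by the bundled checks

The test suite and the acceptance script run the full battery at the
protocol scale — 15 distances x 30 repetitions per condition for the RT
curves and the receptive-field maps, 30 training presentations per mode —
and the statistical property checks use 200 synthetic replicates
(bootstrap/coverage/recovery). A complete battery takes a few minutes on
one core.
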