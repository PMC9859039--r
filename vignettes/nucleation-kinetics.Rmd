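---
title: "Modelling and measuring templated microtubule nucleation"
author: "tirfnuc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring templated microtubule nucleation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirfnuc)
```

## The kinetic model

In a single-molecule TIRF nucleation assay, ring-complex templates are
attached to a passivated coverslip and microtubules (MTs) grow out of
them once polymerization mix is added. The cumulative number of MTs
nucleated, $N(t)$, rises linearly at first and then saturates as the
finite pool of activatable templates is consumed. `tirfnuc` models this
with the saturating-exponential rate law

$$N(t) = N_{max}\left(1 - e^{-k t / N_{max}}\right),$$

where $k$ (MTs s$^{-1}$) is the initial nucleation rate and $N_{max}$
the total number of activatable templates. Two properties anchor the
parameterization: $\mathrm{d}N/\mathrm{d}t|_{t=0} = k$ exactly, and
$N \to N_{max}$. `nucleation_counts()` evaluates this closed form;
`nucleation_trajectory()` integrates its discrete-time counterpart

$$N_t = N_{t-\Delta t} + \Delta t\, k \left(1 - N_{t-\Delta t}/N_{max}\right),$$

the per-second bookkeeping used in deterministic simulations of the
assay ($\Delta t = 1$ s by default). The discrete update is clamped so
$N$ never exceeds $N_{max}$; counts are real-valued here, and
integerization happens only in the movie simulator. As
$\Delta t \to 0$ the recursion converges to the closed form; at
$\Delta t = 1/16$ s the maximum deviation over 150 s is well below 1%
of $N_{max}$ (tested). At $\Delta t = 1$ s the recursion is itself a
geometric saturation with effective rate
$-N_{max}\log(1 - k/N_{max})$, which is why fitting the closed form to
per-second discrete data overestimates $k$ by about 4% at
$k = 24.5$, $N_{max} = 300$ — within the 5% envelope we require of
rate recovery on discrete data.

`two_phase_trajectory()` implements a delayed-activation scenario: a
slow condition runs until a switch time, after which the rate becomes
the wildtype rate and the capacity is redefined as the wildtype
capacity minus the MTs already made (floored at zero — MTs are never
removed). Note that the post-switch law restarts saturation on the
*remaining* capacity; switching a condition to itself therefore
reproduces the single-phase curve only up to this restart (exactly so
when the switch happens at or near saturation).

The model deliberately excludes stochastic (Poisson) nucleation,
catastrophe and rescue: the assay's templated MTs grow persistently on
the timescale analyzed, and the deterministic law is what the fitted
rates refer to.

### Stoichiometric arithmetic

Two small calculations recur when interpreting such assays and are
exposed as functions: `free_tubulin()` applies the 2:1
tubulin-per-stathmin sequestration rule (floored at zero), so 4 µM
stathmin in a 15 µM tubulin reaction leaves 7 µM free — the critical
concentration at which templated nucleation stalls; and
`dimer_occupancy()` converts a measured activator-dimer concentration
over a template concentration into retained/lost fractions (50 nM over
150 nM: two thirds lost).

## The synthetic-movie generator

`simulate_tracks()` turns the real-valued trajectory into whole MTs:
fractional births accumulate and a track spawns whenever the
accumulated count crosses an integer. The floor carries a $10^{-6}$
snap because the trajectory approaches $N_{max}$ strictly from below
in floating point; without the snap the final template would never
fire even arbitrarily long after effective saturation.

Each MT receives a uniform random position on the plane and one of
eight discrete orientations (multiples of 45°), drawn from a stream
seeded by `simulation_config(seed=)` and independent of the caller's
RNG state. Defaults mirror the simulated assay: a 40×40-pixel plane,
1 s kinetic step, 2 s frame interval, 300 s duration. The literature
the assay comes from is ambiguous about whether the simulated plane is
40 px or 40 µm across; both are expressible (`plane_px`,
`pixel_size`), the default takes the pixel reading literally, and the
default pixel size (0.1587 µm = 40 µm/252 px) matches the analysis
window of the real data. Growth is constant-speed, 1.5 µm min$^{-1}$
by default — a typical templated-assay speed chosen once, since the
assay's mean speed is a distribution, not a printed constant.
Templated MTs keep an anchored minus end; `templated_fraction < 1`
makes the remainder grow from both ends, with the minus end at half
the plus-end speed by default (minus ends elongate more slowly).
Tracks may grow out of frame; `grow_tracks()` clips segments to the
plane for rendering (Liang–Barsky) but ground truth keeps the full
length and flags the track censored.

`render_movie()` converts geometry to TIRF-like images: each segment
contributes a line integral (intensity per µm, deposited bilinearly at
¼-px steps so the total equals intensity × in-plane length exactly),
blurred with a Gaussian PSF (σ = 0.17 µm default, a high-NA TIRF
objective at ~570 nm). The blur uses a circular boundary, so total
flux is conserved and the summed frame intensity is exactly
proportional to total in-plane length under zero noise (tested at
R² > 0.999 with the fitted slope equal to the configured intensity).
MTs below the diffraction limit still scatter light, so rendering
floors the effective length at `min_visible_um` (0.2 µm default); set
it to 0 for strict length-proportional photometry. The optional
plus-end channel places a fixed-amplitude Gaussian comet at each
in-plane plus end, mimicking an end-binding marker — this is why MT
*counting* is best done on that channel: a newborn MT is immediately
as bright as an old one. Camera noise is Poisson shot noise on the
expected signal plus Gaussian read noise, then a constant offset, then
quantization to integer camera units. All randomness is seeded:
identical configuration and seeds give byte-identical TIFF files
(tested by checksum).

What the generator does *not* emulate: photobleaching, stage drift,
uneven illumination, depolymerization, out-of-focus light and
aster/bead geometries. Tests passing on these movies therefore
validate the algorithms' correctness on clean, flat-field data; they
do not certify performance on real movies with those artefacts.

## The image pipeline

`measure_mass_trace()` follows the standard mass macro — per-frame
Otsu threshold, sub-threshold pixels zeroed, whole-frame mean,
first-frame mean subtracted — with two numerical choices of our own.
First, the frame median (camera offset plus diffuse background) is
subtracted before the masked mean; otherwise every masked pixel
carries the offset and the trace measures thresholded *area*, not
signal. Second, the mask is computed on a 3×3-smoothed copy of the
frame (intensities still read from the raw frame), which stabilizes
the mask under shot noise. A known limitation remains: Otsu assumes a
usefully bimodal histogram, and on nearly empty noise-free frames
(one or two short MTs) the threshold is bistable and the trace jumps;
in the many-MT regime the assay operates in, the corrected trace is
proportional to true total MT length with R² > 0.999 (tested against
ground truth). Frames with no resolvable threshold (blank movies)
record 0.

`count_plus_end_spots()` reproduces the spot-counting macro: crop
(50×50 µm by default), 3×3 mean smooth, Yen threshold, Sobel gradient
of the binary mask (each particle becomes a closed edge ring), and a
connected-component count within a 2–200 px size band. Yen's
maximum-correlation criterion is implemented directly on a 256-bin
histogram over the image range and pinned against an independent
implementation. Spots closer than the resolution limit merge and
count once — tested explicitly, and the reason counts are exact only
for well-separated MTs. Counting is invariant to whole-pixel
translations (tested).

`extract_kymograph()` resamples a polyline at 1-px spacing and takes,
per position and frame, the maximum intensity across a 3-px
perpendicular width. Classification thresholds the kymograph globally
(Otsu) and tracks the low/high boundary of the signal extent per
frame: a boundary is a growing edge when it moves ≥ 2 px with a
consistently signed least-squares slope. One growing edge means
templated (anchored minus end, a right-triangle wedge), two mean
spontaneous, none yields "indeterminate" and the record is excluded
from rate counts. `growth_speed_and_length()` fits the growing edge
position against time (slope × pixel size × 60 → µm min$^{-1}$) and
reports the largest end-to-end extent, flagging records whose signal
reaches the line's end as censored. On noise-free, non-crossing
tracks, speeds are recovered within 5% and classification is perfect
(tested); crossing MTs corrupt each other's kymographs, which is the
main practical failure mode and the reason the real protocol picks
lines manually.

`count_trajectory_from_movie()` automates MT discovery: per frame
(first 150 s by default), threshold, label components ≥ 2 px, and
declare a birth when a component lies > 3 px from everything detected
in the previous frame, recording its centroid as the nucleation
origin. This is birth detection, not comet tracking; it works on the
plus-end channel (compact, constant-brightness spots) and on the
polymer channel (anchored MTs always overlap their previous
footprint). Two guards matter in practice: thresholds within
$10^{-8}$ relative range of a constant frame are treated as undefined
(FFT convolution leaves ~$10^{-13}$ ripples), and a frame whose
automatic threshold is less than 3 MADs above the frame median is
treated as signal-free rather than thresholding pure camera noise.
On noise-free and default-noise movies of a saturating condition,
recovered counts match the integerized truth within ±1 per frame
(tested).

## Model fitting and statistics

`fit_nucleation()` estimates $(k, N_{max})$ by bounded
Levenberg–Marquardt least squares (lower bounds $10^{-6}$), unweighted,
over the first 150 s. Starts are multi-started: $k_0$ from the largest
early first-difference slope and $N_{max,0} \in \{1, 2, 10\}\times$
max count, keeping the smallest residual. $N_{max}$ is reported per
fit but flagged `weakly_identified` when the Hessian-based 95%
relative half-width exceeds 100% *or* the trajectory never reaches
half the fitted capacity — the latter matters for noise-free
near-linear data, whose vanishing residuals make the covariance
uninformative. Noise-free self-consistency is exact to optimizer
tolerance across $k \in [0.5, 50]$, $N_{max} \in [10, 1000]$; under
Poisson count noise the rate is unbiased within 10% over 100
replicates (tested, seeded).

`late_slope()` reports the ordinary least-squares slope over
25–150 s, the residual nucleation rate after the initial burst; for a
wildtype-like curve ($k = 24.5$, $N_{max} = 300$) it evaluates to
≈ 0.15 MTs s$^{-1}$. Replicates are aggregated as mean ± SEM of $k$
(the between-replicate SEM is the headline uncertainty, not the
per-fit covariance); conditions are compared with two-sided unpaired
Student's t-tests (α = 0.05; two degenerate equal-mean zero-variance
samples give p = 1 by convention), and fold changes divide by the
buffer-control mean, with optional per-experiment pairing. No
multiple-testing correction is applied, matching the assay's
statistical protocol.

## Problem sizes and reproducibility

The test suite and analysis scripts run on deliberately small
configurations — planes of 40–160 px, movies of 30–240 s at 2 s
intervals, 4–25 tracks, 100 noisy fit replicates — chosen so the full
suite exercises every pathway (simulation, rendering, photometry,
kymographs, counting, fitting, statistics) in under a minute while
every quantitative claim above is still asserted at its stated
tolerance. All stochastic steps (placement, orientation, camera
noise, replicate noise) draw from explicit seeds, and byte-identical
reproduction of rendered TIFFs under a fixed seed is itself a tested
property.
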