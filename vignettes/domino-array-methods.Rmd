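---
title: "Models and methods behind dominoArray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dominoArray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dominoArray analyzes single-molecule recordings of reconfigurable DNA
origami domino arrays: lattices of anti-junctions that, once trigger
strands bind along one edge, relay a conformational change diagonally
through the structure. The package covers the whole measurement chain —
a kinetic simulator of the cascade, a renderer producing realistic
dual-color turn-on FRET time-lapse movies, image analysis, two-state
hidden Markov modeling of per-structure intensity transients, and the
coupling statistics used to quantify how tightly pairs of junctions move
together. This vignette explains the models, the defaults, and the
choices made where the underlying experimental literature leaves the
details open.

## The lattice energy landscape

Each anti-junction is a two-state unit, untransformed (0) or transformed
(1). The experimental picture is that intermediates are destabilized in
proportion to their number of open anti-junctions, and that trigger
hybridization tilts the landscape toward the transformed conformation.
We realize this as a lattice Hamiltonian

$$E(s) \;=\; J\, D(s) \;-\; \sum_{i \in \mathrm{triggers}} h_i\, s_i
\;+\; \epsilon \sum_{i \notin \mathrm{triggers}} s_i ,$$

where $D(s)$ counts adjacent site pairs in differing conformations
(each such interface represents open, strained junction arms), $h_i$ is
the hybridization stabilization a bound trigger grants its edge
junction, and $\epsilon$ (`strain`) is a small penalty for the
transformed conformation of an untriggered junction. The field terms are
active from trigger addition onward; with the field off every uniform
state has energy exactly zero. The strain term is not part of the
minimal open-junction picture but is needed for two observed behaviors:
untriggered regions must prefer the untransformed conformation (an
isolated junction should rest dark rather than drift to a 50/50
equilibrium), and withholding a trigger must leave its junction
genuinely bistable.

Dynamics are continuous-time kinetic Monte Carlo over single-site flips
with Metropolis-style barriers,
$k = k_0 \exp[-(\max(\Delta E, 0) + \Delta G_\mathrm{lock})/RT]$, where
the lock barrier applies only to moves taking a locked site out of the
untransformed conformation. No rate law is established experimentally
for these junctions; Metropolis barriers are the standard minimal
choice and satisfy detailed balance in the field-free case (verified
against Boltzmann occupancies in the test suite). Trigger strands bind
after independent exponential delays (`bindingRate`), reflecting
addition of the triggers in excess at the start of the recording.

### Geometry

The array has 5 x 2.5 anti-junctions with five triggers along the long
right edge. We draw it as a 5-row x 3-column grid, trigger column on
the right, and taper the occupancy mask away from the trigger edge
(middle column: 3 junctions; far column: 2) to represent the fractional
width. The taper is also a kinetic modeling choice: it makes the first
reconfiguration step rate-limiting and the remainder of the cascade
downhill, reproducing the observed behavior that structures sit
untransformed for a waiting time and then convert in a rapid, highly
coordinated zip. On a full rectangle, nucleation and propagation
barriers interleave and the simulated cascade stalls mid-way — a regime
the experiments do not show.

The lattice coordinates of the probed positions are not published; the
shipped map (`probePositions()`) is a documented assumption: Position 1
is the middle-column junction next to the strongest trigger corner,
Positions 2 and 4 lie further along the middle column, Position 3 is a
far-column junction downstream of the relay, and Position 5 is the
partner of Position 1 in the same cascade step. `edge` labels the bottom
trigger-edge junction whose trigger strand is withheld in the
four-trigger regime.

### Calibrated defaults

The generator's defaults define the study conditions and were frozen
after trajectory-level calibration runs:

| parameter | value | role |
|---|---|---|
| $J$ | 3.7 kcal/mol | interface penalty; sets the stability of the transformed array (weakest reversal barrier $2J-\epsilon \approx 6.4$ kcal/mol keeps probes quiet over 25 min) |
| $\epsilon$ | 1.0 kcal/mol | strain of transformed untriggered junctions; sets the nucleation ladder ($+\epsilon$ per rung) and the residual flicker of cut-off junctions |
| $h$ | 12, 6, 5, 4.5, 8 kcal/mol (top to bottom) | trigger stabilization; the large top value plus the fastest binding encodes the asymmetric design that initiates the cascade at the top-right corner |
| $k_0$ | 8 s$^{-1}$ | attempt rate; places dwell times of reversible junctions in the seconds range so a 1 Hz recording resolves them |
| binding rates | 0.5, 0.1, 0.1, 0.1, 0.05 s$^{-1}$ | trigger strand binding at the working concentration; the top trigger binds first |

With these values the five-trigger cascade completes in the first
minute(s) of a 25 min recording in essentially every trajectory, probe
junctions show a single irreversible step, and the un-triggered edge
junction in the four-trigger regime flickers reversibly between two
well-defined levels — the qualitative phenomenology of the experiments.
The absolute timescale is faster than the published lag times (which
depend on unknown molecular attempt frequencies); all package-level
statements are therefore about orderings, fractions and recovery, not
about reproducing printed lag times.

### Design presets

* `five_trigger` — all triggers; probes on two junctions that transform
  quasi-simultaneously in the zip.
* `four_trigger` — upper four triggers; the green probe monitors the
  bottom edge junction, which then lacks its own stabilization and
  fluctuates reversibly.
* `lock_design_1..4` — the lock/deletion series, probes on the
  middle-column relay (red) and the far-column terminal junction
  (green). Design 2 adds a 2.8 kcal/mol lock barrier on the terminal
  junction, injecting an exponential-like delay with simulation mean
  59.9 s (the large-sample reference value used by the tests). Design 3
  deletes the central relay junction, leaving the terminal junction
  connected only through a dangling chain that flickers without
  sustaining the transformed state. Design 4 additionally disables the
  terminal junction's switching (modeled as an effectively infinite
  exit barrier — its staples are left out, so the junction cannot
  relay), so the transformation never progresses there.

Deviations from the published design series worth noting: our Design 3
produces a terminal junction that never completes its transformation
(coupling values pile up near zero), whereas the experimental Design 3
showed a reversed transformation order with mostly uncoupled timing.
The ordering of fully-coupled fractions across Designs 1 to 3 — the
property the package asserts — is reproduced; the printed percentages
are not, as they belong to the experimental data.

## The synthetic microscope

`renderMovie` renders each probe as a pixel-integrated 2-D Gaussian
PSF with Poisson photon statistics on a Poisson background,
alternating-excitation timing (100 ms exposure, 1 s period per color,
0.5 s inter-channel lag, 25 min), single-step photobleaching in
cumulative illuminated on-time, always-on fiducials, linear stage drift
with random-walk jitter, and a chromatic offset of the green channel.
Defaults (300 photons/frame on-state, background 20 photons/px, PSF
sigma about 1 px) give a peak-pixel SNR near 5, typical of single-dye
TIRF. The quenched state emits a 2% residual. The conformation sampled
at the start of each exposure determines that frame's emission;
sub-exposure averaging is not modeled, so reversals faster than the
frame period alias, exactly as they would in the real recording.

What the generator deliberately does not emulate: quencher
photobleaching (excluded experimentally by controls), FRET intermediate
levels (the probes are binary turn-on reporters), non-rigid sample
deformation, and camera read noise (shot-noise limited EMCCD detection
is assumed). Passing tests on these movies therefore validates the
algorithmic chain, not detector-specific robustness.

## Image analysis

Fiducials are detected on the average of the first frames
(difference-of-Gaussians, threshold in robust noise units, default 5
sigma) and must stay above half their on-level in at least 95% of
frames including frame 0. Subpixel positions come from an iterated
Gaussian-weighted centroid; iteration removes the shrinkage pull of the
weighting window toward its integer seed pixel. Drift is the median
fiducial displacement per frame, smoothed with a short running mean;
frames are never resampled — shifts are applied to extraction
coordinates. Channel registration fits green-to-red coordinates
least-squares (affine with at least three non-collinear pairs,
translation otherwise; translation can be forced, and is the right
choice when the chromatic aberration is a pure shift).

Appearing spots are detected on the pixelwise maximum of
(drift-corrected temporal block mean minus early baseline mean), DoG
filtered; anything already present in the baseline (fiducials,
pre-transformed structures) is excluded. Transients are disk sums
(radius 3 px) minus the disk area times a robust annulus background
(5-8 px). The annulus statistic is the mean over a symmetric window
around the median — robust to bleed-through from neighboring
structures, yet unbiased on counting noise, which a discrete median is
not. Colocalization pairs mutual nearest neighbors within 1.5 px after
mapping green into red coordinates; structures detected in only one
channel still get a transient extracted at the registered partner
position so that dark partners (as in the deletion designs) enter the
accounting.

## Transient analysis

Each transient is fitted with a two-state Gaussian-emission HMM by
expectation-maximization (tolerance 1e-4 on the log-likelihood, at most
500 iterations) and decoded with Viterbi. EM is run from five
deterministic initializations (central 2-means split, extreme
quantiles, baseline-anchored, and minimum-/maximum-anchored splits) and
the highest-likelihood fit wins; the extra starts matter for turn-on
traces that spend under 1% of the record in one level. A fit collapses
to "single state" when the level separation is below one pooled noise
sigma or when a single Gaussian explains the data at least as well by
BIC; such traces never yield a transformation call.

The transformation time is the time of the first
untransformed-to-transformed transition followed by at least 10 s of
uninterrupted transformed occupancy (the dwell must be uninterrupted;
an interrupted early visit defers the call to the next qualifying
transition). A terminal drop to background that persists to the end of
the record is labeled single-step photobleaching and truncates the
path; truncation precedes fluctuation classification so bleaching is
not counted as a reversal. A structure is kept only if both channels
turned on.

## Coupling statistics

The coupling parameter compares the time two junctions spend in the
same conformation with the time they spend in differing conformations:
$C = n_\mathrm{same} / (n_\mathrm{same} + n_\mathrm{diff})$ over
aligned frames, after truncating both channels at the earlier bleach,
aligning the half-period-lagged green frames to the nearest red frame,
and excluding the frame pair flanking every decoded jump (the
interleaved sampling would otherwise count transition frames as
spurious differences). The published formula for C lives in
supplementary material that constrains only its range and endpoints, so
the normalization window is a documented reconstruction here: the
default counts the whole shared record, which matches the hand-counted
worked example this package validates against; a window starting at the
first transition of either channel is available
(`window = "first_transition"`) for analyses where long pre-transformation
stretches would inflate C. Delta-t is green minus red. Gaussian
summaries of delta-t distributions are maximum-likelihood on the raw
values (bin-free), with the standard error sigma over root n, and exact
zeros can be excluded when quantifying a delayed subpopulation.

Lock-unit energetics use the unified nearest-neighbor dG37 parameter
set at 1 M NaCl with no salt correction; which parameter set and
condition produced the published midpoint energy is not stated, so no
numeric agreement with it is asserted. The transport-efficiency
titration fits a two-parameter logistic (binomial GLM on counts when
available) and refuses to extrapolate a midpoint outside the measured
range.

## Numerical choices and problem sizes

Rates are recomputed from scratch each KMC step (the lattice has at
most 15 sites); the Gillespie clock is capped at field switch-on times
so time-dependent trigger activation stays exact. The test suite runs
the detailed-balance check with 1e6 events on a 2 x 2 field-free
lattice, the two-site first-passage comparison with 1e4 trajectories
against the closed-form CTMC absorption time, end-to-end recovery on 50
rendered structures, and the design orderings with 120-200 trajectories
per condition; these sizes put every stochastic assertion at least
three standard errors from its pass boundary while keeping the full
suite to a few minutes. Rendered fields default to 128 x 128 px with a
minimum separation of 7 px between structures so that one structure's
background annulus is not contaminated by a neighbor's PSF core.

## Known limitations

* The model compresses the experimental multi-intermediate climb into a
  single nucleation wait followed by a fast zip, so lag-time structure
  between probe positions within the five-trigger cascade (beyond the
  lock-injected delays) is not reproduced.
* Four-trigger reversibility is localized at the un-triggered edge
  junction rather than spread across the distal positions, and its
  correlated component is weaker than observed.
* Printed experimental percentages (yields, fully-coupled fractions,
  the 198 s lag, the 16.0 kcal/mol midpoint) are measurements on the
  deposited experimental movies and are not reproduced at desk scale;
  the package asserts orderings, endpoint behavior and recovery of its
  own ground truth instead.
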