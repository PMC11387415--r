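# dominoArray

Single-molecule analysis of allosteric transformation cascades in
reconfigurable DNA origami arrays.

DNA origami "domino" arrays are built from anti-junctions, four-way
motifs that each adopt one of two stable stacked conformations. Trigger
strands hybridizing along one edge bias the edge junctions toward the
transformed conformation and launch a stepwise, diagonal cascade through
the array — an artificial analogue of allosteric signal propagation.
Dual-color turn-on FRET probes placed on chosen junctions make the
cascade observable junction by junction in TIRF time-lapse movies: each
probe is quenched until its junction transforms and then lights up.

`dominoArray` is for researchers analyzing such recordings (and for
anyone who wants a fully controllable synthetic twin of them). It
implements the complete chain:

* **Cascade model** — a lattice kinetic Monte Carlo simulator on an
  energy landscape ranked by the number of open anti-junction
  interfaces,
  `E = J·D − Σ h_i s_i + ε·Σ s_j` (interfaces `D`, trigger fields `h`,
  strain `ε` of transformed untriggered junctions), with Metropolis
  barriers `k = k0·exp(−(max(ΔE,0)+ΔG_lock)/RT)`, trigger-binding
  delays, lock barriers and junction deletions for engineered designs.
* **Synthetic microscope** — renders simulated cascades into dual-color
  movies: Gaussian PSFs, Poisson photons and background, alternating
  excitation (100 ms exposure, 1 s per color, 0.5 s lag, 25 min),
  single-step photobleaching, fiducials, stage drift, chromatic offset.
* **Image analysis** — fiducial-based drift correction, channel
  registration, appearing-spot detection, background-subtracted
  transient extraction, dual-color colocalization.
* **Transient analysis** — two-state Gaussian-emission HMM (EM +
  Viterbi), transformation times under the 10 s minimum-dwell rule,
  photobleach truncation, fluctuation classification, dual-on filter.
* **Coupling statistics** — the coupling parameter
  `C = same/(same+differing)` over aligned, jump-excluded frames
  (`C > 0.95` = fully coupled), Δt = t_green − t_red with Gaussian
  summaries, population fractions with standard errors, transformation
  yield, nearest-neighbor duplex energetics of lock units, and logistic
  transport-efficiency titrations.

## Worked example

```r
library(dominoArray)

m <- latticeModel()
m
#> LatticeModel: 5 x 3 anti-junction lattice
#>   present sites: 10 | triggers: 5 | removed: 0
#>   J = 3.7, h = [12, 6, 5, 4.5, 8], strain = 1 kcal/mol; k0 = 8 /s; T = 310.15 K

traj <- simulateCascade(m, duration = 1500, seed = 42)
traj
#> LatticeTrajectory: 14 events over 1500 s (seed 42 )

P <- probePositions()
trueTransformationTime(traj, P$P1)   # first sustained switch, Position 1
#> [1] 6.881437
trueTransformationTime(traj, P$P3)
#> [1] 7.12844
```

The two probed junctions transform within a quarter second of each
other — the cascade waits for nucleation, then zips through the array.
The full pipeline turns rendered movies back into exactly these
quantities:

```r
ds  <- generateDataset("five_trigger", seed = 7, nStructures = 12)
res <- analyzeDataset(ds)
res$counts
#>    detected colocalized      dualOn transformed    cDefined
#>          12          12          12          12          12

kept <- subset(res$structures, dual_on & colocalized)
median(kept$delta_t_s)
#> [1] 0.5
fractionFullyCoupled(kept$C)$fraction
#> [1] 1
```

All 12 rendered structures are detected, colocalized across the two
channels, turn on in both colors, and are fully coupled (`C > 0.95`):
with all five triggers the two monitored junctions switch within the
1 s frame resolution, so Δt sits at the sampling limit (0.5 s is the
red/green interleave offset).

Scenario presets mirror the study's regimes: `five_trigger`,
`four_trigger` (reversible fluctuations of the un-triggered edge
junction), and `lock_design_1..4` (a lock barrier that injects a
~60 s delay; deletions that decouple or fully block the terminal
junction). `runEndToEnd(runConfig(...))` orchestrates
simulate–render–analyze–summarize with fixed file contracts, and
`inst/scripts/domino.R` exposes the same flow on the command line.

## Layout

| path | contents |
|---|---|
| `R/` | lattice model + KMC (`lattice.R`), renderer (`render.R`, `datasets.R`), imaging (`imaging.R`), HMM (`hmm.R`), coupling statistics (`coupling.R`, `thermo.R`), pipeline (`pipeline.R`) |
| `src/` | Rcpp cores: kinetic Monte Carlo, HMM forward-backward and Viterbi |
| `tests/testthat/` | unit, property and acceptance tests |
| `vignettes/domino-array-methods.Rmd` | models, assumptions, calibration and limitations |
| `inst/scripts/domino.R` | command-line front end |
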