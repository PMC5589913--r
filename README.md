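# epiratchet

Quantification of interfacial ratcheting during epithelial cell
intercalation.

## The problem

Intercalating epithelial cells (for example in the germband of a gastrulating
*Drosophila* embryo) remodel their junctions in pulses: apical areas
oscillate, and the cell–cell interfaces between anterior–posterior neighbors
("AP interfaces", oriented near the dorsoventral axis) contract in discrete
active steps. Whether those steps accumulate into net interface shortening
depends on a *ratchet* — a mechanism, here transient planar-polarized
membrane compartments at the interface, that prevents relengthening between
pulses. Deciding whether a perturbation breaks the ratchet (steps still
occur, but reverse) rather than the contraction machinery itself (steps
disappear) requires a specific quantification chain, which this package
implements for 2-D two-channel time-lapse movies:

* **Tissue model** — seeded-watershed segmentation of the membrane channel
  into a label movie, skeletonized into cells, vertices and interfaces with
  persistent identities across frames.
* **MSD decomposition** — interface-length trajectories are summarized by
  the time-averaged mean squared displacement
  `MSD(τ) = A(1 − e^{−ατ}) + 2Bτ + C²τ²`
  (confined amplitude `A` µm², rate `α` 1/s, diffusion coefficient `B`
  µm²/s, active speed `C` µm/s), fitted by constrained least squares with
  component selection.
* **Step detection** — a rolling-window local MSD exponent γ(t)
  (`MSD ∝ τ^γ`, windows 21/41/61/81 frames, log–log fit over lags
  5…3(W−1)/4) marks active periods; runs ≥ 14 frames become steps, whose
  signed displacements give per-interface frequency, duration, and net
  stepped distance — the ratchet readout.
* **Oscillation amplitude** — Savitzky–Golay smoothing, Gaussian detrending
  (σ = 200 s), analytic-signal (Hilbert) envelope as a percentage of the
  local average area.
* **Compartment detection/tracking** — à-trous B3-spline wavelet
  multiscale-product spot detection; assignment-based frame-to-frame
  linking with gap closing (≤ 4 px and ≤ 3 s).
* **Association analytics** — compartment↔interface assignment (within
  10 px, uniquely closest, clear of vertices), AP/transverse interface
  classification (±15° of the DV axis over the first 90 s), density vs
  orientation, pairing/monopolarity, lifetimes with movie-length
  correction, fixed and live colocalization.
* **Synthetic ground truth** — generators for stepped-lattice label/membrane
  movies, component-wise trajectories, and compartment spot movies, so the
  whole chain is testable without any acquisition.

## Worked example

Generate ground-truthed movies with and without a working ratchet, measure
both, and read out the step metrics for one interior AP interface:

```r
library(epiratchet)

measure <- function(mode) {
  tis <- synth_tissue(mode, n_rows = 4, n_cols = 4, n_frames = 400,
                      n_steps = 4, seed = 1)
  frames  <- lapply(seq_along(tis$labels), function(t)
    frame_from_labels(tis$labels[[t]], tis$meta, t))
  tracked <- track_cells(frames)
  x <- as.numeric(na.omit(tracked$length_series[, "6|7"]))
  list(steps = detect_steps(x, rolling_gamma(x)), fit = msd_components(x))
}

ctl <- measure("control")
ctl$steps
#> step_annotation: 4 steps, net stepped displacement -3.608 um
ctl$fit
#> msd_fit: A=0 um^2, alpha=0 1/s, B=0.0008753 um^2/s, C=0.01312 um/s (rss=22.6)

off <- measure("ratchet_off")
off$steps
#> step_annotation: 4 steps, net stepped displacement 0.000 um
off$fit
#> msd_fit: A=0 um^2, alpha=0 1/s, B=0.0008726 um^2/s, C=0.01427 um/s (rss=21.6)
```

Both interfaces undergo four active steps with near-identical short-lag
MSD components — the contraction machinery itself is indistinguishable.
The net stepped displacement separates them: −3.6 µm of progressive
shortening with the ratchet, zero without it (each contraction reversed).
That single number is the ratchet readout.

The one-call pipeline (`run_pipeline(config)`) chains
segment → track → detect → link → associate → steps → oscillate on a real
or synthetic movie, writes every stage's CSV tables and a JSON summary of
the headline metrics (polarity fractions, lifetimes by interface class,
step metrics, oscillation amplitude).

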