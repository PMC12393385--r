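---
title: "Counting, modelling and profiling ion permeation with permeatr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting, modelling and profiling ion permeation with permeatr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permeatr)
```

`permeatr` analyses ion conduction through a membrane channel from per-ion
coordinate traces. This vignette is the package's account of the science:
the counting model, the stochastic waiting-time models, the profile
observables, the synthetic generator used to validate them, and the
numerical decisions taken where the methods left room.

## The counting model

Conduction is quantified by complete traversals of a bounded cylinder
aligned with the pore axis (+z; extracellular side at larger z). The
cylinder is capped by two boundary planes, placed at the rings of
glutamates that frame the transmembrane pore of cation-selective Cys-loop
receptors, and has a default radius of 17.3 Å — wide enough that an ion
threading the (slightly oblique) helix bundle never leaves it sideways
mid-traversal.

A *TB* event is an ion passing from above the top plane, through the
cylinder, out below the bottom plane; *BT* is the reverse. Three rules
remove ambiguity:

- **Complete events only.** An ion inside the region at the first or last
  frame contributes no event for that residency, so truncated traversals
  never inflate the tally.
- **Radial reset.** If an ion leaves the cylinder through its curved wall
  while inside, its residency is cancelled and it is treated as being back
  outside on the side of its entry ring. This is the conservative
  completion rule; with the default radius it is essentially never
  triggered by genuine traversals.
- **Sub-frame timing.** Event start and end are linear interpolations of
  the boundary-plane crossings between the bracketing frames (switchable
  to frame-snapped times). Frame-to-frame motion over 10-ps intervals is
  small against the pore length, so linear interpolation is adequate and
  makes waiting times independent of the frame phase.

Boundary planes may be fixed or recomputed per frame from the ring-atom
centroids; both are supported because reference analyses do not state
which convention was used. The default when ingesting structures is the
per-frame centroid of the ring C-α atoms.

The net charge translocation of a segment is
`net = TBK⁺ + BTCl⁻ − BTK⁺ − TBCl⁻`; the mean current is
`I = e·net/Δt` and the single-channel conductance `G = |I|/|Ve|`,
reported as a magnitude (inward cation flux at negative voltage is
positive). Long runs are conventionally split into 200-ns windows treated
as independent segments; an event belongs to the window containing its
start time, and waiting times never span a window boundary (they are
pooled across windows for distribution fits).

One bookkeeping caveat is documented rather than hidden: at a single
global voltage of 102 mV the per-segment conductances of the published
count table are reproduced only to within ~1% plus 1–2 pS, because each
run's box height (and hence exact voltage) varied under pressure coupling
and was not published. The column means are reproduced to the printed
rounding.

## Waiting-time models

Inter-event intervals (between start times of consecutive same-direction
events) are modelled two ways.

**Single Poisson.** Density `λe^{−λt}`. The rate comes either from counts
(`λ = N/Δt`) or from a quantile regression: the sorted intervals are
regressed on `−ln(1 − i/N)` with the line forced through the origin (zero
is the shortest possible waiting time), and `λ` is the inverse slope. The
regression uses `i = 1..N−1`; the `i = N` point is excluded because its
regressor is infinite. On data generated exactly from the exponential
quantile function the rate is recovered to machine precision, which the
tests assert.

**Double Poisson (hypoexponential).** Observed intervals show a deficit of
very short waits: an ion entering the pore transiently repels the next
ion at the charged entry ring. This is modelled as two chained exponential
stages — a lag (rate `λ_lag`) and a conduction stage (`λ_cond`) — whose
sum has mean `1/λ_lag + 1/λ_cond` and density

```
f(t) = λ_lag λ_cond / (λ_lag − λ_cond) · (e^{−λ_cond t} − e^{−λ_lag t}).
```

The package implements the order-symmetric form of this density (the
expression above is antisymmetric under exchanging the rates and would be
negative for one ordering; the symmetric form is the distribution of the
sum regardless of labelling). At equal rates the Erlang-2 limit
`λ²te^{−λt}` is returned through an explicit branch (relative rate gap
below 1e-9), keeping density and CDF continuous there; the evaluation
uses `expm1` to remain stable when the rates are close. The expected
event count over a window `T` is `T/(1/λ_lag + 1/λ_cond)`.

Fitting is by maximum likelihood over `(log λ₁, log λ₂)` (Nelder–Mead),
initialised from the method of moments (`mean = 1/λ₁ + 1/λ₂`,
`var = 1/λ₁² + 1/λ₂²`). A binned least-squares alternative is provided
for comparison with histogram-based fits. Two degeneracies are flagged
rather than silently reported: a sample whose variance is at least its
squared mean (coefficient of variation ≥ 1) is statistically
indistinguishable from a single exponential, as is a fitted lag stage
more than 50× faster than conduction — both raise a `near_degenerate`
flag. Fitted rates are labelled by the convention `λ_lag ≥ λ_cond`: in
the reference fits the lag is the faster stage (mean lag ~1–1.5 ns
against mean conduction ~3.6–8.1 ns), and without such a convention the
two rates are interchangeable.

Event durations (traversal times) are fitted with a log-normal by
closed-form maximum likelihood on the log durations; the implied mean is
`exp(μ + σ²/2)`. All-equal durations give `σ = 0` and a degeneracy flag.
Chloride waiting times are not modelled: chloride events are too sparse
in the systems this package targets for any distributional fit to be
meaningful.

## Lateral fenestrations

Some cations enter the pore sideways, through openings between subunits
in the extracellular wall, rather than down the vestibule mouth. An
event's entry leg is classified lateral if, within a look-back window
before its start (default 5 ns), the ion's radial distance exceeded the
wall threshold while its z lay in the extracellular range. Defaults —
threshold equal to the counting radius (17.3 Å), extracellular range
`z_top` to `z_top + 40 Å` — are configuration values, since the reference
boundary was drawn graphically rather than stated numerically. If the
look-back window precedes the start of the ion's trace the entry cannot
be assessed and the event is labelled axial, with a warning. Fractions of
"all events" use potassium-only denominators: the published total (1,089)
equals the potassium sum of the count table, so that convention is
implemented. Rates are reported per microsecond of pooled time.

## Channel profiles

- **Ion density**: ions counted in 0.5-Å disks of the counting radius,
  sampled every 100 ps (profiles are smoother than event statistics and
  do not need the 10-ps stride), normalized to the bulk expectation
  `c·N_A·V_disk` so bulk reads 1. At 150 mM and r = 17.3 Å the expected
  bulk count is 9.03e-5 × π·17.3²·0.5 ≈ 0.0425 ions per disk.
- **Pore radius**: at each z level, the largest sphere centred in that
  plane that clears every nearby atom (3-D distance minus van der Waals
  radius). The centre is found by a deterministic hill-climb on a 0.1-Å
  grid starting from the pore axis — a documented simplification of the
  Monte-Carlo sphere-maximization approach of dedicated pore-profiling
  tools. The tests compare it against an independent brute-force 2-D grid
  search and require agreement within 0.05 Å on constructed ring
  fixtures. Levels with no atoms within the slab neighbourhood are marked
  unbounded (`NA`).
- **Hydration**: for each in-pore K⁺, water oxygens within 3.52 Å (the
  first-minimum of the K⁺–O radial distribution at 150 mM) are counted,
  and separately the protein oxygens occupying that shell (waters
  replaced by protein coordination). The shell test is strictly
  less-than: ties at the threshold are measure-zero in real coordinates,
  and fixing the rule keeps constructed fixtures deterministic.
- **Residue positions**: z-histograms of all atoms (hydrogens included)
  of selected residue types over all subunits, normalized to unit
  integral per type.
- **Axial diffusion**: mean-square displacement of contiguous in-region
  z-segments, fitted as `MSD = 2Dt` over the first 20 lags. A log-log
  MSD slope above 1.5 indicates drift-dominated (ballistic) motion and
  the estimator refuses to report a coefficient, since under an applied
  field the in-pore motion can be advective. Reported in m²/s with a
  ratio to a configurable free-diffusion reference (default 1.96e-9 m²/s
  for K⁺ in water).

## The synthetic generator

`synthetic_spec()`/`generate_run()` emulate exactly the statistical
structure the analysis assumes, with ground truth attached:

- per-direction entry times drawn from the configured single- or
  double-Poisson process; defaults are the study conditions of the
  conducting open state: TB potassium entries with component mean times
  1 ns (lag) and 3.62 ns (conduction), BT with 1.53 ns and 8.14 ns,
  chloride rates zero;
- log-normal transit durations, default mean 1.24 ns with σ_log = 0.45 —
  chosen so that >99% of transits exceed three 10-ps frame intervals and
  the detector's ≥5-frame recovery guarantee applies;
- a noisy monotone path through the cylinder (linear z drift plus 1-Å
  Gaussian jitter per frame — the simplest shape the detector must
  tolerate, since no path model is prescribed by the processes
  themselves), with permeants clamped inside 70% of the counting radius
  while between the rings;
- optional lateral entrants that dwell outside the wall within the
  extracellular range before turning inward and descending; every
  permeant carries at least 5.5 ns of bulk history before entry so the
  default pathway look-back is always available;
- bulk ions at 150 mM random-walking outside the counting region
  (reflected at the box walls and excluded from the cylinder), which
  exercise the radial gate without ever producing events;
- frames on a regular 10-ps grid, fully reproducible from one seed.

Entrants whose traversal would not finish before the final frame are
still simulated but excluded from ground truth, mirroring the
complete-events rule. The lag of the double-Poisson process is realized
purely in entry-time statistics, not spatially: the generator does not
model ion–ion repulsion near the entry ring, water, protein flexibility,
electrostatics or concentration depletion. Passing tests therefore
demonstrate that the estimators recover the processes they assume — not
that real trajectories follow those processes.

## Problem sizes and runtime choices

The test-suite simulations are sized for a desk machine: ground-truth
recovery uses twenty 25-ns runs, convergence checks use 150–400-ns runs
with few bulk ions, and estimator-recovery checks use 10⁴ waiting-time
draws across 20 seeds (median relative error of both rates below 5% is
asserted). These sizes are the package's validation choices; all scale
linearly if larger checks are wanted.

## Known limitations

- Orthorhombic boxes only; unwrapping is minimum-image per axis.
- Trajectory ingestion covers the columnar trace format and multi-model
  PDB; binary trajectory formats are expected to be converted upstream.
- The pore-radius search is local from the axis: a pore whose centre
  wanders more than a few Å off-axis needs a starting guess.
- Per-segment voltages are assumed common unless supplied per segment.
- No inhomogeneous (time-varying-rate) waiting-time processes, no chains
  of more than two stages, and no modelling of intracellular-domain
  portals.
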