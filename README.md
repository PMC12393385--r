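# permeatr

Ion-permeation analysis for membrane-channel trajectories, written for
studies of cation-selective Cys-loop receptors (the α7 nicotinic
acetylcholine receptor in particular) but applicable to any channel whose
conduction can be described by complete ion traversals of a bounded
cylindrical transmembrane region.

Given per-ion coordinate traces (from molecular-dynamics trajectories or
the package's own synthetic generator), `permeatr`:

- detects **complete crossing events** — an ion counts only if it passes
  from above the extracellular boundary ring, through the counting
  cylinder (default radius 17.3 Å), and out past the intracellular ring
  (a *TB* event), or the reverse (*BT*); residencies truncated by the
  start or end of the run are disregarded;
- converts event tallies into the **single-channel conductance**

  ```
  I = (e / Δt) Σᵢ qᵢ nᵢ ,    G = I / Ve ,
  ```

  where `nᵢ = ±1` is the crossing direction, `qᵢ` the ion charge, `Δt`
  the window length and `Ve = Lz·EF` the membrane voltage, with net
  events `TBK⁺ + BTCl⁻ − BTK⁺ − TBCl⁻`;
- models waiting times between event starts as a **single Poisson
  process** (`f(t) = λe^{−λt}`, rate from counts or from a through-origin
  quantile regression of the order statistics on `−ln(1 − i/N)`) or as a
  **double-Poisson (hypoexponential) process** — an electrostatic entry
  lag chained with a conduction stage,

  ```
  f(t) = λ_lag λ_cond / (λ_lag − λ_cond) · (e^{−λ_cond t} − e^{−λ_lag t}),
  ```

  with mean inter-event time `1/λ_lag + 1/λ_cond`, fitted by maximum
  likelihood (or binned least squares), plus log-normal fits of event
  durations;
- classifies **lateral-fenestration entries** (ions that cross the
  extracellular wall between subunits before descending the pore) against
  ordinary axial entries;
- computes **channel profiles** along the pore axis: inscribed-sphere pore
  radius, bulk-normalized ion density in 0.5-Å disks, first-shell
  hydration (3.52 Å threshold) with protein-oxygen replacement counts,
  residue position densities, and an axial diffusion estimate from the
  in-pore mean-square displacement.

A synthetic trajectory generator with ground-truth event labels makes
every stage testable without MD data, and the printed per-segment count
table of the reference open-state simulations ships as a fixture
(`table1_counts()`).

## Worked example

```r
library(permeatr)

# a 200-ns synthetic run at the default study conditions
spec <- synthetic_spec(duration_ns = 200, n_bulk = 10, seed = 7)
run    <- generate_run(spec)
events <- detect_crossings(run$bundle)
summ   <- summarize_events(events, dt_ns = 200, ve_mv = -102)
render_table1(summ)
#>   Index   `TBK+` `BTK+` `TBCl-` `BTCl-` `Net Events` `Conductance [pS]`
#> 1 1       51     20     0       0       31           243
#> 2 Average 51 ± 0 20 ± 0 0 ± 0   0 ± 0   31 ± 0       243 ± 0

w   <- waiting_times(events, "TB")
fit <- fit_double_poisson(w)
fit
#> <double_poisson_model> rate_lag = 1.003 /ns, rate_cond = 0.3455 /ns, mean wait = 3.891 ns
predicted_events(fit, 200)
#> [1] 51.40585
```

The single segment yields 51 TB and 20 BT potassium crossings; the 31 net
charge translocations over 200 ns at −102 mV correspond to 243 pS. The
hypoexponential fit splits the TB inter-event intervals into a ~1-ns entry
lag and a ~2.9-ns conduction stage, and predicts 51.4 events per 200-ns
window — consistent with the tally it was fitted to.

The published 18-segment count table is reproduced directly from the
fixture:

```r
report <- run_pipeline(table1_counts())
tail(report$table, 1)
#>   Index   `TBK+` `BTK+` `TBCl-` `BTCl-` `Net Events` `Conductance [pS]`
#> 1 Average 44 ± 3 16 ± 1 0 ± 0   0 ± 0   28 ± 3       219 ± 23
```

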