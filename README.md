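# filaclock

Single-cell circadian trace analysis for heterocyst-forming cyanobacterial
filaments.

## The problem

Filamentous cyanobacteria such as *Anabaena* carry a circadian clock in
every cell. Under nitrogen deprivation, single cells spaced every 10–15
cells differentiate into heterocysts — terminally differentiated,
nitrogen-fixing cells that lose their photosynthetic pigments — and the
filament becomes a chain of *vegetative intervals* bounded by heterocysts.
Time-lapse microscopy of a clock-controlled reporter then poses a set of
linked quantitative questions: how synchronized are clocks *within* an
interval versus *across* intervals? Does differentiation initiate at a
preferred clock phase? Do heterocysts keep oscillating, at what period and
amplitude? And is the turnoff of expression along an interval graded by
distance to the heterocysts?

`filaclock` is an R package for analysts of such single-cell fluorescence
time-lapse data. It provides the trace data model, the estimators, and a
synthetic filament-cohort generator with ground truth so every estimator
is validated by parameter recovery.

## The statistics at its core

**Synchronization index.** For cells $i = 1 \dots n$ with traces $f_i(t)$
over one full period, with $\mu(t)$ the mean trace,

$$R = \frac{\langle \mu^2 \rangle - \langle \mu \rangle^2}
           {\overline{\langle f_i^2\rangle - \langle f_i\rangle^2}},$$

the ratio of the temporal variance of $\mu$ to the mean per-cell temporal
variance: $R = 1$ for phase-identical cells, $E[R] \approx 1/n$ for
independent phases. For equal-amplitude sinusoids, $R$ equals the squared
mean resultant length of the phases $\lvert\sum_i e^{i\varphi_i}/n\rvert^2$.

**Changepoint onsets.** The onset of autofluorescence decay in an
incipient heterocyst is the stitching point $t_0$ of a piecewise fit —
constant $c$ before, parabola $c - a(t-t_0)^2$ after — solved by least
squares with a grid search over $t_0$. The same machinery detects
expression turnoff times, whose regression on distance-to-heterocyst gives
the turnoff gradient (h/cell).

**Circadian gating.** Each onset is mapped to the fraction of the cycle
between the two bracketing fitted expression minima (0 = minimum);
histograms carry bootstrap error bars (1,000 resamples) and circular
summaries (mean, resultant length) quantify the width of the gate.

## Worked example

Simulate a nitrogen-deprived cohort (4 filaments, 3 heterocyst-bounded
intervals of 10–15 cells each, sampled every 30 min for 96 h) and run the
full analysis:

```r
library(filaclock)

cfg <- regime_preset("nitrogen_deprived", n_filaments = 4, seed = 1)
sim <- simulate_cohort(cfg)
sim$series
#> <filament_series> 4 filament(s), 193 frames, dt = 0.5 h, 34354 records

report <- analyze_traces(sim$series, seed = 1)
report
#> <analysis_report>
#>   R within intervals 0.770 | across 0.038 (gap 0.731)
#>   noise CV^2: interval 0.161 | filament 0.203
#>   Pearson: neighbours 0.305 | cross-interval -0.140
#>   period: veg 20.95 +/- 0.08 h (n=157) | het 21.42 +/- 0.66 h (n=16)
#>   amplitude ratio veg/het: 4.75
#>   turnoff gradient: -0.003 h/cell (561 records)
#>   gating: 4 events
```

Reading the numbers: contiguous cells inside one interval are highly
synchronized (R = 0.77) while cells from different intervals are not
(R = 0.04, near the independent-phase floor) — the hallmark of the
nitrogen-deprived regime, where the vegetative interval, not the filament,
is the synchronized unit. Neighbour intensities correlate positively while
corresponding cells of adjacent intervals do not. Heterocysts oscillate
with the same ~21 h period as vegetative cells at roughly one-fifth the
amplitude. The turnoff gradient is ~0 here because the default waveform is
an idealized cosine; the delayed-decay waveform
(`oscillator_params(waveform = "rise_hold_decay")`) produces the graded
turnoff.

Individual estimators are available directly, e.g. the decay-onset fit:

```r
tt <- seq(20, 40, by = 0.5)
af <- ifelse(tt <= 30, 1000, 1000 - 4 * (tt - 30)^2)
detect_af_onset(af, tt)
#> <onset_fit> t_on = 30.00 h, pre-level = 1000, curvature = 4 /h^2
#>   SSE = 3.627e-26 over 21 pre + 20 post frames (vertex at stitch)
```

A gating analysis at the scale of a typical experiment (45 differentiation
events) with bootstrap histogram:

```r
ev  <- simulate_gating_events(45, seed = 14)
ph  <- event_phases(ev$traces)          # onset -> own-minima -> phase
gating_summary(ph$phase)                # circular mean ~ gate centre 0.6
hist <- phase_histogram(ph$phase, n_bins = 10, n_boot = 1000, seed = 1)
plot(hist)
```

A thin command-line wrapper is installed at `inst/scripts/filaclock`
(`simulate`, `analyze`, `recover` subcommands over config/traces files).

## Package tour

| area | functions |
|---|---|
| data model | `filament_series()`, `read_traces()`, `write_traces()`, `intervals_at()`, `resolve_lineages()` |
| simulator | `sim_config()`, `regime_preset()`, `simulate_cohort()`, `simulate_gating_events()`, `read_config()` / `write_config()` |
| synchrony | `sync_index()`, `synchrony_contrast()`, `expression_noise()`, `neighbor_pairs()`, `interval_pairs()`, `pearson()`, `pick_quarter_times()` |
| oscillation | `detect_minima()`, `estimate_period()`, `cycle_windows()`, `amplitude()`, `amplitude_ratio()`, `align_by_event()`, `detect_turnoff()`, `turnoff_gradient()` |
| differentiation timing | `detect_af_onset()`, `fit_const_parabola()`, `onset_phase()`, `phase_histogram()`, `gating_summary()`, `event_phases()` |
| pipeline | `analyze_traces()`, `simulate_to_files()`, `recover_cohort()`, `write_report()` |

See the methods vignette
(`vignettes/filament-circadian-analysis.Rmd`) for the models, parameter
defaults, and the reasoning behind every numerical choice.
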