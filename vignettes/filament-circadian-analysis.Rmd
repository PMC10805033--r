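---
title: "Methods: circadian trace analysis in heterocyst-forming filaments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian trace analysis in heterocyst-forming filaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filaclock)
```

## The biological setting

Filamentous cyanobacteria such as *Anabaena* run a free
circadian clock in every cell. Under nitrogen-replete growth all cells are
photosynthetic ("vegetative") and clock phases cohere along whole
filaments. When combined nitrogen is withdrawn, roughly every 10th--15th
cell differentiates into a heterocyst — a terminally differentiated,
micro-oxic nitrogen-fixing cell that loses its photosynthetic pigments —
partitioning the filament into *vegetative intervals* bounded by
heterocysts. `filaclock` implements the single-cell time-lapse analyses
relevant to this regime:

* the **synchronization index R** of cell groups, and its contrast between
  contiguous within-interval groups and cells drawn from different
  intervals;
* **expression noise** (squared coefficient of variation across cells) and
  the neighbour / cross-interval **Pearson correlation** structure;
* circadian **minima, period and amplitude** estimation from reporter
  traces;
* detection of the **onset of autofluorescence (AF) decay** that marks
  incipient differentiation, and its mapping to a **clock phase** with
  bootstrap histograms (circadian gating);
* the **sequential turnoff** of expression graded by a cell's distance to
  its bounding heterocysts;
* a **synthetic filament-cohort generator** with ground truth, standing in
  for microscopy data in all tests.

## The synchronization index

For cells $i = 1 \dots n$ with intensity traces $f_i(t)$ sampled over one
full oscillation period, with $\mu(t)$ the across-cell mean trace,

$$R \;=\; \frac{\langle \mu^2 \rangle - \langle \mu \rangle^2}
               {\overline{\langle f_i^2\rangle - \langle f_i\rangle^2}},$$

where $\langle\cdot\rangle$ is a time average over the window and the
overline averages over cells. $R = 1$ for identical traces; for $n$
independent-phase oscillators $E[R] \approx 1/n$. Two numerical choices
matter:

* **Variance estimator.** The sample variance ($n-1$ denominator) is used
  in numerator and denominator alike. Any consistent estimator cancels in
  the ratio's scale and preserves the convexity bound $R \le 1$; mixing
  estimators would not.
* **The "full period" window.** Each contiguous group's window is
  delimited by two consecutive fitted minima of the *group-mean* trace.
  For the separated group (one centre cell per interval, ties broken
  toward the left heterocyst) a mean trace of dephased cells has no
  reliable minima, so one *common* window — the median of the
  contiguous-group windows — is used. For equal-amplitude sinusoids over
  an integer number of periods, $R$ is window-start invariant, which makes
  the common window a neutral choice.

For sinusoids of equal amplitude sampled densely over whole periods, $R$
equals the squared mean resultant length of the phases,
$\lvert \sum_i e^{i\varphi_i}/n \rvert^2$; the test suite verifies this
closed form and the agreement of the implementation with a literal,
loop-written transcription of the ratio (to $10^{-12}$ on $10^4$ random
trace sets).

No detrending or smoothing is applied before computing $R$; inputs are the
lineage-resolved concentration traces (below).

## Trace model and lineage resolution

Traces are long-format CSV records (one row per cell per frame) with a
constant sampling step, 0.5 h by default. Position along the filament is
re-assigned per frame; lineage links (`cell_id`/`parent_id`) are the
stable keys. Because total per-cell fluorescence halves at division,
statistics over a cycle would be corrupted by sawtooth artefacts; the
default `"concentration"` policy divides intensities by cell area before
splicing mother to first daughter (smaller position index), so divisions
cause no jump beyond partitioning and measurement noise. `"first_daughter"`
(raw totals) and `"sum"` (whole-subtree totals) are available for
sensitivity checks. Whether published synchrony values were computed on
totals or concentrations is not documented; concentration is this
package's default.

## Minima, period, amplitude

Candidate minima are local minima of a 5-frame moving mean, kept at least
half an expected period apart (deeper minima win). Each candidate is
refined on the **raw** data in a window of ±20% of the expected period by
two fits: a single parabola (refined time = vertex) and a value-continuous
piecewise *parabola-then-line* (refined time = stitch point). The
lower-SSE fit wins; parameter-count penalties are ignored (3 vs 4
effective parameters; the piecewise fit is only admissible when its fitted
curve actually attains its minimum at the stitch — parabola falling into
it, line non-decreasing after it — otherwise its stitch would not estimate
a minimum at all). A refined time escaping its fit window rejects the
candidate. The ±20% window is this package's convention; smoothing is used
for candidate detection only.

Per trace, the period is the mean spacing of consecutive minima; cohort
summaries are mean ± SE over traces. Amplitude is half the peak-to-trough
range within one cycle window; because the range statistic is biased
upward by noise, the pipeline's amplitude-ratio summary applies a 5-frame
moving mean first (the `amplitude()` default remains the raw range).

## Onset of autofluorescence decay

The onset estimator models the AF trace as a constant $c$ up to a stitch
time $t_0$ and a decaying parabola $c - a\,(t-t_0)^2$ afterwards, with
continuity and (by default) zero slope at the stitch; a variant with a free
linear term is available (`vertex_at_stitch = FALSE`). The stitch is
grid-searched over frames and half-frames, then refined by a continuous
local optimisation around the grid winner (the SSE is smooth in $t_0$
between samples, so an off-grid changepoint is recoverable beyond the
half-frame resolution); each candidate is solved in closed form by linear
least squares and the global SSE minimiser wins, ties toward the earliest
stitch.

Three details make the search well-posed:

* **One common analysis window.** "Initial stages of the decay" is
  operationalised as all frames up to 4 frames past the point where the
  smoothed signal first falls below half its starting plateau. Scoring
  every candidate on the *same* frames keeps SSEs comparable; windows
  chosen per candidate would favour candidates that see only flat data.
* **Stop at the signal's minimum.** The window never reaches past the raw
  signal's minimum: frames beyond it (a following rise, or a clipped
  floor) are not part of the decay being modelled, and their residuals
  against a still-falling parabola would dominate the SSE and drag the
  stitch early. A signal whose minimum sits at the start has nothing
  decaying and raises the no-onset error.
* **Degeneracy guard.** A candidate whose fitted decay over the window is
  numerically negligible ($a\,s_{\max}^2$ below $10^{-6}$ of the plateau)
  is rejected; on a noiseless flat-then-parabolic trace the true
  breakpoint is then recovered exactly, and the estimator is
  scale-equivariant by construction.

The same machinery, applied to the post-peak segment of a GFP trace
(relaxed minimum segment lengths), yields expression *turnoff* times; the
turnoff-delay gradient is the least-squares slope of turnoff time against
distance to the nearest bounding heterocyst, computed within one interval
and cycle, or pooled across groups after within-group centring (absolute
times of dephased intervals are not comparable).

## Clock phase of differentiation

The onset phase is the elapsed time since the preceding fitted expression
minimum divided by the spacing of the two bracketing minima — a cycle
fraction in $[0,1)$. Histograms use equal-width bins on $[0,1]$ (default
10, so that onset/minima errors of up to ~1 h stay below one bin at a
~21 h period), heights normalised as densities, and per-bin standard
errors from 1,000 bootstrap resamples under a fixed seed (the caller's RNG
state is preserved). `gating_summary()` reports the circular mean and mean
resultant length of $2\pi\cdot$phase. Events are restricted to cycles 2--4
by default (the observation window of the differentiation-timing
analysis); `cycles = NULL` lifts the restriction. Bracketing minima come
from the differentiating cell's own expression trace.

## The synthetic generator

`simulate_cohort()` draws, per filament, a heterocyst-bounded layout of
vegetative intervals (lengths uniform on 10--15 cells) and per-cell
oscillators

$$g_i(t) = \bigl(B + A_i\,w(2\pi t/T_i + \phi_j + \epsilon_i)\bigr)\,
           E_i\,\eta_i(t),$$

with interval phase $\phi_j$ (independent uniform per interval under
nitrogen deprivation; one cohort-wide draw under replete conditions),
per-cell jitter $\epsilon_i$, static extrinsic factor $E_i$, and lognormal
per-frame measurement noise $\eta_i(t)$ (both noises mean-one).
Defaults and their reasoning:

| parameter | default | reasoning |
|---|---|---|
| period mean / sd | 21 h / 1 h | observed periods cluster near 21 h; modest per-cell variability |
| amplitude (veg) / baseline | 1000 / 1500 a.u. | high-amplitude reporter, intensities stay positive |
| heterocyst amplitude ratio | 5 | heterocyst oscillations about five-fold smaller |
| within-interval phase sd | 0.5 rad | gives within-interval $R \approx 0.7$--$0.8$, the qualitative "high synchrony within" regime; no quantitative dispersion is published |
| measurement / extrinsic CV | 0.05 / 0.10 | total trace noise vs static cell-to-cell scale |
| sampling step | 0.5 h | one image every 30 min |
| events per interval per cycle | 0.15 | a handful of events per multi-interval cohort over 2--4 cycles |
| gate centre / sd | 0.6 / 0.05 cycles | a narrow gating window in the second half of the cycle |
| AF decay curvature | 20 a.u./h² | AF halves in ~7 h, pigment loss over roughly half a day |
| turnoff delay | 0.5 h per cell | decay delayed with distance from the heterocyst |
| suppression radius | 2 cells | no new event adjacent to an existing heterocyst |

The waveform is a cosine by default (enabling closed-form checks); the
`rise_hold_decay` waveform (linear rise over 40% of the cycle, hold 10%,
parabolic decay 50%) is the realism mode whose decay segment is delayed by
`turnoff_delay_per_cell × distance`, compressing the decay so minima stay
aligned — this is what the turnoff-gradient recovery exercises.
Differentiation events are placed so the cell's clock phase at onset is
wrapped-normal around the gate centre; with a zero-width gate the event is
snapped to the nearest frame with a warning. After the onset the
oscillation amplitude ramps down to the heterocyst level over ~3 h
(prompt promoter repression; a step transition would plant an artificial
edge near the next minimum's fit window, and a slow ramp would tilt it).
Heterocysts inherit the phase of the adjacent interval, standing in for
inheritance from the progenitor's lineage. Divisions are off by default
(keeping variance structure clean); when enabled, areas grow exponentially,
divide in half, and totals partition binomially.

Reproducibility: one root seed; per-filament child seeds are derived by
fixed integer arithmetic, so cohorts are bit-reproducible and stable under
subsetting.

**What the generator does not emulate.** No mechanistic Kai oscillator or
HetR/PatS/HetN patterning dynamics; no filament fragmentation, no
photobleaching drift, no segmentation/tracking errors, no spatially
correlated illumination noise. Passing recovery tests therefore
demonstrates estimator correctness under the stated statistical structure,
not robustness to every artefact of real microscopy data.

## Design decisions on open points

* **Cross-interval pair sampling.** Pair scatter data are taken at one- and
  three-quarters of the cycle, when cell-to-cell fluctuations are maximal.
  The pipeline uses quarter times of a *common* reference cycle (median of
  the per-interval fitted cycles): per-interval quarter times would catch
  every interval at mid-cycle and erase the between-interval spread the
  statistic is designed to expose.
* **Which cell differentiates** is drawn uniformly among interval cells
  beyond the suppression radius; position selection is not modelled.
* **Noise-limited phase precision.** After the onset the oscillation is
  five-fold smaller, so the *following* bracketing minimum is intrinsically
  harder to localise: at 5% per-frame noise its error is ~1.5--2 h,
  propagating to ~0.1 cycle phase errors for single events. The
  cohort-level gating summaries (circular mean, histogram) remain accurate
  at that noise because single-event errors average out; per-event
  precision at the ~1 h level requires imaging-grade (~2%) per-frame
  noise, and the recovery tests state which regime they use. The
  turnoff-gradient recovery likewise runs at 2% per-frame noise: at 5%,
  the shallow decays of near-heterocyst cells acquire a larger early
  stitch bias than the steep, compressed decays of mid-interval cells,
  attenuating the fitted slope by roughly 15% — a property of the noise
  condition, not of the configured delay.
* **Degenerate inputs.** Constant traces are zero-variance errors for $R$;
  monotone traces yield no minima (empty result, not an error) and no
  onset; single-cell intervals yield empty pair sets; gradients need two
  distinct distances. All error conditions are classed
  (`filaclock_*_error`) for programmatic handling.

## Problem sizes

The default test and acceptance runs use cohorts of 2--4 filaments × 3
intervals (~40 cells, 193 frames, ≈ 15,000 records each), 500-replicate
onset/minima recovery, 45--60 simulated gating events across 50 seeds, and
20-seed regime contrasts — sizes chosen so the full suite exercises every
statistical claim at meaningful power while completing in minutes on one
CPU.

## Limitations

Minima refinement assumes an approximately parabolic trough within ±20% of
a period; strongly sawtooth-shaped cycles would be better served by the
piecewise fit alone. The onset model assumes a genuinely flat pre-onset
plateau; a drifting baseline biases the stitch. The synchronization
contrast assumes intervals of at least 8 cells are available. None of the
estimators model photobleaching or focus drift; apply appropriate
corrections upstream.
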