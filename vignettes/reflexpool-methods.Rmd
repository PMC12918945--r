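---
title: "Simulating motor neuron pools and estimating H-reflex amplitudes from PSF and PSTH cusums"
author: "reflexpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating motor neuron pools and estimating H-reflex amplitudes from PSF and PSTH cusums}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reflexpool)
```

## The problem

The monosynaptic Ia (H-) reflex is widely used to probe the input-output
behaviour of spinal motor neurons in humans. With surface-EMG
decomposition, tens of motor units can be followed simultaneously during
a stimulation protocol, and each unit's reflex response can be quantified
from its discharge times by one of two classical estimators:

* the **peristimulus time histogram (PSTH)** — spike counts in bins
  aligned to the stimulus; its cusum rise measures the *extra count per
  stimulation*;
* the **peristimulus frequencygram (PSF)** — each discharge contributes
  its instantaneous rate (the reciprocal of the preceding interspike
  interval); its cusum rise measures the evoked rate excess in Hz per
  stimulation.

Single-unit reflex amplitudes vary widely even at fixed stimulus
intensity. This package provides a controlled simulation environment to
study how that variability depends on the background discharge rate (DR),
the interspike-interval variability (CoV of the ISI, a proxy for total
membrane noise), the activation level, and the motor neuron (MN) size
distribution — and how much of what we read from a reflex estimate is a
property of the estimator rather than of the neuron.

## The motor neuron pool model

Each cell is a two-compartment conductance-based model: an active soma
carrying Na^+^, fast K^+^ and slow K^+^ (AHP) currents described by four
gating variables, electrotonically coupled to a passive dendrite. The
gating rate "functions" are threshold-switched constants (a pulse-based
scheme): above the gating threshold the activation variables relax
exponentially towards 1 and inactivation towards 0, below it the reverse.
This keeps every gating update exact (Rush–Larsen), and the membrane
potentials are advanced with a semi-implicit Euler step, which is
unconditionally stable. The integration step is fixed at
`dt = 0.05` ms — twenty samples per EPSC rise time. Spikes are detected
as upward crossings of 0 mV (absolute scale; rest is −70 mV) with a 1 ms
lockout, and spike times are linearly interpolated within the step, so
they are continuous quantities rather than grid multiples.

All constants of the canonical cell are frozen in one named vector
(`reflexpool:::.mn_canonical`) and printed below:

```{r canonical}
reflexpool:::.mn_canonical
```

**The pool is a one-parameter family of size-scaled copies.** For a cell
of size factor $s$, every conductance and capacitance of the canonical
cell is multiplied by $s$. Dividing the membrane equation by $s$ shows
that such a cell driven by a current $I$ behaves *exactly* like the
canonical cell driven by $I/s$: input resistance is proportional to
$1/s$, rheobase to $s$, and the f–I curve is a horizontally stretched
copy. An exponential input-resistance profile across the pool (the
classical skew towards many small, low-threshold cells) is therefore
equivalent to an exponential rheobase profile, and recruitment in a ramp
follows the size principle by construction.

### Calibration

Two printed facts anchor the default 200-cell pool: about 44.5 % of the
pool fires at the lowest mean drive (4 nA) and about 98.5 % at the
highest (16 nA). With the exponential profile this fixes the exponent,
$k = \log(4)\cdot 199/108 \approx 2.555$, so that the 44.5 % anchor
(index 89) and the 98.5 % anchor (index 197) sit exactly a factor four
apart in drive. The remaining degree of freedom — where the profile sits
on the current axis — is set by one measured number: the canonical drive
at which the cell's *noise-on* discharge rate crosses the 7 Hz
sustained-firing bound (1.183 nA, measured once over long noise-on
simulations and frozen). Index 89 is placed exactly at that point for a
4 nA drive. "Fires" is operationalized as a mean rate of at least 7 Hz
over a 10 s noise-on segment — the same bound as the simulated-mode
inclusion filter, which is what makes "included" and "recruited" counts
coincide at the lowest level.

```{r pool}
pool <- mn_pool(200)
summary(pool)
```

### What the canonical f–I curve does and does not reproduce

The chosen AHP parameters give a noise-on onset rate near 7 Hz and a
concave primary range; the smallest cell reaches ~36 Hz at the highest
drive, so the included pool's discharge rates span roughly 7–36 Hz
across the seven activation levels, close to the ~7–39 Hz span reported
for this kind of pool. A genuine limitation: in this
single-slow-conductance family, a ~7 Hz onset rate cannot be combined
with a *shallow* (~1 Hz/nA) primary range. Our smallest cell therefore
reaches ~20 Hz already at the lowest activation level, where a pool with
a shallower primary range would sit near 10 Hz. Consequently the
lowest-level DR spread is wider than in the reference setting, and
statistics that depend on it (level-1 amplitude dispersion and the sign
of the level-1 amplitude–DR correlation) deviate; the effect is
discussed where those analyses are presented.

## Synaptic input

Each neuron's soma current is the exact sum of three components:

1. **Common drive** — a constant mean (the activation level; the seven
   default levels are 4, 6, …, 16 nA, the paperless partition of the
   4–16 nA range into seven equal segments) plus zero-mean Gaussian noise
   band-pass filtered to 15–35 Hz (fourth-order Butterworth applied
   forward–backward) and rescaled *after* filtering so its SD is 20 % of
   the mean. One realization is shared by the whole pool within a level
   and redrawn across levels (each level is an independent experiment).
2. **Independent noise** — per-neuron zero-mean Gaussian noise low-pass
   filtered below 100 Hz (second-order Butterworth, forward–backward),
   scaled to carry 20 % of the total noise *variance*: its SD is
   $0.2\mu\sqrt{0.2/0.8} = 0.1\mu$. Variance shares add linearly for
   independent processes, which is why the share is defined on variances.
3. **Stimulus train** — an EPSC $6\,\mathrm{nA}\cdot(t/1\,\mathrm{ms})
   \exp(1 - t/1\,\mathrm{ms})$ truncated at 40 ms (where it has decayed
   to ~5·10⁻¹⁵ of its peak), delivered 200 times with Gaussian
   inter-stimulus intervals of 1000 ± 100 ms, truncated below at 200 ms
   so stimuli can never overlap an EPSC support. The same current is
   injected into every cell (uniform afferent distribution), so larger
   cells see a proportionally smaller effective input.

Noise is synthesized on a 1 ms grid (1 kHz), filtered and rescaled
there, and linearly interpolated onto the integration grid. Both
components are band-limited below 100 Hz, a tenth of the 500 Hz
synthesis Nyquist, so nothing is lost; designing the same 15–35 Hz
band-pass directly at 20 kHz would put the normalized band at
0.0015–0.0035 of Nyquist, where IIR designs are numerically fragile.
This also makes long pool runs cheap. Every random stream is derived
deterministically from (master seed, level, neuron), so studies are
exactly reproducible.

## Reflex estimation

`reflex_fit()` builds the PSF or PSTH of one unit in a window around
each stimulus — 300 ms pre / 150 ms post in simulated mode, 200 ms pre /
100 ms post in experimental mode — with 1 ms bins by default (the bin
width resolves the ~10 ms reflex with ≥10 bins and is configurable). The
cusum subtracts the mean pre-stimulus bin value and accumulates; by
construction it returns exactly to zero at the last pre-stimulus bin.

* **Significance (error box):** the threshold is 100 % of the maximum
  absolute pre-stimulus cusum deflection from zero; an excitatory
  response is significant only if the post-stimulus cusum *strictly*
  exceeds it (only positive exceedance is tested — the stimuli are
  excitatory).
* **Onset/end (automated detector):** the slope threshold is the largest
  absolute pre-stimulus forward difference of the cusum; the reflex is
  the first contiguous run of post-stimulus bins exceeding it. In
  simulated mode the onset must fall within 15 ms of the stimulus (no
  conduction delays are modeled); experimental latencies include
  conduction and are not bounded.
* **Amplitude:** the cusum difference between the reflex onset and the
  *first turning point before the peak*, implemented as the first local
  maximum of the cusum at or after the end of the above-threshold run
  (earliest bin wins on plateaus). The amplitude is normalized by the
  number of stimuli: counts/stimulus for the PSTH (the extra-discharge
  probability), Hz/stimulus for the PSF.
* A unit with no above-threshold run returns a non-significant estimate
  with zero amplitude rather than an error.

The estimator is validated against surrogate ground truth rather than
against the simulator: `surrogate_train()` generates Gaussian-renewal
trains with prescribed DR and CoV (ISIs redrawn while below 10 % of
their mean), and `inject_reflex()` either inserts an extra discharge at
a fixed latency with a per-stimulus probability (recording exactly which
stimuli fired) or advances the next natural discharge (a phase reset).
The central oracle property — PSTH normalized amplitude equals injected
count / stimulus count within one bin's discretization — is exercised in
the test suite at several probabilities.

```{r oracle}
stim <- stimulus_train(100, seed = 2)
tr <- surrogate_train(dr = 10, cov = 15,
                      duration = max(stim) + 500, seed = 3)
inj <- inject_reflex(tr, stim, prob = 0.5, latency = 5, seed = 4)
fit <- reflex_fit(inj$train, stim, method = "psth")
c(truth = inj$n_injected / 100, coef(fit)["amplitude_norm"])
```

## Population analyses

Units failing the inclusion filter (simulated mode: background DR — mean
rate over the 500 ms pre-stimulus windows — below 7 Hz, or CoV of the
ISI above 30 %) are excluded; ISIs overlapping the first 100 ms after a
stimulus are excluded from the CoV so it indexes background membrane
noise, not the evoked response. Units with non-significant reflexes are
excluded from regressions and ECDF comparisons.

Amplitudes are z-scored (population SD) before regression so slopes are
comparable across levels; standardization leaves R² and p-values
unchanged. Correlations with DR and with recruitment threshold use a
one-tailed Pearson test in the expected direction, with the conventional
qualitative bands for |ρ| (poor < 0.3, fair 0.3–0.5, moderate 0.5–0.8,
strong ≥ 0.8). Amplitude dispersion per level is the CoV (population SD
/ mean) among significant units.

For the pool-composition analysis, `mn_pool(composition = f)` scales the
resistance-profile exponent by `f` ∈ {0.5, 0.75, 1, 1.25, 1.5} while
keeping the smallest cell fixed: `f < 1` compresses the pool towards
high resistances (proportionally more small cells), `f > 1` towards low
resistances (more large cells). `amplitude_ecdf()` compares the
empirical cumulative amplitude distributions across pools simulated with
shared stimulus and noise seeds and reports signed dominance shifts, so
the direction of a composition bias can be read off the PSF ECDFs.

## Study sizes and numerical choices

* Default study: 200 neurons × 7 levels × 200 stimuli (~200 s of
  biological time per neuron and level). The test suite reproduces the
  headline statistics from one full default study at a fixed seed; the
  desk-scale property tests use 30–50-neuron pools and 12–60 stimuli.
* dt = 0.05 ms everywhere; noise grid 1 ms; bin width 1 ms.
* Rheobase bisection: tolerance 5 pA, bracket doubled until firing,
  sustained firing = ≥2 spikes after a 1.5 s transient.
* Degenerate inputs are errors, not guesses: empty stimulus lists,
  windows that the bin width does not tile, zero-variance vectors in
  z-scores and correlations, mismatched sampling grids.
* Ties in peak finding resolve to the earliest bin; determinism is a
  hard contract (same seed, same configuration → bit-identical spike
  times).

## Known limitations

* No persistent inward currents, spike-threshold accommodation within
  the ISI, or inhibitory stimuli; inputs are effective synaptic
  *currents* (no conductance-based synapses), and the afferent input is
  uniform across the pool by design.
* The f–I family constraint discussed above: the level-1 DR spread is
  wider than the reference setting, which inflates low-level amplitude
  dispersion and flips the (weak) level-1 PSF amplitude–DR correlation.
* PSF amplitudes scale like (trigger probability) × (instantaneous rate
  of the triggered discharges): the cusum rise carries the full
  instantaneous rate of each evoked discharge, with the compensating
  deficit appearing only after the turning point. Reported PSF
  amplitudes are therefore sensitive to where in the interspike interval
  the stimulus can trigger a discharge, i.e. to the AHP trough shape —
  more so than PSTH amplitudes, which count discharges regardless of
  their timing relative to the previous spike.
* The surrogate generator emulates stationary renewal discharge with an
  optional instantaneous response; it does not emulate slow drifts in
  drive, recruitment/derecruitment during a trial, or decomposition
  errors, so passing the oracle tests validates the estimator's
  bookkeeping, not its robustness to such artefacts.
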