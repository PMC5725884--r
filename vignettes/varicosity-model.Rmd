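---
title: "The histamine varicosity model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The histamine varicosity model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histasim)
```

## The model and its assumptions

The package simulates one histamine varicosity and its immediate
surroundings as a well-mixed, ten-compartment mass-balance system.
Histidine enters the blood compartment at a dietary rate `HT_in`
(424 µM/hr at baseline), is transported into the cytosol by a two-step
carrier lumped into one Michaelis–Menten term (Km 1000 µM, Vmax
4680 µM/hr), and either feeds a general-purpose histidine pool or is
decarboxylated to histamine. Cytosolic histamine is packaged into
vesicles (with a linear backleak), catabolised by HNMT, or leaks to the
extracellular space. Vesicular histamine is released at a rate
proportional to the firing rate and to the vesicular content.
Extracellular histamine is cleared by a putative reuptake transporter
(Km 2 µM — no specific transporter has been identified, but one must
exist or repeated firing would empty the vesicular pool), by glial
uptake and catabolism, and by a small removal term; it also binds H3
autoreceptors. Receptor occupancy drives a minimal transduction cascade:
bound receptors activate the G-protein subunit quadratically, the active
subunit activates the RGS protein quadratically, and active RGS
deactivates the subunit — a delayed negative feedback that suppresses
both release and synthesis through the linear factor
`inhib(G*) = 2.4015 − 2.45 G*`.

Key structural assumptions, inherited deliberately:

* **Arbitrary transduction units.** Effective surface concentrations of
  receptors and transducers cannot be estimated, so `G*`, `T*` and `bHA`
  carry arbitrary units; the totals obey `G + G* = g0`, `T + T* = t0`,
  free + bound receptors `= b0`.
* **Bound histamine is not debited from eHA.** Receptor-bound
  extracellular histamine is assumed small relative to the extracellular
  pool, so the `eHA` equation does not subtract it.
* **Firing enters by numeric value.** Firing is in spikes/s while all
  rate constants are per hour; the release coefficient `a2` absorbs the
  conversion. The release term is therefore reproduced literally, not
  "corrected".
* **One histidine transporter.** The cytosolic-histidine equation names
  a glial-looking transport flux, but no glial histidine pathway exists
  anywhere in the model; it is treated as the same neuronal transport
  flux that leaves the blood equation, so blood loss and cytosolic gain
  balance exactly.

## Parameters

`ha_params()` holds the full set: fourteen first-order coefficients
(`a1`–`a14`), the Vmax/Km pairs, pool totals, baseline rates and the
inhibition line, all validated (Km and totals strictly positive, Vmax
allowed to be zero so synthesis blockade is expressible). Two
parameters deserve comment:

* **The derived totals `g0 = 1`, `t0 = 60`.** These totals are not
  measured anywhere; they are pinned by requiring the three transduction
  equations to balance at the reference equilibrium
  (`bHA = 2.94`, `G* = 0.6945`, `T* = 12.69`, `eHA = 1.39`, `b0 = 10`).
  Solving the receptor-binding balance gives
  432·1.39·(10 − 2.94) ≈ 1440·2.94 (0.1% residual), and substituting
  into the two remaining balances yields g0 ≈ 1.00 and t0 ≈ 60.0.
  `verify_derived_totals()` recomputes all three residuals; the test
  suite asserts they stay below 2%, the precision of the rounded
  reference values.
* **The inhibition variants.** The default line (2.4015, 2.45) and the
  strong line (7.645, 10) intersect at the tonic point
  (G* = 0.6945, inhib = 0.7), so the variant switch alters feedback
  gain without moving the steady state. Both lines go negative for
  large `G*` (beyond 0.980 and 0.7645 respectively); `inhib()` clamps at
  zero so release and synthesis can never run backwards, and
  `simulate_varicosity()` reports how many output points were affected
  (the clamp does engage during strong-variant stimulation). Whether the
  original analyses clamped is unknown; clamping is the only choice that
  preserves non-negativity.

## Protocols and integration

Firing and dietary-input protocols are piecewise-constant step
functions with half-open `[start, end)` segments: at a breakpoint the
new rate applies. The integrator (`deSolve::lsoda`, relative tolerance
1e-8, absolute 1e-10) is restarted at every breakpoint, so steps are
resolved exactly instead of being smeared by step-size control. The
fast receptor-binding kinetics (`a13·eHA·b0` is thousands per hour,
i.e. time constants of seconds) make the system stiff during
stimulation; `lsoda` switches methods automatically. Output states are
checked against non-negativity and the conservation caps on every grid
point, with sub-tolerance solver noise clamped and anything larger
raised as an error.

Steady states are solved in two stages: a 500 h integration from a
positive, order-of-magnitude-agnostic guess (all concentrations 1 µM,
transduction variables at half their totals), then Newton polishing of
`rhs = 0`. The stages must agree to 1e-4 relative on every component
and the polished root must satisfy max |rhs| < 1e-6 µM/hr. A
randomised-start probe (`steady_state_probe()`, log-uniform draws over
[1e-2, 1e3] µM, fixed seed 42) confirms a unique attracting equilibrium
in the physiological range: ten starts agree to better than 0.1%.

## The experiments

**Half-life** (`run_half_life()`): `vmax_htdc` is set to zero at t = 0
from the steady state and the system integrated for 12 h on a 0.005 h
grid (well below the 0.01 h readout resolution the half-life
interpolation needs). Each compartment's half-life is the first linear
interpolated crossing of half its initial value; compartments that
never cross are reported censored and block the weighted summary. Mass
fractions use volume fractions (0.30, 0.10, 0.20, 0.40) for
(cytosol, vesicles, extracellular space, glia). The package computes
half-lives (1.43, 1.08, 1.32, 1.97) h and a brain half-life of 1.12 h —
the vesicular compartment dominates (≈92% of mass) and empties fastest,
because falling eHA withdraws the autoreceptor brake and raises release
per spike.

**Histidine loading** (`run_histidine_load()`): input raised from 424
to 6700 µM/hr between t = 1 h and t = 2 h. Outputs are fold changes of
two indices: a histidine index weighting blood at 20% against cellular
histidine at 80%, and a histamine index with volume fractions
(0.4, 0.1, 0.2, 0.3). The cellular histidine term is taken as the
plain mean of cytosolic histidine and the histidine pool: both are
intracellular and nothing separates their volumes, so equal weighting
is the least-informative choice; the weighting is an argument for
sensitivity analysis. Note the two experiments deliberately use
*different* volume-fraction sets — each analysis keeps its own
published convention rather than harmonising them.

**Dietary interventions** (`run_dietary()`): input scaled by 1/3 and
8/3 for two weeks (336 h). The reported value is the root-polished
steady state under the scaled input; the 336 h integration confirms
settling (both values are kept when they differ by more than 0.5%).
The histamine response is monotone in the diet factor and strongly
sub-proportional — the saturable enzymes, not the autoreceptor, do most
of that compression.

**Stimulation** (`run_stimulation()`): control raises firing to
25 sp/s on [5, 8) s and 14 sp/s on [8, 9) s; the antagonist paradigm
reduces `b0` from 10 to 4 (receptor blockade) with slightly lower drive
(22/11 sp/s), and starts from the reduced model's own steady state —
the drug acts tens of minutes before the recording, long enough to
re-equilibrate. Output is on a 10 Hz grid, the sampling rate of FSCV,
both absolute and baseline-relative (FSCV reports only changes from
baseline). The `initial` argument supports acute perturbations instead:
the receptor-blockade monotonicity property is tested by clipping bound
receptors to the new total and stimulating immediately, because at
`b0 = 1` the reduced model has no stable resting state to start from.

**Polymorphisms** (`run_polymorphism()`): Vmax rescaling with the
steady state re-solved. The HNMT deficit applies to both the neuronal
and glial enzyme by default — they are the same gene product — with
`glial_hnmt = FALSE` exposing the neuronal-only reading (the package
computes +29.7% and +27.7% eHA for a 26% activity loss under the two
readings). The HTDC deficit (−67% activity) lowers eHA by 59.7% under
default feedback and only 33.5% under the strong variant: the
homeostasis ordering that motivates the strong line.

**Oscillation variant** (`run_oscillation_variant()`): strong
inhibition plus speed multipliers on the three transduction equations.
Multiplying a right-hand side rescales its kinetics but not its zeros,
so the steady state is untouched. Which two equations received the ×5
and which the ×0.3 is ambiguous, so `scan_oscillation_multipliers()`
evaluates the three distinct assignments; only
(G* ×5, T* ×5, bHA ×0.3) yields at least three detected cycles, with a
24.7 s period — nearest the expected ~25 s — and that assignment is the
frozen default. The ringing is damped (amplitude roughly halves per
cycle, the `decay_ratio` the runner reports), so "oscillatory" is
defined operationally: at least three peaks above a 2% prominence floor
within the 100 s window, matching what a 100 s recording can
distinguish. Under nominal parameters the same stimulation produces no
qualifying cycles.

## Trace analysis choices

Half-life extraction is first-crossing with linear interpolation —
robust to the non-exponential early decay that an exponential fit would
distort. Period detection finds strict local maxima (ties broken toward
the first sample of a two-point plateau, which arises whenever the
period is not a grid multiple), requires prominence of at least 2% of
the trace range relative to adjacent minima, and reports the median
peak-to-peak interval — the median resists the drifting first cycle
right after stimulation — cross-checked against the autocorrelation
maximum. Both readouts are invariant under affine transforms of the
trace values.

The pseudo-FSCV fixture generator resamples eHA to 10 Hz, subtracts
baseline and adds seeded Gaussian noise. It emulates the sampling rate
and baseline-relative convention of the measurement only: no electrode
adsorption kinetics, drift, or correlated noise. Tests passing on these
fixtures show the analysis pipeline is correct on clean, white-noise
traces, not that it is robust to real electrochemical artefacts.

## Numerical edge cases

* All-zero states are legal inputs to the flux functions: every
  saturable velocity vanishes, leaving only the constant dietary inflow
  and the blood-histidine setpoint exchange.
* Cutting dietary input entirely does not empty the system: the
  setpoint term imports histidine from body stores until transport
  balances it, and histamine settles at a low but non-zero fixed point.
* `b0` well below its resting occupancy removes the feedback brake and
  sends extracellular histamine far above the reuptake Km; the reduced
  model can lose a stable resting state altogether, which is why acute
  (rather than re-equilibrated) blockade is the well-posed comparison
  there.
* The mass-balance audit is exact by construction: the ODE right-hand
  side is assembled from the same signed flux vector that
  `flux_balance()` reports, so the audit can only fail if the
  decomposition itself is wrong.

## Problem sizes

The defaults keep every analysis at desk scale: steady-state solves are
a 500 h integration plus Newton polish (fractions of a second);
half-life runs use 2 401 output points over 12 h; stimulation runs 301
points over 30 s; the oscillation scan three 100 s runs at 10 Hz; the
dietary experiment three 336 h integrations. The full test suite runs
in well under a minute on one core.

## Known limitations

The model is a single-varicosity, well-mixed caricature: no spatial
structure or diffusion, no mast-cell histamine (roughly half of brain
histamine), no serotonin co-modulation, no SAM dependence of HNMT, and
a transduction cascade that is minimal by design — inhibition of
release surely involves calcium channel machinery that is not
represented. Vmax values were originally chosen to reproduce
steady-state and perturbation behaviour rather than measured directly,
and the printed reference values are rounded to 3–4 significant
figures, which is why equilibrium residuals are audited against
rounding-consistent bounds rather than zero.
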