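---
title: "Reducing HTC triple isotope runs: model, corrections, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing HTC triple isotope runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripleiso)
```

## The measurement and its signal chain

High-temperature conversion (HTC) pyrolyses an organic sample at
>1400 °C to H~2~ and CO, so that the hydrogen, carbon and oxygen isotope
ratios (δ²H, δ¹³C, δ¹⁸O, all in permil against VSMOW/VPDB) can be measured
in a single continuous-flow IRMS run. The convenience comes with a chain of
instrument and chemistry effects that the data reduction must undo:

1. **Memory**: each analysis carries over a small fraction of the previous
   analysis's signal (typically 1–3%).
2. **Drift**: slow instrument drift over the hours of a run.
3. **Scale**: raw deltas sit on an instrument scale and must be normalized
   to VSMOW/VPDB through calibration standards. For δ¹³C the HTC reactor
   itself (glassy carbon tube and filling) contributes a roughly constant
   ~15% of the CO carbon, compressing the measured scale.
4. **Exchangeable hydrogen**: hydroxyl-bound hydrogen re-equilibrates with
   ambient water, so samples are equilibrated with water vapour of known
   δ²H before analysis, and only the carbon-bound (nonexchangeable)
   fraction carries the environmental signal.

`reduce_run()` applies the corrections in exactly that order. Memory and
drift are sequence effects on the measured values and must precede scale
normalization; the exchange correction operates on calibrated,
VSMOW-scale values because the water deltas it uses are on that scale.

## The exchange model

With exchangeable fraction $x_e$ and a fractionation factor
$\alpha_{e\text{-}w}$ between exchangeable hydrogen and water, the
equilibrated sample is a two-pool mixture:

$$\delta^2H_e = (1-x_e)\,\delta^2H_{ne} +
  x_e\left(\alpha_{e\text{-}w}\,\delta^2H_w +
  1000\,(\alpha_{e\text{-}w}-1)\right).$$

Two equilibrations with isotopically distant waters (the package defaults
use −160 ‰ and −412 ‰) invert this for $x_e$
(`exchanged_fraction()`); a single equilibration plus a known $x_e$
inverts it for $\delta^2H_{ne}$ (`nonexchangeable_delta()`). The three
functions are exact algebraic inverses of one another, which the test
suite asserts to 10⁻⁹ ‰ over randomized conditions.

The permil form above, with its $1000(\alpha-1)$ term, is used exactly as
written; no ratio-space variant is attempted. $\alpha_{e\text{-}w}$
defaults to 1.082, the cellulose value, and is applied to all
carbohydrates on the assumption that hydroxyl groups dominate exchange in
each of them; it is a configurable parameter because other functional
groups would need different values.

### Which x~e~ gets used

Apparent $x_e$ varies more with equilibration conditions (temperature,
vapour flux, drying, autosampler atmosphere) than with sample identity, so
the resolution order in `reduce_run()` is: an explicit per-run override
(ideally a run-level estimate from `estimate_run_xe()` on two-water data),
then the material registry value, then the class default (0.20 cellulose,
0.15 wood, 0.36 sugar). Leaf and other bulk materials have no trustworthy
class default and stay `NA` unless characterised. Estimates falling
outside $[0,1)$ are returned unclamped and flagged — they usually indicate
noise or an equilibration failure, and silently truncating them would hide
that.

## Correction details and numerical choices

**Memory.** The routine correction is the first-order difference form,
$c_i = y_i + m\,(y_i - y_{i-1})$. The simulator, by contrast, generates
carry-over recursively ($y_i = (1-m)v_i + m\,y_{i-1}$), which is the
physically motivated picture of residual material in the reactor. The two
meet exactly: the difference form inverts the recursive model at
$\hat m = m/(1-m)$, which for the 1–3% range differs from $m$ by well
under one grid step. `fit_memory_fraction()` scans $m$ over
0–5% in 0.1% steps, minimizing the pooled within-material standard
deviation of the calibration standards *after memory and drift
correction*, and then refines the best grid point with a bounded
continuous search (`stats::optimize`, tolerance 10⁻¹⁰). The refinement
exists because a purely gridded $\hat m$ cannot hit $m/(1-m)$ exactly,
leaving second-order residuals of order $10^{-2}$ ‰ on deterministic
runs; with the refinement, noise-free runs are inverted to machine
precision. Evaluating the objective on drift-corrected values matters:
with a genuine linear drift, the memory objective evaluated on
uncorrected values is biased and joint recovery of $(m, \text{drift})$
fails. The fit is done per isotope channel; ties break toward smaller
$m$, and a channel without at least one standard in triplicate keeps
$m = 0$ with a flag.

**Drift.** Drift is modelled as linear in analysis position (timestamps
are optional in run files, position order is not). The slope comes from
the standards analysed in both end blocks: per material, the difference
of block means over the difference of block mean positions, averaged
across materials. Correction is gated by a threshold, default
0.005 ‰/position, because drift should be corrected only when present:
below the threshold the estimate is mostly estimation noise and
subtracting it would add variance. The series is then flagged
`"no drift applied"` so the decision is auditable.

**Two-point calibration.** Per-material means of the corrected standards
(QC analyses are never used) are regressed against certified values —
exactly for two standards, by least squares for more. For δ¹³C on glassy
carbon, the constant reactor-carbon admixture
$y = (1-f)\,\delta_{true} + f\,\delta_{reactor}$ is itself affine, so the
calibration absorbs it and the fitted gain equals $1/(1-f)$;
`reactor_fraction_from_gain()` recovers $f$ as a diagnostic. δ¹⁸O is
treated identically but has no reactor term (the oxygen in CO comes only
from the sample in a glassy-carbon inner tube). For hydrogen the
standards are compared at their *forward-equilibrated* certified values
(certified δ²H~ne~ pushed through the mixing model with the run water and
each standard's own $x_e$): calibrating in equilibrated-delta space is
exact even when the standard set mixes materials with different exchange
fractions (e.g. celluloses, sugars and a non-exchanging polyethylene
foil), whereas calibrating in nonexchangeable space would only be exact
for a uniform $x_e$.

**Steady-state window.** On an argon-flushed autosampler tray,
equilibrated cellulose loses part of its exchange signal during roughly
the first two hours. Analyses of cellulose-class material earlier than
120 min (configurable) on such runs are flagged `"pre-steady-state"` and
excluded from every fit, though their reduced values are still reported.
Sugars do not show the effect and are not flagged; neither are runs on a
zero-blank (evacuated, helium-filled) autosampler.

## What the simulator emulates — and what it does not

`generate_run()` builds the canonical sequence (standard block, samples
with a QC analysis every 12, closing standard block; four calibration
materials in triplicate plus one QC per block) and applies, in forward
order: exchange mixing, reactor-carbon mixing, linear drift, recursive
memory, and i.i.d. Gaussian noise per channel. Defaults are the routine
study conditions: noise 3.0/0.2/0.3 ‰ (δ²H/δ¹³C/δ¹⁸O, the long-term QC
precisions of triple analysis with one equilibration), memory 0.02, drift
0, reactor fraction 0.15 at δ¹³C −25 ‰, a 12-minute analysis cadence and
a 120-minute pre-run wait. Equilibration loss, when enabled, relaxes the
effective $x_e$ exponentially with $\tau = \text{window}/3$ so the
transient is ~95% complete at the window end; the exponential shape and
time constant are simulator conventions — only the endpoint behaviour
(e.g. apparent $x_e$ 0.13 at first analysis vs 0.07 at steady state) is
empirically anchored.

Deliberately not emulated: heavy-tailed or drifting noise (only SDs are
reported for the instruments), nonlinear or step drift, signal-size
(linearity) effects, blank contributions, and the HCN/H₂S chemistry
behind the nitrogen and sulfur biases — those enter only as rule-based
flags (`interference_flags()`), with the predicted δ²H bias taken from
the packaged glassy-carbon vs chromium comparison (`read_reactor_table()`,
five materials spanning 0.2–10.4% N). Passing tests against this
generator therefore demonstrate that the *corrections invert the effects
they model*, not that real instruments contain no other effects.

Note on that packaged comparison: refitting the published difference
column against nitrogen content by ordinary least squares on the table's
rounded values gives slope 0.62 ‰ per %N, intercept −3.03 ‰, r² 0.57 —
the intercept and r² differ by one unit in the last printed digit from
the coefficients published alongside the table (−3.04, 0.58), which were
presumably fitted on unrounded data. The package reports its own computed
fit. The regression is unweighted (the published fit is) and descriptive;
no inference is attached to it.

## Problem sizes and reproducibility

All randomness is seeded; the seed is recorded in the run metadata and
round-trips through the CSV format. The test suite validates the pipeline
on runs of 37–142 analyses: closure (exact truth recovery at zero noise)
on 8 combinations of memory, drift and reactor fraction; precision
propagation with 10 QC replicates per run over 100 seeded repetitions,
asserting that the per-run QC standard deviations achieve the nominal 95%
coverage of the 9-degree-of-freedom chi-square band after the pipeline's
known rescalings (calibration gain, memory-correction noise
amplification $\sqrt{(1+m)^2+m^2}$, and $1/(1-x_e)$ for the exchange
step).

## Known limitations

* Memory is barely identifiable on the hydrogen channel at routine
  precision (3 ‰ noise against ~1–2 ‰ carry-over contrasts); the
  SD-minimizing fit then legitimately shrinks to zero. Carbon, with
  0.2 ‰ noise against ~15 ‰ contrasts, identifies it reliably; fit
  memory per channel and expect the hydrogen value to be noisy.
* Drift is position-linear by design; block-offset or nonlinear drift
  will be partially absorbed, partially flagged.
* The exchange correction multiplies hydrogen uncertainty by
  $1/(1-x_e)$ — a 3 ‰ equilibrated SD becomes ~4.7 ‰ on δ²H~ne~ for a
  sugar QC at $x_e = 0.36$. This is propagation, not a defect, but it is
  why two-equilibration designs are more precise.
* Chromium-reactor runs reduce δ²H only (no CO is formed); requesting
  carbon or oxygen from them is structurally impossible rather than an
  error of the pipeline.
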