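# tripleiso

Data reduction for **triple stable isotope analysis** (δ²H, δ¹³C, δ¹⁸O) of
cellulose, sugars and bulk organic matter by high-temperature conversion
(HTC) IRMS.

Converting a sample to H₂ and CO at >1400 °C allows all three isotope
ratios to be measured in one run, at the price of a chain of effects the
data reduction must undo: carry-over between consecutive analyses
("memory", typically 1–3%), instrument drift, scale normalization to
VSMOW/VPDB — for δ¹³C including the ~15% of CO carbon contributed by the
glassy-carbon reactor itself — and the exchangeable-hydrogen correction for
water-vapour-equilibrated samples. `tripleiso` implements the full pipeline
plus quality control, a glassy-carbon vs chromium reactor comparison with a
nitrogen-bias screen, and a seeded forward simulator that generates runs
with known truth so every correction stage is testable end to end.

## The model in brief

Deltas are relative isotope-ratio deviations,
δ = (R_sample/R_standard − 1) × 1000 ‰. An equilibrated sample's hydrogen
is a two-pool mixture of carbon-bound (nonexchangeable) hydrogen and
hydrogen exchanged with the equilibration water:

    δ²H_e = (1 − x_e)·δ²H_ne + x_e·(α_ew·δ²H_w + 1000·(α_ew − 1))

with α_ew = 1.082 for carbohydrates. Two equilibrations with distant
waters invert this for the exchanged fraction x_e; one equilibration plus
a known x_e (0.20 cellulose, 0.15 wood, 0.36 sugar) inverts it for
δ²H_ne, the climatically meaningful signal. Reduction order:
memory → drift → two-point calibration → exchange correction. The δ¹³C
calibration gain equals 1/(1 − f) when a fraction f of the CO carbon comes
from the reactor, so the reactor contribution is absorbed and can be read
back off the fitted gain.

## Worked example

Simulate a routine run (51 analyses: two standard blocks of four
calibration materials in triplicate plus a QC sucrose, 24 cellulose
samples with interleaved QC) at the routine precisions, then reduce it:

```r
library(tripleiso)

g   <- generate_run(generator_config(seed = 42))
red <- reduce_run(g$run, g$materials)
red
#> <reduced_run> 51 analyses
#> <calibration_model> reactor: glassy_carbon
#>   H2  gain 0.99974 offset    1.312 | m 0.0000 | drift +0.0345 (applied)
#>   C13 gain 1.16918 offset    4.266 | m 0.0234 | drift -0.0012 | reactor C fraction 0.145
#>   O18 gain 1.00555 offset   -0.212 | m 0.0500 | drift +0.0030
#>   sequence valid
```

The δ¹³C gain of 1.169 implies that 14.5% of the CO carbon came from the
reactor (the simulator injected 15%); the fitted memory fractions sit in
the typical percent range on the well-conditioned carbon channel. QC
precision and the first reduced samples:

```r
qc_precision(red)
#> # A tibble: 4 × 3
#>   isotope     n    sd
#> 1 d13C        3 0.223
#> 2 d18O        3 0.161
#> 3 d2H_e       3 1.23
#> 4 d2H_ne      3 1.92

red$results[red$results$role == "sample",
            c("material_id", "d13C", "d18O", "d2H_ne", "x_e_used")]
#>   material_id  d13C  d18O d2H_ne x_e_used
#> 1 SAMPLE-01   -28.8  34.8  -63.6      0.2
#> 2 SAMPLE-02   -24.6  28.7  -62.8      0.2
#> 3 SAMPLE-03   -26.3  24.8 -118.       0.2
#> ...
```

`d2H_ne` is the calibrated nonexchangeable δ²H in permil VSMOW; `x_e_used`
records which exchange fraction the correction applied (here the cellulose
class default). Reactor comparison and nitrogen-bias screen:

```r
tab <- read_reactor_table()           # packaged 5-material comparison
nitrogen_bias_regression(tab)         # slope 0.62 ‰/%N, intercept -3.03, r² 0.57
interference_flags(default_materials())  # flags the 10.4%-N insect material
```

A thin command-line front end over the same functions ships in
`inst/cli/tripleiso.R` (`simulate`, `reduce`, `qc`, `compare-reactors`
subcommands).

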