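# ringmotor

Quantitative machinery for doping experiments on hexameric AAA+ unfoldases.

Hexameric AAA+ machines such as VAT, the archaeal CDC48/p97 homologue,
unfold proteins by threading them through their central pore. A sequential
"hand-over-hand" mechanism — in which the one substrate-free ("seam")
protomer rebinds ATP, re-engages at the top of the substrate-gripping helix,
and the bottom protomer releases in turn — predicts that a single
catalytically dead protomer stalls the whole ring. Mixing experiments test
this: assemble hexamers from wild-type and Walker-B-mutant protomers at a
mutant fraction *r* and measure ensemble activity *A(r)* normalized to the
all-wild-type rate. This package is for biochemists and modelers who design
or interpret such experiments.

## The model

Random assembly makes the number of dead protomers per hexamer binomial,
*P(k) = C(6,k) r^k (1−r)^(6−k)*. Under a threshold-coupling hypothesis —
activity is unaffected until *m* dead protomers are present, then all
hydrolysis stops — the fractional activity is

    A(r) = (1/6) * sum_{j=0}^{m-1} (6−j) C(6,j) r^j (1−r)^(6−j)

with the limiting cases *m* = 1 → *A* = (1−r)^6 (strict hand-over-hand),
*m* = 2 → *A* = (1−r)^6 + 5r(1−r)^5, and *m* = 7 (no coupling) → *A* = 1−r.

Around this core the package provides:

* `activity_threshold()` / `enumeration_oracle()` — the closed form and an
  independent brute-force enumeration over all 2^6 ring configurations;
* `simulate_motor()` / `ensemble_activity()` — a Gillespie simulator of the
  sequential cycle with stalling by dead protomers and an optional
  escape/re-engagement mechanism, plus doped-ensemble activity curves;
* `atp_dependence()` — simulated ATP titrations with a Hill fit (the
  single-engaging-site cycle gives Michaelis-Menten kinetics, h ≈ 1);
* `initial_slope()`, `normalize_and_aggregate()`, `fit_threshold_model()`,
  `fit_escape_model()`, `quantify_degradation()` — assay reduction and model
  selection;
* `fit_helix()`, `aperture()`, `pore_tilt()`, `grip_extent()`,
  `layer_line()` / `measure_layer_line()` — geometry of substrate-gripping
  pore-loop helices, with leave-one-out seam detection;
* `gen_doping_dataset()`, `gen_fluorescence_trace()`,
  `gen_pore_loop_helix()`, `gen_band_timecourse()` — seeded synthetic-data
  generators for every input above.

## Worked example

Generate a triplicate doping dataset whose truth is the strict sequential
mechanism (*m* = 1, noise SD 0.02), fit all threshold models, and check the
stochastic simulator against the closed form:

```r
library(ringmotor)

d <- gen_doping_dataset(list(m = 1), r_grid = seq(0, 0.9, 0.1),
                        reps = 3, noise_sd = 0.02, seed = 42)
fit <- fit_threshold_model(d, n_bootstrap = 200, seed = 1)
fit
#> Threshold (subunit-poisoning) model fit
#>   best m = 1
#>   RSS by m:
#>        1        2        3        4        5        6        7
#> 0.018328 0.815298 2.312510 3.625887 4.443962 4.766597 4.766597
#>   bootstrap selection frequency (200 resamples):
#> 1 2 3 4 5 6 7
#> 1 0 0 0 0 0 0

ensemble_activity(motor_params(), r = 0.2, n_complexes = 2000,
                  t_end = 300, seed = 42)
#> Ensemble point r = 0.2: activity 0.2521 (SE 0.0097), unfolding 0.2521 (SE 0.0097), n = 2000

fit_helix(gen_pore_loop_helix(jitter_sd = 0.3, seed = 42), "NBD1-PL1")
#> Helix fit (NBD1-PL1): rise 13.355 A, twist 61.172 deg, pitch 78.60 A
#>   radius 13.35 A, rms residual 0.223 A, seam protomer 6
```

The fit selects *m* = 1 in every bootstrap resample: one dead protomer per
hexamer abolishes activity, the signature of the sequential mechanism. The
simulated ensemble at *r* = 0.2 lands on the (0.8)^6 ≈ 0.262 prediction
within its Monte Carlo error (activities are normalized to a paired
all-active reference, so *r* = 0 is exactly 1). The helix fit recovers the
programmed staircase (rise 13 Å, twist 60°) from jittered pore-loop
coordinates and identifies the seam protomer by leave-one-out residuals.

## The methods vignette

`vignettes/subunit-poisoning.Rmd` documents the model assumptions, the
simulator's mechanistic design choices (stall rule, ATP stoichiometry,
escape semantics), what the synthetic data do and do not emulate, the
least-squares helix fit, and numerical tolerances.
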