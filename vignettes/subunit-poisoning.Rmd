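---
title: "Subunit poisoning and hand-over-hand translocation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subunit poisoning and hand-over-hand translocation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringmotor)
```

## The scientific problem

Hexameric AAA+ unfoldases such as VAT (the archaeal CDC48/p97 homologue)
thread substrate proteins through their central pore and unfold them. A
sequential "hand-over-hand" mechanism makes a strong, testable prediction:
because every protomer must hydrolyze ATP in turn as the cycle moves around
the ring, a single catalytically dead protomer blocks the whole complex. The
classical way to test this is a doping experiment: mix wild-type protomers
with Walker-B double mutants (which bind but cannot hydrolyze ATP) at a
fraction `r`, let hexamers assemble randomly, and measure ensemble activity
`A(r)` normalized to the all-wild-type rate. This package implements the
quantitative machinery around that experiment: the closed-form composition
and activity models, a stochastic simulator of the cycle, assay reduction and
model fitting, helix geometry of the substrate-gripping pore loops, and
synthetic-data generators so every stage is testable end to end.

## The binomial subunit-poisoning model

With equal insertion probability for either protomer species, the number of
dead protomers per hexamer is binomial,

$$P(k) = \binom{6}{k} r^k (1-r)^{6-k},$$

implemented by `composition_pmf()`. The coupling hypothesis is a threshold
`m`: activity in the functional sites is unaffected until `m` dead protomers
are present, at which point all hydrolysis in that complex stops. A complex
with `j < m` dead protomers runs at `(6 - j)/6` of the wild-type rate
(proportional to its functional protomers, each carrying two nucleotide
sites that are poisoned together by the double mutant), giving

$$A(r) = \frac{1}{6}\sum_{j=0}^{m-1} (6-j)\binom{6}{j} r^j (1-r)^{6-j}.$$

Three special cases matter: `m = 1` (strict sequential mechanism) gives
`A = (1-r)^6`; `m = 2` gives `A = (1-r)^6 + 5r(1-r)^5`; and `m = 7`, which
extends the sum over all `j`, collapses to the uncoupled (independent
subunits) line `A = 1 - r`. Encoding "no coupling" as `m = n + 1` keeps one
code path instead of a flag. `m` is defined on protomers, not nucleotide
sites, matching the double Walker-B construct that kills both sites of a
protomer at once.

`enumeration_oracle()` recomputes `A(r)` by enumerating all `2^6` labeled
active/dead configurations and never shares code with
`activity_threshold()`; the test suite holds the two equal to `1e-12` across
every `m` and a grid of `r`. The enumeration refuses `n > 20` explicitly
rather than truncating.

## The hand-over-hand simulator

`simulate_motor()` runs a Gillespie-style event loop over the cycle of the
sequential model. The ring state is a staircase of ranks: rank 0 grips
substrate nearest the folded domain, rank `n - 2` is the bottom gripping
position, and rank `n - 1` is the seam, which does not contact substrate
(five of six protomers grip at any instant). One productive transition
re-engages the seam protomer at the top while every other rank increments,
so the former bottom protomer becomes the new seam; the substrate advances
13 Å (about two extended residues) and `atp_per_step` ATP are consumed.

Design choices where the mechanism leaves freedom:

* **Which protomer's defect stalls the ring.** The one nucleotide event
  mandated by the cycle is that the seam protomer must rebind ATP as it
  re-engages. A transition therefore requires the current seam protomer to
  be active; a dead protomer blocks the cycle when it reaches the seam. With
  one dead protomer any placement rule gives the same long-run `(1-r)^6`
  ensemble limit, so this choice does not affect the headline curves.
* **Stall timing.** A dead seam is detected at the next attempted
  ATP-binding event (one exponential waiting time at the step rate), so
  event times stay strictly increasing and a stall is a failed binding
  attempt rather than an instantaneous state change.
* **ATP stoichiometry.** `atp_per_step` defaults to 2 — one per AAA+ ring
  per transition, because the two nucleotide-binding domains of each
  protomer move along the substrate in unison — and is configurable to 1;
  normalized activities are invariant to it. Both rings are modeled as a
  single coupled staircase (one rank per protomer) for the same reason.
* **Escape semantics.** A stalled complex disengages at rate `k_escape`,
  waits at rate `k_reengage`, and re-engages a *fresh* substrate with a
  uniformly random seam phase; no ATP is consumed while stalled or
  disengaged. Whether a real complex can resume the same partially unfolded
  substrate is unknown; the fresh-substrate rule is the conservative choice
  and only affects throughput bookkeeping, not ATPase activity.
* **Waiting times** are exponential with a single lumped rate (ATP
  hydrolysis and ADP release are not resolved as separate substeps; their
  position in the cycle is not fixed by structural data). With `atp_conc`
  and `K_bind` set, the rate saturates as `k_step · c/(K + c)` — a single
  engaging site per transition, which is what makes the simulated ATP
  titration hyperbolic (Hill coefficient near 1) rather than cooperative.

`ensemble_activity()` samples per-protomer dead flags independently with
probability `r` (the same assembly assumption as the binomial model),
simulates each complex, and normalizes by a paired all-active reference run
from the same per-complex sub-seed. The common random numbers make the
`r = 0` point exactly 1, cancel most Monte Carlo variance in the ratio, and
pair cleanly across parameter scans, which `fit_escape_model()` exploits to
keep its grid objective quasi-deterministic.

## Synthetic data: what it emulates and what it does not

The generators produce every input the reduction layer consumes, with the
statistical structure the analysis assumes:

* `gen_doping_dataset()` — triplicate activity measurements on an `r` grid
  with additive Gaussian noise (default SD 0.02 on the normalized-activity
  scale, a few percent of the dynamic range, matching a well-behaved
  plate-based assay); optional finite-assembly binomial sampling noise on
  top of the analytic mean. Truth is either a threshold model or the
  simulator.
* `gen_fluorescence_trace()` — first-order fluorescence decay
  `F_bg + F0·exp(-k t)` plus noise. A chaperonin trap prevents refolding in
  the real assay, so the decay is monotone in expectation; only initial
  slopes are used downstream, which are insensitive to the tail shape.
* `gen_pore_loop_helix()` — four pore-loop helices per hexamer with defaults
  emulating the substrate-engaged geometry: rise 13 Å, twist 60°, NBD1 loop
  radius 14 Å (28 Å aperture), NBD2 radius 9 Å (18 Å aperture), −28 Å
  inter-ring offset (≈80 Å combined grip span), and a seam protomer
  displaced 8 Å outward and 6 Å upward from its helical continuation.
* `gen_band_timecourse()` — exponential band-intensity decay plus a flat
  control series standing in for the -ATP/-proteasome controls.

What passing tests on these data do *not* show about real experiments:
plate-reader drift and photobleaching, gel densitometry artifacts,
non-binomial (biased) assembly, partial per-site poisoning, force-dependent
stepping, and substrate unfolding energetics are all outside the generators,
so parameter-recovery results quantify estimator behavior under the stated
noise model only.

## Assay reduction and model fitting

`initial_slope()` fits an OLS line over the leading window (first 10% of
points or 5 points, whichever is larger). The slope of an exponential over a
finite window is biased toward zero by curvature, by roughly `k·t_window/2`;
recovery studies therefore keep `k·t_window ≲ 0.1` and assess the study
mean, where the estimator is unbiased to well under 5%.

`normalize_and_aggregate()` divides by the mean `r = 0` rate — normalization
is per dataset, since the protocol does not say whether undoped rates were
shared across mixing experiments — and reports per-`r` mean ± sample SD.

`fit_threshold_model()` compares the data against `A(r; m)` for every
`m ∈ {1..7}` by residual sum of squares. `m` is a discrete hypothesis with
no free parameters, so no information criterion is needed; ties break toward
smaller `m` (the more parsimonious, stricter coupling), and a bootstrap over
replicates-within-`r` turns the selection into a frequency. Weighting is
unweighted by default (the protocol states none); inverse-variance weighting
by replicate SD is available.

`fit_escape_model()` grid-searches `k_escape`, simulating an ensemble curve
per candidate with per-`r` sub-seeds shared across the grid, and reports the
full objective profile so flatness is visible rather than hidden behind a
point estimate. Data generated without escape drive the estimate to the
lower grid boundary; moderate escape leaves the signature the threshold fit
cannot absorb — systematically positive residuals above the `(1-r)^6` curve
at intermediate `r`.

## Helix geometry

`fit_helix()` is a genuine least-squares helix fit. The axis is seeded from
the null space of the second differences of consecutive points (which lie in
the plane perpendicular to the axis for an ideal helix), then refined by
Nelder-Mead over two axis-tilt angles and the twist; for fixed axis and
twist every remaining parameter (center, radius, phase, rise, offset) is a
linear least-squares solve, so the refinement is a 3-parameter problem with
closed-form innards. The fit runs in a canonical frame derived from the data
(centroid at origin, seeded axis along +z), which makes the result invariant
under rigid-body motion of the input down to rounding error (~1e-13), and
the axis is oriented so rise > 0, with the twist sign following the
right-hand rule about that axis.

The seam is found by leave-one-out: the fit excludes the single protomer
whose exclusion minimizes the RMS residual, mirroring the structural
definition of the seam as the subunit displaced off the gripping helix.
Protomer cyclic order is taken from the input labels and trusted, never
inferred.

At the generator's own conditions (five gripping points, 0.5 Å jitter) the
least-squares estimates are unbiased but have intrinsic spread — twist SD
about 3% with occasional ~9% excursions — so recovery at that jitter is a
property of the study mean, not of every individual fit; the tests assert
both the mean and the fraction of individual fits inside 5%.

Other measurements are closed-form: `aperture()` is twice the minimal radial
distance from the pore axis (the widest axis-centered cylinder through the
opening — atom-center distances, no van der Waals correction, stated so
users compare like with like); `pore_tilt()` is the angle between the
centroid-to-centroid vector of two rings and the mean of their least-squares
plane normals; `grip_extent()` is the projection span of contact points on
the pore axis; `layer_line()` is `1/pitch`, and `measure_layer_line()` finds
the first off-origin maximum of the power spectrum, taking the
lowest-frequency local maximum with at least 10% of the dominant off-origin
power (the floor keeps noise wiggles from posing as the layer line) and
refusing a peak in the Nyquist bin as undersampled.

## Problem sizes and numerical tolerances

The validation studies use sizes chosen so Monte Carlo error is comfortably
below the effects being tested: ensembles of 2000 complexes over a horizon
of 300 waiting times for the convergence check (standard errors ≈ 0.01 on
the activity scale, against 3-SE tolerances), 1000 complexes for the escape
scan, 100 seeded datasets for each recovery study, and 50–100 seeded
structures for the geometry round-trips. Closed-form identities are held to
`1e-12`, rigid-motion invariance to `1e-9`, and exact round-trips (zero
jitter, zero noise) to `1e-9` or better. Trajectories are bit-reproducible
for a fixed seed.

## Known limitations

The simulator has no force dependence, no substrate secondary structure or
unfolding energetics, no proteasome docking, and no N-terminal domain
effects; nucleotide occupancy of the sites flanking the seam is tracked only
implicitly through the cycle position. The throughput counter counts
translocated residues, so partially unfolded substrates released by escape
still contribute. ATP in the unfolding-assay generators is treated as
saturating. The aperture and grip numbers produced from generator defaults
describe the synthetic geometry the generator was programmed with — they are
consistency checks of the measurement code, not re-measurements of deposited
experimental structures. The printed ~80 Å grip over 12–14 residues and
~13 Å step over ~2 residues imply a per-residue spacing larger than a fully
extended chain; the simulator therefore takes Å and residue step sizes as
independent parameters rather than resolving that tension.
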