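---
title: "Methods: stochastic-titration constant-pH dynamics under umbrella sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic-titration constant-pH dynamics under umbrella sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uscphmd)
```

## The problem this package models

Membrane transporters that carry charged substrates couple two slow
processes: the substrate's motion along the channel axis and the
protonation equilibria of the substrate and of titratable residues lining
the cavity. Neither can be sampled by brute force: the transport
coordinate hides large free-energy barriers, and protonation states are
discrete variables whose populations depend on the local electrostatic
environment. The established remedy combines *umbrella sampling* (US) —
harmonic restraints that force coverage of the transport coordinate —
with *stochastic-titration constant-pH dynamics* (CpHMD), which
periodically resamples protonation states from their Boltzmann
distribution at fixed conformation and pH.

`uscphmd` implements that full protocol at desk scale, on low-dimensional
model systems: one continuous reaction coordinate `z` (nm) carrying a
substrate with titratable sites through a configurable electrostatic
channel environment. Every analysis component — WHAM, bias re-weighting,
Hill fits, pKmod calibration, split-half and autocorrelation-block errors
— is the real method, exercised end to end against analytic truths.

## Protonation model

A titratable site has an intrinsic pK (`pk_int`, its *pKmod*: the
reference value that makes the simulated bulk titration reproduce the
experimental aqueous pKa), a set of protonated tautomers, and state
charges (acid: deprotonated −1 e; base: protonated +1 e). The microstate
free energy, in kT, is

\[
E(s) \;=\; \sum_{i:\,\mathrm{prot}} \Big[\ln 10\,(pH - pK_i - \delta_{t})
  + \ln T_i\Big] \;+\; \ln 10 \sum_{i<j} W_{ij}(s_i, s_j),
\]

where \(T_i\) is the tautomer count (the \(\ln T_i\) degeneracy
correction keeps the site-level curve exactly Henderson–Hasselbalch when
tautomer offsets \(\delta_t\) vanish) and \(W_{ij}\) are pairwise
couplings in pK units. The protonated-fraction formula
\(f = 1/(1+10^{pH-pK})\) holds for acids and bases alike — only the
charges differ — so the per-site energy term is deliberately identical
for both kinds.

Couplings come from a pluggable electrostatics backend. The default is a
Debye–Hückel screened Coulomb interaction between state charges
(`couplings_from_geometry()`), with the Bjerrum and Debye lengths computed
from physical constants at the configured temperature, dielectric and
ionic strength. The reference continuum-electrostatics constants of the
full grid Poisson–Boltzmann setup this backend stands in for are recorded
in `reference_electrostatics()`; the backend interface (per-state site
energies plus pairwise coupling matrices) would accept a grid solver
unchanged.

### Metropolis sampling and detailed balance

`mc_sample()` runs Metropolis Monte Carlo over microstates. One *cycle*
performs `n_sites + n_pairs` elementary attempts, each drawn uniformly at
random from the combined move set: single-site state changes, plus
concerted two-site moves for pairs whose coupling magnitude strictly
exceeds 2 pK units (ties excluded). Two details matter:

* **Why random move selection rather than a fixed sweep.** A
  deterministic sweep preserves the stationary distribution but is not a
  reversible kernel, so empirical transition counts between microstates
  need not balance. Drawing each move uniformly makes the elementary
  kernel reversible, and a cycle (a power of that kernel) inherits
  reversibility — the detailed-balance property tests then hold exactly,
  not just approximately. Each site and each eligible pair is still
  attempted once per cycle in expectation.
* **Why proposals include the current state.** With a propose-other-state
  rule, an energy-neutral two-state site (pH = pK) is *always* accepted
  and therefore flips deterministically; an even number of cycles returns
  it to its start, which silently freezes the site when the sampler is
  embedded in the dynamics engine with a fixed cycle count per update.
  Proposing uniformly over all states (a symmetric proposal) restores
  proper mixing at degeneracy at the cost of some wasted proposals.

The first 10% of cycles are discarded as burn-in; one microstate is
recorded per cycle. Per-site standard errors use batch means with
\(\sqrt{n}\) batches — a consistent MCMC error estimate that stays honest
for rarely flipping sites, where an empirical autocorrelation cutoff can
misjudge the block length (verified against 10-seed repeat experiments on
near-saturated sites). `enumerate_exact()` provides the brute-force
Boltzmann-sum oracle for systems of up to \(10^6\) microstates.

## The channel field

The channel environment is modelled by two Gaussian components along the
coordinate (`channel_field()`): a *cationic well* (depth in pK units) that
stabilises anionic states, and a *desolvation* penalty that destabilises
any charged state. For an acid the effective pK is

\[ pK_\mathrm{eff}(z) = pK_\mathrm{int} + \mathrm{desolv}(z) -
   \mathrm{well}(z), \]

recovering the bulk pK far from the channel. The same terms, multiplied
by \(\ln 10\) and the state charge pattern, enter the microstate energies
and exert forces on the coordinate, so protonation and motion are
genuinely coupled. The default channel fixture places a 2 pK well at
−1 nm and a 2 pK desolvation peak at +1 nm (0.6 nm widths) on a −4…+4 nm
scan: deep enough that the PMF well (~4.6 kT) and the protonation bump
(bulk 24% → ~97%) are unmistakable, while the most depressed effective pK
(4.5 at pH 7) still leaves every profile bin with expected protonation
counts well above zero. These amplitudes are the fixture's definition of
the study conditions; tests do not move them.

## Dynamics engine

`run_cphmd()` alternates overdamped Euler–Maruyama Langevin steps on `z`
with Metropolis protonation updates every `protonation_period = 10` steps
(20 MC cycles per update; both are engine defaults, since the reference
protocol's inner cycle lengths live in its cited prior methods). Forces
combine the gridded external potential, the field force on the current
charge state, and the optional harmonic umbrella bias. The time step is
0.002 ps, matching standard production MD.

Friction (default 10 ps⁻¹, i.e. \(D = 0.1\) nm² ps⁻¹ in kT units) is an
integrator-accuracy choice: for an Euler–Maruyama chain in a harmonic
well of stiffness \(k\), the stationary variance is inflated by roughly
\(1/(1 - kD\,\Delta t/2)\). At the stiffest umbrella used
(1000 kJ mol⁻¹ nm⁻², \(k \approx 388\) kT nm⁻²) the default gives
\(kD\Delta t \approx 0.08\), a ≈4% variance bias, while positional
decorrelation (\(\tau = 1/(kD) \approx 0.03\) ps) stays far shorter than
a window run. Reduced-scale test fixtures with soft windows lower the
friction to 2 so that samples decorrelate within one recording interval.

Counter-ion bookkeeping follows the neutralisation protocol:
`neutralize_system()` estimates the mean total charge from a short
pre-run and `counterions_for_neutrality()` returns the fixed number of
monovalent ions bringing the expectation nearest zero (ties round away
from zero, over-neutralising, so the uniform background correction only
ever handles sub-0.5 e residuals).

## Umbrella sampling

`window_schedule()` / `place_windows()` tile the coordinate with a dense,
stiff interior (|z| ≤ 2 nm, 0.1 nm spacing, 1000 kJ mol⁻¹ nm⁻²) and
sparser, softer exterior windows (0.2 nm, 500 kJ mol⁻¹ nm⁻²; 250 is the
other customary choice). `steer()` generates starting configurations by
dragging the substrate with a moving restraint (default rate
0.025 nm ns⁻¹, k = 1000) and extracting snapshots at window centers.
`overlap_diagnostics()` makes the usual visual overlap check quantitative
as the histogram intersection of adjacent windows (flagging pairs below
0.05). Transport interrupted by a conformational transition is handled by
`split_segments()`: windows split at the transition position (+0.2 nm by
default), and the junction window belongs to *both* segments, because the
two PMFs share that physical position while each is anchored to its own
water phase.

## WHAM and re-weighting

`wham()` iterates the standard self-consistent equations on binned window
histograms until every window free-energy constant moves by less than
\(10^{-6}\) kT (bin width 0.05 nm — half the finest window spacing;
neither is prescribed by the reference protocol, both are package
defaults). Three numerical choices deserve explanation:

* **Bin-averaged bias factors.** With stiff biases, \(e^{-\beta c(z)}\)
  varies by tens of percent across one bin; evaluating the bias at bin
  centers produced systematic ~0.2 kT humps in flat-truth scans. The
  discrete model therefore uses the exact bin average of the harmonic
  Boltzmann factor (a closed form via the normal CDF).
* **Minimum bin occupancy.** Bins with fewer than 5 total samples are
  reported `NA`: a lone far-tail sample carries an enormous unbiasing
  weight and can otherwise masquerade as the profile minimum.
* **Anchoring.** Profiles are anchored to zero over the bulk region
  (mean over |z| ≥ 3.5 nm); configurations whose windows never reach bulk
  fall back to minimum-anchoring with a warning.

`reweight_observable()` computes unbiased conditional means
\(E[\mathrm{obs}\,|\,z]\) with the WHAM weights
\(w_s = 1/\sum_j N_j e^{f_j - c_j(z_s)}\); it reduces exactly to the
plain binned average when biases vanish, and empty bins are reported
missing, never interpolated. Per-bin standard errors use the weighted
variance with the effective sample size \((\sum w)^2 / \sum w^2\).
Profile errors pooled across windows sharing a bin are per-bin pooled
(the alternative, per-window assignment, is noted as an open choice in
the protocol; pooling is what the estimator above does naturally).

### Error estimators

Two estimators mirror the protocol's error analysis. The *split-half* PMF
error computes independently anchored PMFs from the two time halves of
every window and reports \(|G_1 - G_2|/2\) per bin; anchoring makes it
invariant to constant offsets. Note that a single half-difference is a
folded-normal draw with ~100% relative noise per bin — tests and
consumers that need a stable scale should pool it (the RMS over bins
estimates \(\sigma(G)\), since \(E[(|G_1-G_2|/2)^2] = \sigma^2\)). The
*autocorrelation-block* SEM finds the first lag at which the normalised
autocorrelation drops below 0.1, cuts the series into blocks of that
length (capped at n/2 so at least two blocks remain), and reports the SEM
of block means. On AR(1) data with \(\phi = 0.9\) it recovers the
analytic SEM of the mean to within ~25% (slightly low, as the cutoff
ignores the correlation tail — a known property of the estimator).

## Titration analysis and calibration

`hill_fit()` performs a bounded least-squares fit of
\(f = 1/(1 + 10^{\,n(pH - pK)})\) in occupancy space with
\(n \in (0, 5]\) (occupancy space rather than logit space keeps the noise
model sensible near 0 and 1). Curves that never cross 0.5 within the
sampled pH range carry no midpoint information and are flagged
degenerate. `run_titration()` averages replicate trajectories and reports
replicate standard errors of the mean, mirroring the three-replicate
protocol.

Calibration closes the loop: simulate the model compound with a trial
reference pK of zero, measure the apparent pKa, form the shift
(`pka_shift()`), and set `pk_mod = target − shift`
(`calibrate_pkmod()`). Re-simulating with the calibrated value recovers
the experimental pKa — the package's round-trip test does this with a
compound carrying two fixed anionic neighbours that engineer a ~1.5 pK
shift, recovering the 6.5 target to within 0.01 pK. The triphosphate and
diphosphate mimics (`make_atp_mimic()`, `make_adp_mimic()`) reproduce the
qualitative calibration picture: the shift collapses when only one
charged neighbour remains.

## What the fixtures do and do not emulate

The synthetic systems reproduce the *statistical structure* of the real
protocol — biased, time-correlated trajectories; coupled
protonation/conformation sampling; window bookkeeping across a
conformational transition; re-weighted observable profiles with
realistic error behaviour — at sizes that run in seconds to minutes on
one CPU (production fixture: 61 windows × ~3,500 retained samples;
reduced fixtures: 11–21 windows × ~1,700). They do **not** emulate
explicit solvent, a membrane dielectric slab, real protein
electrostatics, multi-dimensional pulling geometry, or force-field
physics; passing tests therefore validate the *method implementation*,
not any biological prediction about a real carrier.

## Known limitations

* The exact-enumeration oracle is exponential in site count (capped at
  \(10^6\) microstates).
* WHAM here is 1-D and harmonic-bias only; an MBAR backend would drop
  both restrictions.
* A statistical caveat worth stating plainly: a pointwise 3σ band applied
  simultaneously to ~170 profile bins is *expected* to be exceeded
  somewhere in roughly 40% of runs even with perfectly calibrated error
  bars (the median of the maximum of 171 absolute standard normals is
  ≈ 2.9). The package's profile error bars were verified to be calibrated
  (empirical z-score dispersion 1.05 over repeated scans); single-bin
  3–4σ excursions in a full-scan comparison are the extreme-value
  statistics of honest errors, not evidence of bias.
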