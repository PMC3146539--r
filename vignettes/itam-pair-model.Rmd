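---
title: "Bead-assay quantification and the opposing-ITAM-pair model"
author: "ipfcmKinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bead-assay quantification and the opposing-ITAM-pair model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipfcmKinetics)
```

This vignette is the package's own account of its methods: the
quantification conventions for bead immunoassays read by flow cytometry, the
mechanistic model of proximal TCR-CD3–ZAP70 signalling, the choices made
where the design was genuinely open, and what the synthetic-data tests do
and do not demonstrate.

## 1. Quantifying bead immunoassays

An IP-FCM sample is a table of bead events: forward and side scatter plus
one intensity per fluorescence channel.  The package reduces a sample to a
channel summary in four steps.

**Gating.** Bead populations are selected by a rectangular gate in
(FSC, SSC).  Real analyses draw polygon gates; a rectangle is used here
because it is fully determined by four numbers and therefore reproducible.
Gating fails loudly when fewer than `minEvents` events survive (default
5000, the number of beads typically acquired per sample), rather than
silently summarising a thin population.  For two-plex assays two bead sizes
are mixed before capture; the generator places their scatter centres more
than four combined standard deviations apart, which makes midpoint gating
essentially error-free (Gaussian tail mass beyond 4 s.d. is < 10⁻⁴).

**Geometric MFI.** Fluorescence distributions of bead populations are
close to lognormal, so the location statistic is the geometric mean,
`exp(mean(log x))`.  Events at or below zero (instrument floor artifacts)
are dropped before the log and their count is reported; they are not offset,
because an additive offset changes the statistic for every event rather
than only the corrupted ones.

**Background subtraction and ratios.** Uncoupled beads stained with the
same antibody provide the control MFI; the net signal is
`max(sample − control, 0)`, with flooring flagged.  The assay readout is the
ratio of two net MFIs (e.g. ZAP70/CD3ε), which cancels the amount of
captured complex.  The subtraction happens at the MFI level, not per event —
the natural choice when the control is a separate bead population rather
than a paired measurement.

**Replicate statistics.** Replicates are summarised by mean, s.e.m.
(sd/√n) and percent coefficient of variation (100·sd/mean), all with the
n − 1 sample standard deviation.  At triplicate scale the sample sd is
biased low by the c₄ factor (≈ 0.886 at n = 3); the Monte-Carlo test of the
5 % noise generator therefore expects a long-run average %cv slightly below
5 rather than exactly 5.

**Absolute calibration.** Calibration beads carrying 515, 5 956, 26 653 and
69 045 PE molecules define a standard curve fitted by ordinary least squares
in log–log space, with molecules regressed on MFI because the curve is used
to *predict* molecules from a measured MFI.  On an exact power law the
correlation coefficient is 1 to machine precision.  Molecule estimates are
divided by the antibody labelling efficiency (fluorophores per antibody,
default 1 for one-PE-per-antibody conjugates).  Stoichiometries follow as
`target / (reference / copies)` — e.g. ZAP70 per TCR-CD3 uses CD3ε with two
copies per complex — and uncertainties propagate by the first-order delta
method, the standard choice when only per-count s.e.m.s are available.
Because stoichiometries are ratios of calibrated counts, they are invariant
to the instrument gain, and the package tests this as a property.

## 2. The opposing-ITAM-pair model

The model describes the core signalling unit at the TCR-CD3 cytoplasmic
tails: a pair of opposite ITAMs, as found in the paired CD3 and ζ chains.
All ITAMs of the complex are treated as identical, so per-pair fractions
equal per-complex fractions.

A single ITAM occupies one of seven states:

| state | meaning |
|---|---|
| `U` | both ITAM tyrosines unphosphorylated |
| `P1` | one tyrosine phosphorylated |
| `P2` | both phosphorylated, no ZAP70 |
| `Z` | ZAP70 bound (tandem SH2 on the doubly phosphorylated motif) |
| `Z319` | bound ZAP70 phosphorylated at Y319 |
| `Z319_493` | bound ZAP70 phosphorylated at Y319 and Y493 |
| `Z493` | bound ZAP70 phosphorylated at Y493 only |

`Z493` deserves a note: it arises when Y319 is dephosphorylated while Y493
is still phosphorylated.  It is the only combinatorially consistent seventh
member of the state set — three ZAP70-free ITAM phospho-states plus four
modification states of a bound ZAP70 — and it is treated as *closed* (no
pY319), so it can neither catalyse nor receive trans-autophosphorylation.

An ordered pair of ITAMs has 7 × 7 = 49 configurations.  The two ITAMs are
indistinguishable and the two tyrosines within an ITAM are treated as
having identical properties with random phosphorylation order, so the
dynamics close on the 28 unordered pairs {(s,t) : s ≤ t} = 7 + C(7,2).
`enumeratePairStates()` fixes the canonical ordering and the 49 → 28
bijection.  The test suite carries an independently coded brute-force
49-state model and checks that the reduced system reproduces it to 10⁻⁸ —
the symmetry reduction is verified, not assumed.

**Reactions.** Every step is first-order mass action with the active Lck
and free ZAP70 concentrations absorbed into the rate constants
(pseudo-first-order).  Per site: `U ⇌ P1` at 2·k_itam_p / 1·k_itam_dp·g(t)
(two ways to place the first phosphate), `P1 ⇌ P2` at 1·k_itam_p /
2·k_itam_dp·g(t), `P2 ⇌ Z` at k_on / k_off, `Z ⇌ Z319` at k_y319 /
k_y319_dp·g(t), `Z319_493 ⇌ Z493` at k_y319_dp·g(t) / k_y319 (the same
Y319 chemistry on the Y493-phosphorylated branch), and Y493
dephosphorylation `Z319_493 → Z319`, `Z493 → Z` at k_y493_dp·g(t).  ZAP70
unbinding applies identically from all four bound states; the departing
ZAP70 rejoins the implicit free pool, which stays constant and
unphosphorylated.  The single *pair-coupled* reaction is Y493
trans-autophosphorylation `Z319 → Z319_493` at k_y493, allowed only when
the opposing ITAM carries an opened (pY319) ZAP70 — two opened ZAP70
molecules must be juxtaposed.  Transitions out of symmetric states (s,s)
carry a combinatorial factor 2.

**Stimulation.** Pervanadate irreversibly inhibits tyrosine phosphatases;
it is modelled as an instantaneous drop of the phosphatase activity to
f_min at each dose with slow exponential recovery (time constant τ,
attributed to ongoing phosphatase synthesis):
g(t) = f_min + (1 − f_min)(1 − e^(−(t−t_dose)/τ)), resetting at every dose
and equal to 1 before the first.  g(t) multiplies all *dephosphorylation*
rate constants; it does **not** multiply k_off, which is not a
phosphatase-catalysed step.  The exponential form is one simple monotone
recovery; it sits behind a single function (`phosphataseActivity`) so that
an alternative form is a one-function change.

**Integration and steady state.** The field is linear,
dx/dt = (A₀ + g(t)A₁)x, so the analytic Jacobian is supplied to the
stiff-capable `deSolve::lsoda` integrator, and integration restarts at each
dose so the discontinuity in g is never stepped across.  The resting state
is the null vector of A₀ + A₁ (g ≡ 1), computed by SVD and normalised to
sum 1, with a long-time relaxation fallback; the returned state must have
residual ‖dx/dt‖∞ < 10⁻¹⁰.  Trajectories are returned without
renormalisation so that Σx = 1 along the trajectory remains a measurable
property of the integration (tested at 10⁻⁸).  At k_on = 0 the four ITAM
tyrosines decouple and the resting occupancies follow a closed-form
binomial product law, which the tests verify against the solver.

**Observables.** Per ITAM pair: `bound_Z` counts ITAMs in
{Z, Z319, Z319_493, Z493} scaled by s_Z; `bound_pY319` counts
{Z319, Z319_493} scaled by s_pY; `bound_pY493` counts {Z319_493, Z493} and
is never fitted — it is the model's prediction channel.  The scales are free
positive parameters because IP-FCM ratios are in arbitrary units.

## 3. Default parameters

The experimental time courses the model targets are published as figures,
not tables, so the package's defaults were chosen once, by simulation, to
reproduce the features the accompanying text states, and then frozen:

| parameter | default | unit | role |
|---|---|---|---|
| k_itam_p | 0.8 | 1/min | per-site ITAM phosphorylation by Lck |
| k_itam_dp | 60 | 1/min | per-site ITAM dephosphorylation |
| k_on | 6 | 1/min | ZAP70 binding (pseudo-first-order) |
| k_off | 0.1 | 1/min | ZAP70 unbinding |
| k_y319 | 0.04 | 1/min | Y319 phosphorylation by Lck |
| k_y319_dp | 0.4 | 1/min | Y319 dephosphorylation |
| k_y493 | 0.02 | 1/min | Y493 trans-autophosphorylation |
| k_y493_dp | 0.3 | 1/min | Y493 dephosphorylation |
| f_min | 0.02 | — | residual phosphatase activity after a dose |
| tau_rec | 200 | min | phosphatase recovery time constant |
| s_Z, s_pY | 1 | a.u. | observable scales |

At these values a single dose at t = 0 gives: bound ZAP70 peaking near
10 min and its Y319 phosphorylation near 20 min; a transient *dip* of the
bound pY319/ZAP70 ratio at 2 min below its resting value (the first
recruitment wave is unphosphorylated cytosolic ZAP70) followed by a rise
above it; a ~60-fold increase of bound ZAP70 from rest to peak; a resting
bound pool a few percent Y319-phosphorylated; and Y493 phosphorylation
rising and peaking later than Y319.  These defaults are the study
conditions of the synthetic generator (`genKineticDataset`), which adds
multiplicative lognormal replicate noise — 5 %cv and triplicates by
default, matching the replicate precision of the bead assay (measured %cv
4.0–7.2) — and never global RNG state: every generator takes an explicit
seed.

Default observation grid: {0, 2, 5, 10, 20, 60} min, the stimulation times
named in the experimental narrative; the exact acquisition grid of the
original experiment is not published, so this grid is a stand-in.

## 4. Fitting

`lossFunction` is plain unweighted least squares over both observables and
every replicate individually (replicates are not averaged first; their
scatter is information).  A variance-weighted scheme was considered and
left out: the assay noise is near-proportional and a weighted objective
would need per-point variance estimates triplicates cannot support.
Failed simulations inside the search return a large finite penalty so the
optimiser can walk out of bad regions.

`annealFit` searches a chosen parameter subset in log₁₀ space (rates span
orders of magnitude; bounds default to [10⁻⁴, 10³] per minute, f_min ≤ 1):
Gaussian proposals reflected at the bounds, Metropolis acceptance, geometric
cooling.  Two points matter in practice:

* **The initial temperature must match the objective scale at the
  starting point.** If the search starts far uphill, using that large
  objective as T₀ keeps the chain effectively hot for any short schedule
  and lets it wander onto the degenerate ridge where a tiny occupancy is
  compensated by a huge observable scale.  For recovery studies we pass an
  `initialTemp` on the scale of the data-level residual sum of squares.
* **A polish stage finishes the job.** Annealing locates the basin;
  restarted Nelder-Mead (two rounds, fresh simplex each time) converges
  within it.  It is on by default and bounded by the same box.

The fit is reproducible for a fixed seed, and the trace (iteration,
temperature, accepted and best objective) is returned for inspection; the
best-so-far objective is non-increasing by construction.

Parameter identifiability at this data volume (two observables, six times,
triplicates) is partial: the well-constrained quantities are the observable
*curves* and combinations such as resting levels, peak times and the
inhibition depth, not all twelve raw constants.  The package's recovery
study therefore scores curve recovery — normalised RMSE of the fitted
noiseless curves against the generating truth within the 5 % replicate
noise — rather than per-parameter agreement, and the toy two-parameter
problem (everything else held at truth) is where raw-parameter recovery
within 5 % is asserted.

## 5. What the synthetic data do and do not show

The generators emulate: lognormal fluorescence with additive lognormal
autofluorescence background; two bead-size scatter populations; the
four-rung PE ladder with a configurable gain; and model-derived kinetic
observables under multiplicative replicate noise.  They do not emulate
optical spillover/compensation (channels are treated as pre-compensated),
doublets or debris beyond what rectangular gates exclude, antibody binding
curves (saturating staining is assumed), acquisition drift between samples,
or biological deviation from the model itself.  Green tests therefore
certify the *computational* pipeline — gating, statistics, calibration
algebra, the symmetry reduction, the integrator, the optimiser — under the
model's own assumptions; they cannot certify that the mass-action scheme
describes any particular cell system.

## 6. Known limitations

* The Y493-before-Y319 peak ordering is a property of the slow
  trans-autophosphorylation regime that realistic data select, **not** of
  arbitrary rate combinations: when Y493 turnover is fast relative to its
  drive (k_y493_dp large), the pY493 peak can precede the pY319 peak
  slightly.  The package asserts the delay around the default regime and on
  fitted models, and `predictUnfitted` reports the flag rather than
  presuming it.
* Event tables are read from CSV; binary cytometer formats are out of
  scope for this package and should be exported to CSV upstream.
* The model has no spatial structure, no receptor clustering, no
  proximal/distal ITAM distinction, no explicit Lck activation dynamics,
  and tracks no phosphorylated species after ZAP70 unbinding (the free pool
  is constant and unphosphorylated).  The single-dose/double-dose
  comparison and the bound-versus-total resting ratio are exactly the kind
  of coarse-grained predictions such a model can support.
* Desk-scale problem sizes are used throughout the tests (hundreds to
  thousands of events per population, tens of annealing temperature
  levels); they were chosen as the smallest sizes at which the statistical
  assertions have comfortable margins.
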