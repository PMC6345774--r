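---
title: "Models and methods for the p53-peptide/MDM2 binding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for the p53-peptide/MDM2 binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53mdm2)
```

## The system and the question

The transactivation (TA) domain of p53 (here residues Glu17-Asn29) is
intrinsically disordered in solution but binds the N-terminal domain of
MDM2 as an amphipathic α-helix. Binding therefore couples folding to
association, and phosphorylation of Thr18 or Ser20 — or their Asp/Glu
phosphomimetics — tunes both the residual helicity of the free peptide and
the binding thermodynamics and kinetics. This package implements the full
quantitative analysis of that problem for a panel of thirteen capped
peptides: residual-structure estimation (CD, TFE titrations, NMR
conformational shifts, conformational ensembles), binding kinetics
(stopped-flow), equilibrium binding (fluorescence titrations, ITC), and
mass-action models that ask whether a one-step mechanism can explain the
data. The published parameter tables ship with the package
(`table_cd_helicity()`, `table_kinetics()`, `table_itc()`) and act as
inputs: every derived column can be recomputed from its printed inputs,
and every fitter can be exercised on synthetic data generated from those
values as ground truth.

## Helicity from CD

Raw ellipticity is converted to mean residue ellipticity
$[\Theta] = \theta_\mathrm{mdeg} / (10\,c\,l\,N)$
(deg cm² dmol⁻¹ residue⁻¹). The helix percentage is the linear estimate
$100\,[\Theta]_{222}/(-31500)$, using the standard fully-helical
reference value; estimates are clamped to [0, 100] and positive bands
warn, since a positive 222 nm signal (seen for the quadruple mutant,
whose spectrum suggests PPII/β-turn content) carries no helix
information.

TFE titrations are fitted to a two-state helix ↔ coil model with a
cosolvent-linear free energy,
$$[\Theta](x) = \frac{\theta_c + \theta_h K(x)}{1 + K(x)},\qquad
K(x) = \exp\!\left(-\frac{\Delta G_\mathrm{water} - m\,x}{RT}\right),$$
with $x$ in % v/v, $R = 1.987$ cal mol⁻¹ K⁻¹ and $T = 278.15$ K (the CD
experiments run at 5 °C); both are configurable. The sign convention is
$\Delta G_\mathrm{water} > 0$ for helix unfavourable in water, so all
fitted helix fractions $K_0/(1+K_0)$ fall below 50 %. The midpoint obeys
the exact identity $[\mathrm{TFE}]_{1/2} = \Delta G_\mathrm{water}/m$,
which the `tfe_fit` object preserves to machine precision. Baselines are
fitted as constants: over the short ranges available for 13-mers, sloped
baselines are not identifiable, and the constant-baseline fit reproduces
the published derived quantities. A fit is reported `sigmoidal = FALSE`
(and population estimates withheld) when the fitted midpoint is not
bracketed by the data or the amplitude $|\theta_h - \theta_c|$ fails a
95 % significance test — the situation of the phosphorylated peptides,
whose ellipticity drifts without a resolved transition.

## Helicity from NMR conformational shifts

Conformational shifts are $\Delta\delta = \delta_\mathrm{obs} -
\delta_\mathrm{RC}$ against caller-supplied random-coil references
(tabulated values; phosphorylated residues need references from
phosphorylated model peptides, which is why the package does not ship
them). A residue is random coil iff $|\Delta\delta| \le 0.1$ ppm
(boundary inclusive). Window helicity divides the mean of the *negative*
Hα shifts by the full-helix value of −0.39 ppm; positive shifts are
excluded rather than averaged in, because upfield shifts are the helical
signature and downfield excursions report other effects (ring currents,
phosphate). The estimate is reported unrounded: the Ser20-Leu25 window
with mean −0.21 ppm gives 53.8 %, the number behind the "about half"
population statement, with the usual ambiguity between *half the
residues always helical* and *all residues helical half the time*. The
downfield NH check for phospho residues is a boolean report only; no
quantitative threshold exists for it.

## Stopped-flow kinetics

Traces are averaged pointwise (warning below 4 replicates, the study's
practice) and fitted to $y = \mathrm{offset} + A e^{-k_\mathrm{obs}t}$.
Starting values are deterministic — offset from the tail mean, rate from
a log-linearised early decay — so fits are reproducible without random
restarts. An amplitude indistinguishable from zero at 95 % raises a "no
exponential behaviour" error, which is how the non-binding quadruple
mutant presents. Observed rates at several MDM2 concentrations are
regressed as $k_\mathrm{obs} = k_\mathrm{on}[\mathrm{MDM2}] +
k_\mathrm{off}$; weighting by $1/\sigma^2$ is available but off by
default (the published analysis does not state weighting). The kinetic
dissociation constant is $K_d = k_\mathrm{off}/k_\mathrm{on}$ with
first-order quadrature error propagation; a Monte-Carlo propagation is
provided, and the two agree within a few percent whenever the rate
errors are in the perturbative regime (relative error ≲ 0.3) — for
larger relative errors the ratio distribution grows heavy tails and no
scalar error bar is meaningful. A negative fitted intercept is flagged,
never clamped. No dead-time correction is applied (the instrument dead
time is not stated).

Because the y-axis intercept is an extrapolation, its standard error
exceeds the precision of the fitted line inside the measured
concentration range several-fold; this extrapolation penalty is the
reason dissociation-rate errors dominate the kinetic $K_d$ error.

## Fluorescence titrations (tight binding)

With MDM2 fixed at 4 μM and peptide titrated to 10 μM, free and total
concentrations differ materially, so the quadratic (tight-binding)
isotherm is fitted:
$$F = F_0 + \frac{\Delta F_\mathrm{max}}{2 M_T}\left[(M_T + P_T + K_d)
 - \sqrt{(M_T + P_T + K_d)^2 - 4 M_T P_T}\right].$$
The discriminant is clamped at zero before the square root: it is
algebraically non-negative but floating-point cancellation can push it
below zero near the stoichiometric corner. Blank subtraction (peptide
intrinsic fluorescence) is a separate preprocessing step, with a warning
when supplied absorbance exceeds 0.2 (inner-filter regime). Replicate
curves are fitted jointly with shared parameters. Fits with
$\sigma_{K_d} > K_d$ or insignificant amplitude carry a
`poorly_determined` flag — the small-amplitude situation responsible for
the large published titration errors.

## ITC

Injection heats may come directly or from a raw power trace via a
simplified integrator: per-injection baselines are linearly interpolated
between pre-injection quiet windows and heats are trapezoidal integrals
of (power − baseline). Overlap (no return to baseline before the next
injection) is flagged by comparing quiet-window levels to the
pre-titration baseline, which assumes negligible instrument drift.

The dilution correction subtracts the mean heat of the post-saturation
plateau (default: last 4 injections, accepted when their spread passes a
tolerance or, absent one, a 95 % trend test; explicit indices override).
The 1:1 isotherm uses exact displacement bookkeeping — each injection of
volume $v$ scales cell concentrations by $(1 - v/V_0)$ and delivers
$v/V_0$ of syringe titrant — and predicts differential heats
$\Delta H \, V_0\, \Delta[\mathrm{complex}]$. Free parameters are
$(n, \log_{10} K_A, \Delta H)$; alternatively the stoichiometry is fixed
at 1 and the binding-competent fraction of the nominal cell
concentration floats, the parameterisation that rationalises apparent
stoichiometries near 0.25 from partially aggregated MDM2 preparations.
The first (0.5 μl) injection is excluded by default. An optional
constant per-injection offset absorbs residual mis-subtraction of the
dilution heat: for weak binders the "plateau" still contains binding
heat, and subtracting it without the nuisance term biases
$\log_{10} K_A$ upward by as much as 0.4 at Wiseman $c \approx 2$. A $c$
value ($K_A n [\mathrm{cell}]$) outside ~1–1000 warns.

Decomposition uses $K_d = 10^{-\log_{10} K_A}$,
$\Delta G = -RT\ln 10 \cdot \log_{10} K_A$ with
$R = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹ and $T = 288.15$ K (15 °C, below
the aggregation temperature of MDM2), and $T\Delta S = \Delta H - \Delta
G$; the identities hold to machine precision. Recomputing the entropic
column of the calorimetric table from its printed $\Delta H$ and
$\log_{10} K_A$ reproduces every determined row within 0.06 kcal mol⁻¹
*except* wild type, whose printed −3.23 recomputes to −2.52; the
package documents rather than repairs that internal inconsistency, and
the P53-pS row misses the 0.05 kcal mol⁻¹ band by 0.008, beyond what
rounding of its printed inputs can explain.

## Mechanism models

Three mass-action schemes are integrated with a stiff-capable solver
(lsoda, tight tolerances), with mass conservation verified at every
output point:

* **two-state** — P + M ⇌ C;
* **conformational selection** — Pᵤ ⇌ Pₕ (rates $k_f$, $k_u$) followed by
  Pₕ + M ⇌ C: only the pre-folded helical conformer binds;
* **induced fit** — P + M ⇌ C* followed by C* ⇌ C (rates $k^*_\mathrm{on}$,
  $k^*_\mathrm{off}$): folding happens on MDM2.

The probe signal is total bound peptide with equal weights by default (a
Trp probe may in reality weight the intermediate differently; the weight
vector is configurable). Apparent equilibrium dissociation constants,
referred to total free peptide and total complex, are
$k_\mathrm{off}/k_\mathrm{on}$,
$(k_\mathrm{off}/k_\mathrm{on})(1 + k_u/k_f)$ and
$(k_\mathrm{off}/k_\mathrm{on})/(1 + K^*)$ with
$K^* = k^*_\mathrm{on}/k^*_\mathrm{off}$. Observed rates are extracted
by the kinetics module's exponential fitter; the reported rate comes
from a refit restricted to $t \ge 1/k_\mathrm{obs}$, because even in
excess the binding partner depletes slightly and the tail is governed by
the slowest eigenmode of the linearised system (available directly from
`relaxation_rates()` as an oracle). The single-exponential flag uses the
whole-trace residual structure.

This machinery grounds the central mechanistic inference: for wild type
the kinetic ratio gives 5.6 μM while ITC gives 1.8 μM. A one-step
mechanism forces these to coincide (and the simulator confirms it to
within the pseudo-first-order approximation), whereas an induced-fit
step with $K^* \approx 2.1$ — a modestly favourable post-binding folding
step — reconciles them exactly. One caveat is quantitative: at the
minimum 8-fold excess used experimentally, the pseudo-first-order
approximation itself biases the refitted constants by up to ~2 % (the
intercept absorbs $k_\mathrm{on}[\mathrm{P}]_\mathrm{eq}$), so
consistency checks are run at ≥ 30-fold excess where the approximation
error is negligible.

## Ensembles, free-energy surfaces and helix propensity

Synthetic backbone ensembles are built residue-by-residue with ideal
geometry: helical residues (probability per residue) receive
$(\phi, \psi) = (-60°, -45°)$, coil residues draw
$\phi \in (-180°, -50°)$ and $\psi \in (60°, 180°) \cup (-180°, -150°)$
uniformly — a basin covering β/PPII while excluding α. Only Cα-level
RMSD/Rg statistics are consumed downstream, so fixed bond lengths and
angles are adequate. RMSD to the bound-form reference uses Kabsch
superposition (proper rotations only); Rg is mass-uniform over Cα atoms.
The FES is $-\ln(\mathrm{population})$ over a 2D histogram of (RMSD,
Rg), shifted to zero at the occupied minimum, with unsampled bins marked
`NA` rather than given a numeric level — downstream consumers must treat
missingness explicitly. Default 50 × 50 bins; all units nm internally,
with Å accepted on PDB input. Helix propensity counts residue-frames
with $\phi \in [-100°, -30°]$ and $\psi \in [-67°, -7°]$; termini are
undefined (`NA`), never zero. The dihedral window is one defensible
criterion among several — DSSP-style assignments would differ near basin
edges — so absolute propensities from other analyses are not expected to
match exactly.

## The synthetic-data generator, and what passing tests show

Every generator draws i.i.d. Gaussian noise on the signal, the standard
model for shot-noise-dominated photomultiplier/CD/ITC data at these
levels; identical (parameters, seed) give bit-identical output. The
study conditions are encoded as defaults: stopped-flow peptide at
0.125 μM with MDM2 at 1–3 μM, fluorescence titrations of 0–10 μM peptide
into 4 μM MDM2, TFE titrations of a 40 μM peptide at 5 °C, ITC with one
0.5 μl then nineteen 2 μl injections at 15 °C. Where the source
measurements leave a value unstated it was chosen once as realistic and
not revisited: per-point noise of 1 % of the kinetic amplitude, 2 % of
the fluorescence amplitude, 1 % of the CD baseline span, 0.15 μcal per
injection; ITC concentrations of 50 μM MDM2 (cell) and 750 μM peptide
(syringe), set so the Wiseman $c$ spans 1.8–27 across the peptide panel
(weaker concentrations would leave the 25 μM-$K_d$ peptides below
$c = 1$, which no calorimetrist would run).

The generator emulates the *functional form* of each experiment, not the
instruments: no correlated noise or drift, no aromatic side-chain
contributions to the 222 nm band, no ITC instrument response beyond
simple peaks, and ensembles with neither side chains nor tertiary
interactions. Passing recovery tests therefore demonstrate that the
fitters are unbiased and correctly error-calibrated for data obeying the
stated models — they do not certify behaviour under real-instrument
artefacts, and the absolute FES and helix-propensity surfaces of real
trajectory data are outside what synthetic ensembles can validate.

## Problem sizes and runtime choices

Tests and the acceptance script run at desk scale: 100-replicate
coverage checks for noisy recovery (each fit on 20–150 points),
ensembles of 0.4–2 × 10³ frames for binomial checks at ±0.03, ODE
trajectories of 300–1000 points, and 25-replicate medians for the
reported recovery quantities (a single TFE replicate at the
property-test noise level has ~30 % midpoint scatter; the median is the
stable run-time measurement). These sizes were chosen as the smallest
that leave the statistical assertions comfortably powered.

## Known limitations

* Constant CD baselines are an approximation; the original fitting
  software's baseline treatment is not printed, so derived values match
  but the parameterisation may differ.
* The plateau-based dilution correction is principled only at true
  saturation; for weak binders prefer the floating-offset fit.
* Quadrature error propagation for $K_d$ is first-order only.
* The displacement dilution model is one of several instrument
  bookkeeping conventions; others differ at the fraction-of-percent
  level for 2 μl injections into 200 μl.
* Mechanism fitting to experimental traces is out of scope: the schemes
  are simulators and hypothesis tests, not estimators.
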