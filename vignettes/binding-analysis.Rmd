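---
title: "Models and methods for optical binding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for optical binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindkit)
```

bindkit analyses the optical experiments used to characterise how a
small-molecule ligand binds a biomacromolecule (serum albumin or
double-stranded DNA): fluorescence quenching titrations, continuous-variation
(Job's) mixtures, competitive dye displacement, viscometry, and supplied
frontier-orbital and drug-likeness property tables. This vignette states the
models, the assumptions behind them, the defaults, and the numerical
decisions, so that results can be interpreted — and distrusted — correctly.

## Units and data model

All computation is in SI-consistent units: concentrations in mol/L,
temperatures in kelvin, times in seconds. Micromolar concentrations and
degrees Celsius are accepted only at the file-reading boundary
(`read_titration_table()` converts a `conc_uM` column by 1e-6 and
`temperature_C` by +273.15). Mixing unit systems inside the regression and
thermodynamic formulas is the classic source of silently wrong binding
constants, since Ksv and Kb are reported in L/mol while titrations are
pipetted in µM.

A titration series must start with a zero-concentration point: its signal
*is* F0, the reference intensity of the free macromolecule. F0 is never
estimated by extrapolation — the experiment measures the pure
macromolecule first, and treating F0 as a fitted quantity would let the
reference drift toward the fit. Duplicate concentrations are rejected
rather than averaged: replicates belong in separate series, and averaging
inside a series would hide heteroscedasticity from the fit diagnostics.

## Stern–Volmer quenching

For a fluorophore quenched by a ligand Q, the Stern–Volmer relation

$$\frac{F_0}{F} = 1 + K_{sv}[Q] = 1 + k_q \tau_0 [Q]$$

is linear in [Q] for either purely static (ground-state complex) or purely
dynamic (collisional) quenching. `stern_volmer_fit()` performs ordinary
least squares of $F_0/F$ on $[Q]$ over *all* points, including the
$([Q]=0,\,y=1)$ reference — it is a measured datum, not a constraint. The
intercept is fitted free rather than pinned to 1: a free intercept exposes
inner-filter and dilution artefacts, and a deviation beyond 0.05 attaches a
warning instead of silently renormalising the data. A diagnostic quadratic
refit with a significantly positive curvature term (p < 0.05) attaches a
"possible mixed quenching" warning; the reported Ksv always remains the
slope of the linear fit, since upward-curved plots are reported, not
re-modelled.

The bimolecular quenching constant $k_q = K_{sv}/\tau_0$ uses the
conventional average biopolymer fluorescence lifetime $\tau_0 = 10^{-8}$ s;
it is a supplied constant, never fitted (no time-resolved data enters the
package). Mechanism classification combines two standard diagnostics:

* **magnitude** — $k_q$ above the maximum diffusion-controlled (scattering)
  rate constant, default $10^{10}$ L mol⁻¹ s⁻¹, is incompatible with purely
  collisional quenching and indicates ground-state complexation;
* **temperature trend** — static complexes dissociate on heating (Ksv
  non-increasing), collisional quenching accelerates (Ksv strictly
  increasing).

The classifier returns *static* when every $k_q$ exceeds the limit and the
trend is non-increasing (or only one temperature exists — magnitude alone
suffices); *dynamic* when Ksv strictly rises and every $k_q$ stays within
twice the limit (the 2× grace absorbs the spread of literature
diffusion-limit values, which range from 1 to 2 ×10¹⁰); *mixed* when $k_q$
is super-diffusional yet Ksv still rises; otherwise *indeterminate*. A
single temperature with sub-limit $k_q$ is deliberately indeterminate:
without a trend, sub-limit $k_q$ is merely consistent with dynamic
quenching, not evidence for it. Ties and plateaus in the trend count as
non-increasing so that measurement noise cannot flip a static call.

## Binding constant, site number, free energy

The double-log binding relation

$$\log_{10}\frac{F_0 - F}{F} = n\,\log_{10}[Q] + \log_{10} K_b$$

assumes the quenched fraction reports occupancy of $n$ equivalent
independent sites. Base-10 logarithms are used throughout (so an intercept
of 5.2 means $K_b \approx 1.6\times10^5$ L/mol); the natural logarithm
appears only inside $\Delta G^\circ = -RT\ln K_b$, computed with
$R = 1.9872\times10^{-3}$ kcal mol⁻¹ K⁻¹ so free energies land in kcal/mol.
Celsius temperatures convert as 25/30/35 °C → 298.15/303.15/308.15 K.

Points with $F \ge F_0$ (non-quenched) and the zero-concentration reference
are excluded from the double-log fit — their logarithm is undefined — and
every exclusion is reported with its index and reason rather than silently
clipped. At least three eligible points are required.

When the data follow the 1:1 static model exactly, $(F_0-F)/F = K[Q]$, so
the double-log fit returns $n = 1$ and $K_b$ identical to the Stern–Volmer
Ksv; this algebraic equivalence is asserted in the test suite to 1e-6.

A caution on reference tables of this kind: published
$\log_{10}K_b$ / $K_b$ / $\Delta G^\circ$ triplets are typically rounded
independently and can disagree with each other by ~0.1–0.2 kcal/mol (the
bundled `tzp_binding_constants()` table does). The package always reports
full-precision values from its own fits; comparisons against such tables
should use tolerances of that order, which is what the acceptance tests do
(±0.25 kcal/mol on ΔG°).

## Job's method of continuous variation

Mixtures with ligand mole fraction $x$ at fixed total concentration $C_T$
(default 20 µM, a typical working concentration for protein–ligand UV work)
form an m:n complex whose concentration peaks at $x = m/(m+n)$. The
"corrected absorbance" is the mixture absorbance minus the mole-fraction
weighted free-component contributions,
$A_{corr}(x) = A_{mix} - (1-x)A_{macro} - xA_{lig}$ — the standard
continuous-variation correction, applied only when component blanks are
supplied; otherwise inputs are taken as pre-corrected, and the curve records
which path was used.

The maximum is located by fitting a parabola through the grid maximiser and
its two neighbours and taking the vertex (clipped to the neighbour
interval). Grid argmax alone would quantise $x_{max}$ to the measurement
grid — a 9-point grid cannot distinguish 0.5 from 0.46 — while the local
quadratic uses the curvature information the curve actually carries. A
maximum on the grid boundary indicates a monotone curve (no interior
optimum); refinement is skipped and a warning raised. The integer-ratio
search is capped at 3:3 with a snapping tolerance of 0.08: a 9-point
continuous-variation grid cannot reliably resolve ratios beyond 3, whose
theoretical maxima are separated by less than the grid spacing.

## Binding-mode evidence and the verdict

Three assay families vote on groove binding versus intercalation:

* **UV titration**: hyperchromism or a red shift of the macromolecule band
  (thresholds 2% intensity, 1 nm) hints groove binding; hypochromism or a
  blue shift hints intercalation. Conflicting signals (e.g. hyperchromic
  but blue-shifted) yield no hint.
* **Dye displacement**: Hoechst 33258 occupies the minor groove, ethidium
  bromide intercalates; a ligand displaces the probe sharing its mode,
  quenching the dye–DNA emission. Displacement requires both magnitude
  (≥5% fractional decrease by default) and a monotone trend (Spearman sign
  check) — a single-point dip is not displacement. The 5% default is a
  declared package choice; qualitative reports rarely state one.
* **Viscometry**: intercalation lengthens the helix, so
  $(\eta/\eta_0)^{1/3}$ — proportional to contour length — rises with the
  ligand/DNA ratio, while groove binders leave it flat. Replicate flow
  times are averaged arithmetically per sample; relative viscosity is
  $(t_{complex}-t_0)/(t_{DNA}-t_0)$ (the buffer-time denominators of the
  textbook form cancel). The slope threshold of 0.05 per unit ratio
  separates flat from rising; significantly negative slopes are left
  indeterminate rather than interpreted.
* **Circular dichroism** enters only as a supplied boolean (bands perturbed
  or not); CD spectral modelling is out of scope.

The combiner demands at least two evidence sources, returns *groove* only
with ≥2 groove votes and zero intercalative votes (symmetrically for
*intercalative*), and lists every vote in its rationale. Requiring
concordance without dissent mirrors how such studies triangulate orthogonal
assays, and guarantees the verdict can never contradict a dissenting
source — a property the tests verify by exhaustive enumeration of vote
patterns.

## Reactivity descriptors and drug-likeness

Orbital energies arrive as data (computed upstream by quantum-chemistry or
force-field software; the package never computes them). Under Koopmans'
theorem IP = −E_HOMO and EA = −E_LUMO, and the conceptual-DFT global
descriptors follow: gap ΔE = IP − EA, hardness η = ΔE/2, softness
S = 1/(2η), electronegativity χ = (IP+EA)/2, chemical potential µ = −χ,
electrophilicity ω = µ²/(2η). All are exact identities of the two inputs;
the test suite checks them to 1e-12 and checks recomputed descriptor tables
against their published three-decimal values to |Δ| ≤ 0.005, since tables
of this kind round intermediates before deriving ω. A zero HOMO–LUMO gap
leaves softness and ω undefined and is an error, not an Inf.

Rule-of-five evaluation counts violations among MW > 500, cLogP > 5,
HBA > 10, HBD > 5 with *inclusive* boundaries (a compound at exactly 500
g/mol does not violate), flags TPSA > 140 Å² separately (passive-absorption
limit), and predicts oral bioavailability when at most one rule is violated
and TPSA is acceptable.

## Synthetic data: what it emulates, and what it does not

Every generator is a deterministic function of its parameters including the
seed (RNG state is isolated via `withr::with_seed`, so generators do not
disturb the session RNG). Noise is multiplicative Gaussian with a stated
coefficient of variation, truncated at ±4σ so signals stay positive —
fluorescence error scales with intensity, which additive noise would
misrepresent. The zero-concentration point is never noised: F0 is exact by
construction, mirroring its role as the reference in both fits. The default
test CV of 2% is a declared assumption about a well-run fluorimeter, not a
measured value.

The generators invert the analysis models exactly: static quenching as
$F = F_0/(1 + K_{sv}[Q])$, the binding model as
$F = F_0/(1 + K_b[Q]^n)$, viscometry by back-computing flow times from a
target cube-root slope, Job mixtures from the mass-action 1:1 quadratic
(the smaller root of $C^2 - (P+L+1/K)C + PL = 0$, which respects both mass
balances). General m:n Job curves use the strong-binding limiting-reagent
approximation min(L/m, P/n) — adequate for locating maxima, not for
curvature studies; this is a documented limitation. The default titration
grid is 0–48 µM in 8 µM steps, a typical ligand-titration layout.

Because generation inverts the same functional forms the fitters assume,
passing round-trip tests demonstrates correct estimation *under the model*:
it does not validate the models against real spectra, nor does it exercise
inner-filter effects, photobleaching, dilution drift, or instrument
response, none of which are simulated. Parameter-recovery claims (median
relative Ksv error ≤5% and median site-number error ≤0.05 at 2% CV over
500 seeds) hold for titrations designed the way a practitioner would design
them — the binding-decade study spans one decade of [Q] bracketing the
half-quench concentration ($K_b[Q]^n \approx 1$); a decade placed far below
half-saturation carries much less information about $\log_{10}K_b$ because
the intercept is then a long extrapolation.

## Problem sizes and tolerances in the test suite

Fixtures use 7–9 point titrations; Monte-Carlo properties use 500 seeded
replicates (quenching and binding recovery) and 100 seeded profiles per
class (viscosity classifier, slopes 0 vs 0.5 at 1% CV, required 100%
correct). Noiseless round trips are checked at 1e-6 to 1e-9 relative —
closed-form inversions should be exact to numerical precision. Identity
relations (kq·τ0 = Ksv, the Koopmans identities, mass balance) are checked
at 1e-12.

## Known limitations

* No inner-filter or dilution correction of raw signals; series are
  analysed as given.
* τ0 is always supplied, never fitted; no time-resolved analysis.
* No van't Hoff ΔH/ΔS decomposition — the thermodynamic summary stops at
  ΔG° per temperature.
* No estimation of K from Job-curve curvature, and no quantitative CD.
* cLogP, TPSA, orbital energies and similar upstream descriptors are
  consumed, never computed.
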