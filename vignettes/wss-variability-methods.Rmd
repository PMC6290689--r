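---
title: "Methods: standardized aneurysm WSS parameters and cohort variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardized aneurysm WSS parameters and cohort variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wssvar)
```

## The problem

Image-based CFD of intracranial aneurysms predicts wall shear stress (WSS)
on the lumen wall, a quantity widely studied in relation to aneurysm growth
and rupture. When many teams model the *same* aneurysms independently —
choosing their own segmentations, inflow rates, blood properties and solvers
— their WSS predictions disagree, and quantifying that disagreement requires
a *centralized*, standardized post-processing pipeline applied identically to
every submission. `wssvar` implements such a pipeline, modelled on the
centralized analysis of the 2015 International Aneurysm CFD Challenge (five
middle-cerebral-artery bifurcation aneurysms, 26 teams, 28 submitted
datasets): it computes per-submission parent-artery and sac hemodynamic
parameters from surface WSS fields and cross-sectional velocity data, then
summarizes inter- and intra-team variability with nonparametric statistics.

## Per-submission parameters

Inputs per submission are (i) a triangulated lumen surface carrying a
per-vertex WSS-magnitude field (mm, Pa), assumed co-registered so that one
set of region definitions applies; (ii) planar cross-section patches with
per-vertex velocity vectors, or magnitudes when a team supplied only those
(cm/s); and (iii) region definitions: clipping planes for the aneurysm sac
and for a parent-artery (MCA) band, one to five transverse slice planes, and
one slice per outlet with the dominant outlet labelled.

**Parent artery.** Each transverse slice contributes a lumen area $A$ (planar
section of the surface, shoelace formula on the chained intersection loop)
and a mean through-plane velocity
$\bar V = \tfrac1A \int \mathbf v\cdot\mathbf n\, dA$ (linear per-triangle
quadrature; $\tfrac1A\int |\mathbf v|\,dA$ in magnitude mode). Area and
velocity are averaged arithmetically over the slices, and the averages give

* effective diameter $D = 2\sqrt{A/\pi}$ (circular cross-section assumption),
* flow rate $Q = A \bar V$ (mm² · cm/s = 10⁻² mL/s, exact factor),
* Reynolds number $Re = \rho \bar V D / \mu$ (evaluated in SI),
* Poiseuille WSS $\tau_P = 32\,\mu Q / (\pi D^3)$,
* calculated WSS $\tau_c$: the vertex-area-weighted mean of the submitted
  WSS field over the clipped parent band, and the ratio $\tau_c/\tau_P$,
* outflow division: the dominant outlet's share of total outlet flow, with
  outlet flows integrated from the outlet patches.

The Poiseuille formula includes $\pi$. The challenge's report prints the
parenthetical "32 × viscosity × flow/diameter³", but its own tabulated
values (e.g. 8.25 Pa for μ = 4.0 cP, Q = 2.72 mL/s, D = 2.38 mm) are
reproduced only with $\pi$ in the denominator; without it every value would
be ≈ 3.14× larger.

**Aneurysm sac.** After clipping the sac with the case's neck plane(s):
AWSS (area-weighted mean WSS), MWSS (maximum vertex WSS, deliberately
unrobustified — the definition is the sac maximum), and LSA, the fraction of
sac area with WSS < 0.4 Pa. Normalized variants divide by the parent WSS:
AWSS* = AWSS/τ_c, MWSS* = MWSS/τ_c, and LSA* uses the relative threshold
0.1 τ_c. Both thresholds (0.4 Pa, 0.1) are configuration parameters.
Steady and time-averaged pulsatile fields are treated identically; OSI and
other time-resolved metrics are out of scope.

## Geometry: exactness choices

* **Clipping** splits triangles along each plane exactly (Sutherland–Hodgman
  per triangle, new vertices deduplicated per cut edge, fields interpolated
  linearly), so region areas carry no whole-triangle resolution bias. The
  kept and discarded sides of a plane partition the original area to within
  accumulation error, which the tests assert at 10⁻⁹ relative. After all
  planes, the connected component containing the vertex nearest a per-region
  seed point is selected, which is how the sac is isolated even where
  surfaces overlap or a plane grazes another vessel.
* **LSA** is measured on exactly split sub-triangles at the threshold
  isocontour of the piecewise-linear field — the same exactness rationale,
  since LSA is itself an area fraction. A vertex-lumped estimate is kept as
  a cross-check (`lsa_method = "lumped"`) and the two agree under
  refinement.
* **Surface averages** use vertex-lumped weights (one third of each incident
  triangle's area): exactly conservative and simple to verify.
* **Sections**: intersection segments are chained via their mesh-edge keys,
  so loop closure is a topological property and an open contour is reported
  as an error with the offending degree. Among multiple loops the one whose
  centroid is nearest the plane origin is the lumen contour (region
  definitions place slice origins inside the target vessel).
* Degenerate inputs: zero-area triangles contribute nothing; planes that
  miss the mesh, empty clip regions, seeds on the discarded side, non-planar
  patches, and ambiguous velocity fields all raise explicit errors.

## The synthetic cohort and its ground truth

There is no public fixture small enough to test a whole challenge, so the
package generates one. The reference geometry is deliberately idealized —
a straight parent tube (D₀ ≈ 2.45 mm, the cohort median), a spherical sac
(~8 mm, the challenge's case size), two daughter branches whose cubed
diameters set the outflow split — because idealization is what buys
closed-form ground truth for *every* pipeline output.

The sac WSS profile is axisymmetric and linear in $u=\cos\theta$ (polar
angle from the dome apex), rising from `sac_apex_frac`·τ_c at the apex to
`sac_neck_frac`·τ_c at the neck ($u_n$ = `sac_neck_cos`). Because the
spherical area element is uniform in $u$, the closed forms are elementary:
cap area $2\pi a^2(1-u_n)$, AWSS = τ_c(a_f+n_f)/2, MWSS = τ_c n_f, and
LSA(τ) = clamp(((τ/τ_c)−a_f)/(n_f−a_f), 0, 1). The defaults a_f = 0.01,
n_f = 1.11 put AWSS* at 0.56 (the cohort median) and keep the low-shear cap
large enough that the mesh resolves it; `oracle_metrics()` evaluates all
closed forms without any mesh, and the tests also check them against direct
numeric quadrature. Velocity patches carry the parabolic profile
$v(\rho) = 2\bar V(1-(2\rho/D)^2)$, whose exact mean is $\bar V$.

The tube, sphere and branches are separate connected components that overlap
at the junctions instead of being stitched watertight. Every analysed region
(sac cap, parent band, slices) is bounded by planes away from the junctions
and selected per connected component, so the junction geometry never enters
any metric and each region keeps its closed form. This is the one deliberate
departure from a watertight mesh, traded for exact oracles.

**Perturbation model.** Each virtual team draws a strategy that mirrors the
challenge's questionnaire frequencies: inflow scaling law Q ∼ Dⁿ with
n ∈ {0, 1, 2, 3, other} at frequencies (6, 2, 10, 4, 4)/26 ("other" draws a
continuous exponent on [0, 3]); viscosity {3.5, 3.7, 4.0} cP at
(12, 2, 12)/26; density 1.055 g/cm³ with probability 22/26, else uniform on
[1.00, 1.05]; experience high/medium/low at (5, 13, 8)/26. Per dataset and
case, a diameter scale ε ∼ lognormal(0, σ_D) models segmentation error and
rescales the whole geometry; the team's flow follows its law,
Q = 2.43·(D/2.45)ⁿ mL/s (2.43 mL/s is the literature mean MCA flow). A
lognormal shape factor (median 1.5, sdlog 0.16) multiplies the tube WSS
field relative to τ_P, emulating the non-developed velocity profiles of real
parent arteries (the challenge's median calculated:Poiseuille ratio was 1.5).
σ_D defaults to 0.034; note that a lognormal with sdlog σ has quartile CoD
tanh(0.6745σ) ≈ 2.3% at this value, the same order as the challenge's 3.4%
diameter CoD. Two teams contribute a second dataset from an independent ε
draw (paired a/b submissions sharing one strategy), so the default 26 teams
yield 28 datasets. Everything is reproducible from one integer seed.

What this emulates — and what it does not. The generator reproduces the
*input-driven* variability of a challenge cohort (inflow scaling, rheology,
segmentation scale, profile shape) with exact bookkeeping. It does not
emulate morphological segmentation differences (necks, blebs, smoothing),
solver/discretization error, registration error, or outliers such as
unit mistakes. Consequently the normalized sac metrics, which are defined
relative to each team's own parent WSS, are *exactly* invariant across
virtual teams — the mechanism behind the real cohort's drop in dispersion
after normalization (case-average CoD 48% for AWSS vs 18% for AWSS*), in
idealized-pure form (CoD → 0). Passing tests therefore validate the
pipeline's measurement and statistics, not any claim about real inter-team
variability.

## Statistics

Distributions of the derived parameters are generally non-normal, so
summaries are median, IQR (Q₁–Q₃) and the quartile coefficient of dispersion
CoD = (Q₃−Q₁)/(Q₃+Q₁), extended with the 10th/90th percentiles since the IQR
covers only half the datasets. Quantiles use linear interpolation at rank
p(n+1) clamped to [1, n] — R's `type = 6`, matching GraphPad Prism, the
analysis software behind the published tables; the estimator is a
configurable argument. Case-average statistics average each team over the
cases, and a team missing *any* case for a parameter is excluded from that
parameter's case-average set entirely.

Hypothesis tests follow the challenge's choices: D'Agostino–Pearson omnibus
K² for normality (hand-coded from the standard skewness/kurtosis
z-transformations and cross-checked against an independent implementation),
and Kruskal–Wallis with Dunn's post hoc z-tests across cases and experience
levels at α = 0.05. The Dunn familywise adjustment is Bonferroni by default
(Prism's convention for multiplicity-adjusted Dunn tests; the published
report does not state the correction) and is configurable. Intra-team
comparisons use the symmetric percent difference 200·|b−a|/(a+b); rank-order
consensus counts, per rank, the teams naming each case, with a *strict*
majority (> half) required — 13 of 26 is not consensus. Rank ties are broken
deterministically by case-label order and flagged.

For the published-table regressions, rows whose printed integers cannot be
recovered from their printed (rounded) inputs are flagged in the shipped
CSVs and checked to one reporting unit instead; the known case is the
diameter CoD row, where quartiles printed to 0.01 mm are too coarse to pin a
CoD printed to 0.1%.

## Problem sizes and tolerances

Default mesh density (`resolution = 1`) is 64 circumferential segments, 4
axial rings per mm, and a 64-row sphere (~20k triangles per submission);
at this density the unperturbed reference case recovers D and Q within 0.5%,
AWSS/MWSS within 0.1%, and LSA within 1.3% of the closed forms, and the
worst metric error shrinks by ~4× per resolution doubling (second-order
convergence of inscribed facets and linear quadrature). Cohort-scale runs in
the analysis scripts and tests use `resolution` 0.3–0.5 (3–5k triangles),
chosen because CoD-type statistics are scale-invariant and therefore immune
to the common-mode discretization bias that dominates at coarse resolution;
the simulated challenge (28 datasets × 5 cases) completes in under a minute
at 0.5. Monte-Carlo checks use 200-team cohorts for point recovery and
~10⁵ closed-form draws for the CoD sampling intervals.

One floating-point subtlety is worth recording: multiplying every WSS field
by a constant changes AWSS/MWSS/LSA but must leave AWSS*/MWSS*/LSA*
unchanged. For a power-of-two constant the invariance is bit-exact (IEEE-754
scaling is exact); for other constants, such as 10, each vertex value rounds
once, so the normalized metrics agree to ~10⁻¹⁵ relative rather than
bitwise. The tests assert both forms.

## Limitations

Registration of submissions is assumed done (region definitions are inputs);
pulsatile dynamics, OSI and spectral metrics are out of scope, as are
segmentation and CFD solving themselves. The generator's geometry is
idealized, its components are not stitched watertight, and its perturbation
menus are frequency-matched but independent (no correlation between, say,
experience and strategy). Published cohort-level medians (e.g. AWSS 4.57 Pa)
depend on the 28 real datasets and are not reproducible from this package;
they are covered only through the printed-quartile and percent-difference
regressions plus the property-based tests above.
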