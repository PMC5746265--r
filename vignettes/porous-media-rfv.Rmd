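---
title: "Porous-media hemodynamics of coiled aneurysms: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Porous-media hemodynamics of coiled aneurysms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After endovascular coiling of a cerebral aneurysm, a fraction of
aneurysms recanalize: blood re-enters the coiled sac and the patient may
need re-treatment. Morphological risk factors (large dome, wide neck,
low coil packing density) are well known but individually weak. The
hypothesis this package operationalizes is hemodynamic: recurrence is
driven by the volume of the coiled dome in which blood keeps moving
faster than a threshold speed. That quantity — the **residual flow
volume (RFV)**, here the dome volume with cell-centre speed strictly
above 1 cm/s — can be computed *before* coiling by simulating the coil
mass as a porous medium, and then fed into a standard risk-prediction
workflow.

`coilflow` implements that chain end to end at desk scale: idealized
geometry instead of patient angiography, a 2D solver instead of a
commercial 3D code, and a synthetic cohort generator instead of patient
records. Every downstream definition (RFV, neck zones, the statistics
pipeline) is the clinical one.

## Flow model

Blood is an incompressible Newtonian fluid (density $\rho = 1056$
kg/m$^3$, viscosity $\mu = 0.0035$ Pa·s), in laminar flow:

$$\nabla \cdot \mathbf{v} = 0, \qquad
\frac{\partial \mathbf{v}}{\partial t}
 + (\mathbf{v}\cdot\nabla)\mathbf{v}
 = -\frac{1}{\rho}\nabla p + \frac{\mu}{\rho}\nabla^2 \mathbf{v}
 + \mathbf{F} - \frac{K(|\mathbf{v}|)}{\rho}\,\mathbf{v}\,\chi_{dome}.$$

The last term is the coil model: inside the dome (indicator
$\chi_{dome}$) the momentum sink $-K\mathbf{v}/\rho$ with the
quasilinear packed-bed resistance

$$K = \alpha\,|\mathbf{v}| + \beta, \qquad
\alpha = \frac{1.75\,\rho\,(1-\kappa)}{\kappa^3 D_P}, \qquad
\beta = \frac{150\,\mu\,(1-\kappa)^2}{\kappa^3 D_P^2},$$

the Ergun coefficients of a bed of uniform particles of diameter $D_P$
at porosity $\kappa$. Porosity follows from the packing density
$PD = 100\,CV/DV$ (coil volume over dome volume, %) as
$\kappa = 1 - PD/100$. $D_P$ defaults to 0.010 in $= 2.54\times10^{-4}$
m, the primary diameter of a bare platinum coil, and is a config knob
(`D_P_inches`) for sensitivity studies. Where the sink dominates
(clinically packed domes, $\beta h^2/\mu \gg 1$) the dome approaches the
Darcy balance $0 = -\nabla p - K\mathbf{v}$; the porous-plug
verification test checks the integrated form
$\Delta p = (\alpha U + \beta)\,U\,L$ to 5%.

A single unified equation — a Navier–Stokes–Brinkman system with a
cell-masked sink — is solved everywhere, rather than coupling a pure
Darcy dome to a Navier–Stokes lumen. This needs no interface conditions
at the neck, recovers the Darcy balance in the packed limit, and makes
the coil-free limit exact: at $\kappa = 1$ both coefficients vanish
identically and a "porous" run is bit-for-bit the control run (tested).

## Geometry idealization

Two parametric configurations stand in for patient anatomy:

* **sidewall** — a circular dome of diameter $D$ seated on one wall of a
  straight parent vessel, opening through a neck gap of width $W \le D$.
  The dome centre height is $\sqrt{(D/2)^2 - (W/2)^2}$ so the circle's
  chord on the vessel wall is exactly the neck.
* **terminal** — the same dome facing the inlet stem of a symmetric
  T-junction (one inlet, two outlets), the configuration in which the
  inflow jet impinges on the dome.

The domain is planar with a declared `slab_depth` (default 1 mm) that
converts cell areas to volumes (RFV in mm$^3$) and lengths to areas
(neck area in mm$^2$), keeping every 2D→3D conversion explicit and
testable. The neck plane is the segment $y=0$ between parent lumen and
dome; one cell row of vessel wall is laid along $y=0$ outside the gap so
that the aperture equals `neck_width` rather than the slightly wider
circle overhang. Morphometrics are computed from the raster: dome
volume from the dome-cell count, neck area from the neck-face measure,
maximum size as the largest chord of the dome region (convex hull of
dome cell centres, plus one cell size). These converge at first order
in the cell size $h$, which the geometry tests check against the
closed-form circular-segment area.

## Numerics

The solver is a staggered-grid (MAC) finite-volume scheme:

* velocities on faces, pressures in cells; uniform cell size $h$;
* first-order upwind convection (a `central` option exists), explicit
  second-order diffusion, no-slip walls via ghost reflection;
* the porous sink treated pointwise implicitly
  ($u \leftarrow u/(1 + \Delta t\,K/\rho)$), which removes the sink's
  stiffness at any packing density; $K(|\mathbf{v}|)$ is lagged one
  step (Picard linearization);
* incremental pressure projection: one sparse Cholesky factorization of
  the Poisson operator per run (Matrix package), reused every step.
  Outlets are traction-free ($p = 0$ Dirichlet on the open face,
  zero-gradient velocity); after projection every fluid cell is
  divergence-free to solver precision, so inlet and outlet fluxes
  balance exactly (tested to 0.1%, observed at machine precision).

Steady states are reached by pseudo-time marching with an adaptive CFL
step and an inlet ramp; convergence is declared when the normalized
per-step velocity change $\max|\Delta u|/(\Delta t\,U_{in})$ falls
below `steady_tolerance` (default $10^{-6}$). Non-convergence raises an
error carrying the final residual. The inlet profile is the fully
developed parabola (the idealized analogue of adding a straight inlet
extension), renormalized so the discrete mean equals the configured
mean velocity exactly; a `flat` profile is available. Pulsatile runs
use a fixed `time_step` (default $10^{-4}$ s) over `n_cycles` (default
2) of a mean-one waveform (`constant`, `sine`, or a user table,
renormalized to mean one within $10^{-6}$), are initialized from the
steady solution at the mean rate, and accumulate the per-cell time-mean
speed over the final cycle for the transient RFV. A time step violating
the convective/diffusive stability limit is rejected with the maximum
stable value in the message.

Degenerate inputs are defined rather than accidental: a zero inlet
yields the identically zero field; a zero reference shear makes
normalized WSS 0 with a `zero-reference` flag; an all-zero neck plane
gives two empty zones with a warning; constant ROC scores give AUC 0.5
with a `constant-scores` flag.

## Hemodynamic parameters

All summaries mirror the clinical definitions: dome WSS is the
area-weighted mean of $\mu\,|u_t|/(h/2)$ over dome-wall faces
(one-sided difference; area weighting is a package decision, recorded
here, since vertex averaging is the plausible alternative); normalized
WSS divides by the parent-vessel wall mean of the same run (the
normalization is otherwise underdetermined — this definition is written
into the outputs); dome flow velocity is the volume-weighted mean
cell-centre speed in cm/s; the neck plane is split into inflow/outflow
zones by the sign of the velocity component normal to the neck plane
(the orientation-free reading of "vertical velocity at the neck");
RFV uses a strict `>` at the threshold, matching the defining
inequality, with the standard scan set {0.5, 1, 2, 5, 10} cm/s.

## Study conditions and problem sizes

The shipped defaults are the package's study conditions, chosen once:

* sidewall reference geometry: vessel 4 mm, dome 8 mm, neck 4 mm —
  mid-range of the morphology spans seen in coiling series (maximum
  size ~4–19 mm, neck ~2.4–11.2 mm);
* terminal reference: vessel 3 mm, dome 10 mm, neck 6 mm;
* inlet mean velocity 0.25 m/s: parent-vessel wall shear
  $6\mu U/H \approx 1.3$ Pa, a physiological arterial value;
* verification grids: $h = H/20$ for the Poiseuille/plug channels;
  $h = 0.4$–0.5 mm (8–12 faces across the neck) for aneurysm runs;
  packing sweep {0, 10, 20, 30, 40}%; pulsatile checks with a 0.3 s
  cycle at $\Delta t = 2\times10^{-4}$ s, two cycles. These sizes make
  the full verification suite run in about a minute on one core while
  keeping every closed-form check inside its stated tolerance.

In 2D, a sidewall dome is a shear-driven cavity: dome speeds and WSS
are substantially lower than in 3D patient geometries with skewed
impinging jets, and clinical packing densities (>13%) suppress RFV to
zero on the sidewall reference. The terminal configuration, where the
jet faces the neck, retains nonzero RFV at 20% packing and is used for
the transient-consistency check. The qualitative
physics — RFV strictly nonincreasing in packing density and in the
threshold, porous runs slower and lower-shear than their paired
controls — is the portable content, and is what the tests assert.

## Synthetic cohort generator

The distribution-matched generator emulates the *statistical* structure
of a published two-group coiling series (24 stable / 13 recurrent):
per-group means and SDs for age, morphology, packing density, the seven
control-model and seven porous-model hemodynamic parameters and RFV,
plus categorical proportions (sex, subtype, coil type). Positive
right-skewed quantities are log-normal with moments matched by the
standard $(\mu, \sigma)$ inversion — their SDs exceed their means,
ruling out truncated normals; age and packing density are truncated
normals. A shared latent size factor (loading $\sqrt{0.95}$) induces
the strong intercorrelations among size-type variables (Spearman ~0.94,
matching the reported ~0.93–0.97 cluster) so that collinearity pruning
has realistic work to do; RFV loads at 0.62 (moderate correlation with
dome volume, ~0.6) and packing density at −0.3. RFV draws are capped
at the dome volume to honour the physical invariant; the cap touches a
few percent of recurrence-group draws and biases that group's RFV
moments by under ~5%, which the generator tests account for. Note that
the SD of a heavy-tailed log-normal (CV > 1) carries >3% sampling error
even at $n = 10^4$; the moment tests use tolerances that respect this.

Two generation modes are kept separate: `groups` draws each outcome
group from its own distributions (for screening-stage behaviour);
`logistic` draws one pooled population and assigns labels by a
Bernoulli draw of $P(\text{recurrence}) = \text{logit}^{-1}(\beta_0 +
\beta_{RFV}\,\text{rfv})$ (defaults $\beta_0 = -2$,
$\beta_{RFV} = 0.06$ per mm$^3$, giving a ~35–40% prevalence). The
logistic mode is the ground-truth harness: when recurrence is generated
from RFV alone, the full workflow must recover RFV in the final
multivariate model, and does so in ≥90% of seeded replicates at
$n = 200$.

What the generator does **not** emulate — and hence what passing tests
cannot show: real angiographic geometry and its hemodynamic
consequences, measurement error in morphometrics, informative
missingness, or any causal pathway other than the configured logistic
dependence. The physics-first mode (`simulate_cohort`) ties the
generator to the actual solver instead, at the cost of 2D physics.

## Statistics pipeline conventions

The workflow fixes the conventions its upstream description leaves
open, and records them in the report metadata:

* Mann–Whitney U: exact enumeration when $n_1+n_2 \le 20$ without ties,
  otherwise the normal approximation with tie and continuity
  correction; average ranks throughout.
* Categorical tests: Fisher's exact test when any expected cell count
  is below 5, otherwise chi-square without continuity correction.
* Spearman pruning: edge at $|R| \ge 0.7$ (the reported correlated
  pairs cluster at ≥0.93; 0.7 separates them cleanly from the ~0.59
  RFV–dome-volume pair) with correlation $P < 0.05$; each connected
  component keeps its lowest screening-P member, ties broken
  lexicographically.
* Stepwise backward logistic regression: likelihood-ratio removal at
  $P \ge 0.10$ (the common statistics-package default; Wald removal is
  a config option), refitting after each removal, with the removal
  trail reported. Separated fits are flagged, never silently reported.
* ROC: empirical curve, AUC equal to $U/(n_1 n_2)$ with half-weight
  ties (identity tested to $10^{-12}$), DeLong 95% CI, cutoff by the
  Youden index with ties broken toward higher specificity, direction
  chosen so AUC ≥ 0.5 and recorded (lower packing density predicting
  recurrence is a legitimate reversed-direction marker).

## Known limitations

* 2D slab physics: absolute WSS/velocity/RFV levels are not
  patient-scale; only orderings and ratios transfer.
* One porosity for the whole dome; real coil masses are heterogeneous.
* Circular domes only; ellipsoidal/lobulated shapes would be config
  extensions.
* The shipped waveforms are generic (constant/sine/table); no claim is
  made about any specific measured waveform.
* First-order upwind convection is diffusive; it buys robustness on
  coarse grids and costs sharpness in the neck jet.

```{r}
## the 30-second tour
library(coilflow)
grid <- rasterize(make_geometry("sidewall"), h = 0.4)
ctl <- solve_steady(grid, fluid_properties(), boundary_conditions(0.25),
                    settings = solver_settings(steady_tolerance = 1e-5))
por <- solve_steady(grid, fluid_properties(), boundary_conditions(0.25),
                    porous_coefficients(packing = 30),
                    solver_settings(steady_tolerance = 1e-5))
hemodynamic_summary(ctl)
hemodynamic_summary(por)
report <- run_full_workflow(
  generate_cohort(cohort_config(mode = "logistic", n = 200, seed = 1)))
report
```
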