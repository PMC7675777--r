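---
title: "Methods: six-network poroelastic transport in brain tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: six-network poroelastic transport in brain tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpet6)
```

## The model

`mpet6` solves a six-compartment multiple-network poroelastic (MPET) system:
one linear-elastic solid skeleton saturated by six interpenetrating Darcy
networks — arterial/arteriole (`a`), capillary (`c`), CSF/ECF (`e`),
venule/venous (`v`), glymphatic/perivascular (`l`) and glial/intracellular
(`g`). The primitive variables are the skeleton displacement $\mathbf u$ and
the six pore pressures $p_i$. Quasi-static momentum balance (body forces and
inertia omitted — acceleration frequencies in these biological flows are
low) reads

$$ G\nabla^2\mathbf u + (G+\lambda)\nabla(\nabla\!\cdot\!\mathbf u)
   \;=\; \sum_i \alpha_i \nabla p_i, $$

equivalently $\nabla\!\cdot\!\boldsymbol\sigma_{\rm eff} = \sum_i \alpha_i
\nabla p_i$ with total stress $\boldsymbol\sigma = \boldsymbol\sigma_{\rm
eff} - \sum_i\alpha_i p_i\,\mathbf I$. Each network obeys

$$ c_i\,\dot p_i + \alpha_i\,\nabla\!\cdot\!\dot{\mathbf u}
   - \nabla\!\cdot\!(K_i\nabla p_i) \;=\; \textstyle\sum_x S_{xi}
   \;(+\,Q\ \text{terms}), $$

with Biot–Willis coefficient $\alpha_i$ (bounded by the total porosity,
$\phi \le \sum_i\alpha_i \le 1$), constrained specific storage $c_i$
(m² N⁻¹) and mobility $K_i = \kappa_i/\mu_i$. Cross-storage coupling is
omitted (a known limitation of this model family), and the constitutive law
is linear elastic.

**Transfer topology.** Fluid exchanges along exactly eight unordered pairs
(a–c, c–v, a–l, c–l, v–l, e–l, g–l, e–g) with
$S_{xy} = \omega_{xy}(p_x - p_y)$; there is no direct a–e exchange.
Antisymmetry $S_{xy} = -S_{yx}$ holds by construction, so exchange conserves
mass pointwise. The physiology of the blood path motivates one-way valves:
by default a→c, c→v (forward flow through the microcirculation) and a→l
(periarterial influx) are rectified, $S = \omega\max(p_x-p_y,0)$, and all
glymphatic/glial pairs are bidirectional. The exact arrow directions are not
machine-readably fixed by the source material, so every valve is a
configuration key and the defaults are audit-logged in every run manifest.

**Microcirculatory transit.** The arterial and venous mass balances carry a
volumetric sink $-Q_{\rm in}$ and source $+Q_{\rm out}$ respectively, set
equal to the instantaneous boundary inflow distributed uniformly per unit
volume. This pair represents blood delivered through the microcirculation at
scales below the continuum model. It is needed for a well-posed periodic
problem at the reference coefficients: $\omega_{ac} = \omega_{cv} =
1.5\times10^{-19}$ m² N⁻¹ s⁻¹ cannot carry a physiological volumetric blood
flow through the intercompartmental route, so without transit the arterial
compartment integrates its inflow at a rate $Q/(c_a V)$ of a few Pa/s and no
periodic steady state exists. The pair is switchable
(`transit = FALSE`) for reduced and verification problems.

## Parameters

`mpet_params()` carries the reference coefficient set; every entry is SI and
`validate_params()` reports all violated invariants as a tibble (it never
raises). Choices that the reference table does not pin down:

* **Poisson ratio** $\nu = 0.35$: both tabulated Lamé pairs imply it —
  $\lambda/G = 505/216$ gives $\nu = 0.3502$ and $1010/433$ gives
  $0.3500$. `lame_from_young(584, 0.35)` reproduces (505, 216) after
  rounding; the white pair gives $G = 433$ and $\lambda = 1009$ (the table's
  1010 reflects its own rounding).
* **Viscosities** are not tabulated: CSF/water-like
  $8.9\times10^{-4}$ Pa s for `e`, `l`, `g` and blood-like
  $3.5\times10^{-3}$ Pa s for `a`, `c`, `v`; explicit, configurable
  assumptions.
* **Porosity** $\phi = 0.3$, used only in the admissibility check.
* **Glymphatic skull pressure** `p_ls` is subject-derived in origin
  (arterial-pressure-like); default 13332.2 Pa (100 mmHg).
* **Ventricular reference radius** `r_v = 0.02` m, matching the default
  shell geometry.
* **Outflow resistance** `R` is applied only through the product
  $\mu_e R\,Q_o$ (units then close: Pa); $Q_o$ defaults to the production
  rate $Q_p$ (absorption = production at steady state).
* **White-matter stiffness perturbation**: each white element receives
  $E_{\rm white} + \delta$, $\delta \sim U(-10, 10)$ Pa i.i.d. from a seeded
  generator (a smooth correlated mode is available but off by default, since
  only the amplitude, not the correlation structure, is specified). Grey
  elements keep $E_{\rm grey}$ exactly.

Config files are YAML with sections `elasticity`, `networks`, `transfer`,
`boundary`, `time` (+ run-level `geometry`, `waveform`, `solver`, `output`);
pressures may carry an explicit `mmHg` suffix (converted at 133.322 Pa/mmHg).
The bundled `default_config.yaml` reproduces the reference table verbatim,
and every assumed default is a visible key recorded in the run manifest.

## Boundary conditions

On the cortical (skull) surface and the ventricular wall:

| variable | skull | ventricular wall |
|---|---|---|
| $\mathbf u$ | $\mathbf u = 0$ (rigid skull; cortical SAS omitted) | total normal stress $-p_V\mathbf n$, $p_V$ = wall-averaged $p_e$ |
| $p_a$ | Neumann pulsatile inflow | no flux |
| $p_c$ | no flux | production efflux $-Q_p/|\Gamma_v|$ |
| $p_e$ | Dirichlet $p_v|_{\rm skull} + \mu_e R\,Q_o$ | nonlocal aqueduct balance |
| $p_v$ | Dirichlet $p_{bp}$ (sagittal-sinus-like) | no flux |
| $p_l$ | Dirichlet $p_{ls}$ | Dirichlet $p_{lv}$ |
| $p_g$ | Dirichlet linked to $p_e$ | Dirichlet $p_{gv}$ |

Three readings had to be fixed where the source notation is ambiguous, all
flagged here and in the configuration: (i) the ventricular stress condition
uses the **total** stress (the effective-stress reading exists; with
$\sum\alpha_i = 1$ the total-stress reading makes a uniform-pressure state an
exact equilibrium, which we verify); (ii) "$p_v n = p_{bp}$" is read as a
Dirichlet value, consistent with the venous drainage role; (iii) the primed
glymphatic/glial entries are ventricular-side Dirichlet values.

**Arterial inflow.** `synth_waveform()` builds a raised-cosine
systole/diastole shape normalised so the trapezoidal mean equals the
requested flow exactly and peak/mean $= 1 +$ pulsatility by construction
(defaults 1.25×10⁻⁵ m³/s ≈ 750 ml/min, pulsatility 0.4, period 1 s — an
ICA+VA-like total). `flux_density()` converts instantaneous total inflow into
the per-area Neumann datum: division by the tagged skull area and the
arterial mobility $k_a/\mu_a$, so the imposed normal Darcy influx integrates
back to the waveform value. Distribution is uniform over the skull; arterial
territory maps are imaging-derived and out of scope.

**Aqueduct balance.** CSF produced at rate $Q_p$ partitions between
Poiseuille aqueduct flow with conductance $C = \pi d^4/(128\mu_e L)$
(≈ $3.19\times10^{-8}$ m³ Pa⁻¹ s⁻¹ at the reference geometry) acting on the
difference of the surface-averaged $p_e$ between wall and skull, the
ventricular cavity volume rate $|\Gamma_v|\,\dot u_1$ ($u_1$ = mean outward
wall displacement), and ependymal permeation into the tissue, which closes
the balance and enters the $p_e$ equation as a natural boundary flux. This
cavity-bookkeeping form is the sign-stable reading of the printed relation
(whose permeation term, taken literally, feeds back positively and
diverges); it is evaluated on the reference configuration, consistent with
linear kinematics, with the $(r_v + u_1)$ geometric factor available as a
diagnostic.

## Numerics

* **Elements.** Equal-order continuous piecewise-linear (P1) displacement
  and pressures on simplices (1D/2D/3D generic assembly, vectorised over
  elements). The classical argument for a mixed (quadratic/linear) pairing
  concerns the undrained incompressible limit; at $\nu = 0.35$ with strictly
  positive storages $c_i \ge 1.5\times10^{-5}$ m² N⁻¹ the system is
  storage-regularised and P1/P1 delivers the nominal second-order $L^2$
  pressure convergence, which the manufactured-solution study verifies.
* **Time.** Implicit first-order (backward Euler) at $\Delta t = 0.1$ s by
  default; monolithic solve of all seven fields; direct sparse LU, with the
  factorisation reused while the valve state is unchanged.
* **Transfer terms** are assembled with a lumped (nodal) mass so one-way
  valves rectify pointwise; valve open/closed indicators are taken from the
  previous time level (semi-implicit), and a state change triggers
  re-factorisation.
* **Nonlocal couplings.** The ventricular traction ($p_V$ = wall-averaged
  $p_e$) and the aqueduct Poiseuille/wall-motion terms are surface-average
  functionals and are treated **implicitly** as rank-one blocks in the
  monolithic matrix. A one-step-lagged treatment of these two couplings is
  an oscillatory iteration with gain above one at the reference parameters
  (shear modulus ~216 Pa against kPa-scale boundary pressure mismatches) and
  diverges within a few steps — a defect no inner fixed-point loop can
  repair, since it iterates the same map. The genuinely weak couplings (the
  skull outflow-resistance value, which rests on the Dirichlet-pinned venous
  pressure, and the glial skull value linked to $p_e$) remain lagged one
  step with the documented $O(\Delta t)$ splitting error, and an optional
  inner fixed-point loop (tolerance $10^{-8}$) is retained for them.
* **Initial state.** Hydrostatic constants compatible with the boundary
  data (arterial at `p_ls`, capillary ~18 mmHg, CSF/ECF at the skull outflow
  value, venous at `p_bp`, glymphatic/glial at their surface mid-values),
  with the displacement equilibrated against those pressures.
* **Cycle control.** `run_cycles()` iterates whole periods and records, per
  field, the phase-matched relative $L^2$ difference between consecutive
  cycles; convergence requires every field below the tolerance (default
  $10^{-4}$), with the first two cycles excluded as transient. Fields at
  numerically zero amplitude are measured against the overall state scale
  rather than their own vanishing norm. A divergence detector flags total
  cycle-norm growth over three consecutive cycles.
* **Mass accounting.** Boundary fluxes through Dirichlet surfaces are
  recovered as discrete reaction residuals of the unconstrained equations,
  so the cycle-integrated budget (`mass_balance()`) closes to solver
  precision at a periodic steady state (measured ~2×10⁻⁶ relative on the
  default run).

## Synthetic study conditions

The generators define the default study conditions and emulate the *shape*
of a subject-specific pipeline, not its content:

* `make_shell()` — a 2D annulus (or 3D icosphere-based spherical shell)
  with inner `VENTRICLE` and outer `SKULL` boundaries, a radial grey/white
  partition (outer half grey), and angular-sector region labels standing in
  for an anatomical atlas. The 2D annulus is triangulated with alternating
  diagonals, making it *exactly* mirror-symmetric about the x-axis — this is
  what lets the symmetry of the solution under symmetric forcing be tested
  to discretisation accuracy. The smooth shell cannot reproduce
  concavity-driven focal fields (peak perfusion/clearance localisation,
  periventricular hot spots at ventricular horns), so regional biomarker
  tables from synthetic geometry are structural outputs only.
* `synth_anisotropic_Ke()` — a radially-aligned SPD permeability tensor
  field standing in for diffusion-imaging-derived maps.
* `synth_waveform()` — the parametric pulse above, standing in for
  subject-specific blood-flow profiles.

Consequently, a passing test suite demonstrates correctness of the
discretisation, the boundary-condition machinery and the biomarker
definitions — not agreement with any subject's regional values, which
require imaging-derived geometry, permeability maps and flow waveforms.

## Verification harness

* **Consolidation limit.** `reduce_to_single_network()` zeroes all transfer
  coefficients and the solid coupling of five networks; on a column with a
  step load at the drained end the survivor obeys classical consolidation
  with $c_v = (k/\mu)\,M\,m_v/(m_v + \alpha^2 M)$ ($M = 1/c$,
  $m_v = \lambda + 2G$) and undrained initial pressure
  $p_0\,\alpha M/(m_v+\alpha^2 M)$. The series solution
  (`terzaghi_pressure()`, 200 terms, truncation controlled against 400) is
  itself checked against an independent Crank–Nicolson finite-difference
  oracle (mid-column dimensionless value 0.7356513152 at $T = 0.1$, agreeing
  to $10^{-10}$). The solver matches the series within 0.25% $L^\infty$ on
  64–256-element columns with the error falling monotonically under
  refinement (time step refined as $t_{\rm char}/4n$ so both error
  components shrink together).
* **Manufactured solutions.** `mms_study()` injects closed-form solutions
  with analytically derived forcings into all seven equations (transfer
  terms included) on the annulus. Spatial orders use a trigonometric
  solution over resolutions 4/8/16 with $\Delta t \propto h^2$ (observed
  1.87–1.96, nominal 2); temporal order uses a spatially *linear* solution —
  exactly representable by P1, transfer off so lumped/consistent quadrature
  agree — giving a clean backward-Euler measurement against the exact
  solution (observed 0.95–1.01, nominal 1). Forcings are applied through
  nodal evaluation with consistent-mass loads.
* **Structure checks.** Sealed networks stay at their uniform initial
  pressures; the assembled operator has zero coupling blocks for them; the
  discrete poroelastic energy decays in the unforced reduced problem; six
  identically parameterised uncoupled networks evolve identically.

Problem sizes were chosen to keep the full verification battery fast on a
single CPU — the default annulus run uses 252 nodes (2016 unknowns) for 50
cycles of 10 steps, the consolidation study columns of 64–256 elements, and
the convergence study up to ~6500 unknowns; the whole test suite runs in
about half a minute. The same physics runs unchanged on finer meshes and in
3D.

## Known limitations

* Linear elasticity with brain-soft moduli (G ≈ 216–433 Pa) against
  kPa-scale boundary pressure mismatches produces strains of order one on
  the idealised annulus: displacement fields are qualitative there, and the
  small-strain assumption is a recognised constraint of the model class
  (alongside the rigid-skull condition and the omitted cortical
  subarachnoid space).
* Cross-storage effects, inertia/body forces, osmotic (Donnan) effects and
  ventricular CFD/cilia-driven flow are outside the model.
* The display normalisation of published regional swelling/drainage ranges
  is not recoverable from the source; `region_table()` therefore reports
  both raw fluid content $\zeta = \alpha\nabla\!\cdot\!\mathbf u +
  c\,(p - p_{\rm ref})$ (reference: cycle average at the periodic steady
  state, configurable) and a variant normalised by its parenchymal maximum.
* The periventricular (PVL) index uses a band width of 10% of the domain's
  radial extent by default; no distance threshold is fixed by the source.
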