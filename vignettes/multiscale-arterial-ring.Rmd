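---
title: "Multiscale active mechanics of an arterial ring: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale active mechanics of an arterial ring: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasomech)
```

# The problem

A small arterial ring mounted on two steel hooks in a wire myograph develops
isometric force that reflects the contractile state of the smooth muscle
cells (SMCs) in its media layer.  `vasomech` simulates this experiment as a
chain of one-way coupled subsystems:

1. **Ionic dynamics.** Each SMC carries three state variables — cytosolic
   Ca²⁺ concentration χ (µM), sarcoplasmic-reticulum (SR) Ca²⁺ ζ (µM) and
   membrane potential η (V) — governed by a balance of ten concentration
   currents.  Cells exchange Ca²⁺ and voltage with their face-sharing
   neighbours through gap-junctional coupling.
2. **Cross-bridge (CB) kinetics.** Cytosolic Ca²⁺ catalyses myosin
   phosphorylation in a four-state actin–myosin cycle (free and
   phosphorylated myosin, attached phosphorylated bridges, and the
   dephosphorylated latch bridge).
3. **Contractile-unit (CU) mechanics.** The attached fractions drive relative
   actin–myosin filament sliding at each Gauss point of the tissue mesh and
   produce an active fibre stress.
4. **Continuum mechanics.** A quasi-static, incompressible, fibre-reinforced
   hyperelastic finite-element model of the ring (trilinear hexahedra with
   element-constant pressure) turns the active energy into a hook force.

Information flows strictly forward: the mechanics never feeds back into the
cellular model, which matches the isometric experimental configuration and
lets each level use its own integrator.

# Cellular model

The balance laws are

$$\dot\chi = \Phi_A + \Phi_S + \Phi_V + \Phi_N - \Phi_B + \Phi_C + \Phi_L -
\Phi_D + \tilde J_{Ca}, \qquad
\dot\zeta = \Phi_B - \Phi_C - \Phi_L, \qquad
\dot\eta = \gamma\,(\Phi_V - \Phi_N - \Phi_{Cl} - \Phi_K) + \tilde J_V .$$

The currents are: a constant non-selective cation influx $\Phi_A$; a
store-operated influx $\Phi_S = A_S\,\zeta_S^2/(\zeta_S^2+\zeta^2)$ that
grows as the store empties; a voltage-operated Ca²⁺ influx
$\Phi_V = E_{Ca}(z_{Ca1}-\eta)\,\sigma((\eta-z_{Ca2})/R_{Ca})$ with logistic
activation $\sigma$; reverse-mode Na⁺/Ca²⁺ exchange
$\Phi_N = E_{NCX}\,\chi/(\chi+x_{NCX})\,(\eta-z_{NCX})$; SERCA uptake
$\Phi_B = B_{SR}\chi^{n}/(\chi^{n}+x_{SR}^{n})$; Ca²⁺-induced Ca²⁺ release
$\Phi_C = C_{Ry}\,\frac{\zeta^{m}}{\zeta^{m}+y_{Ry}^{m}}\,
\frac{\chi^{p}}{\chi^{p}+x_{Ry}^{p}}$ (Hill exponents $m=2$, $p=4$, the
classical CICR form); a linear store leak $\Phi_L = L_{SR}\zeta$; ATPase
extrusion $\Phi_D = D_{EX}\chi^{k}(1+(\eta-z_{Ex})/R_{Ex})$; and Cl⁻/K⁺
fluxes that vanish at their reversal potentials,
$\Phi_{Cl} \propto (\eta-z_{Cl})$ and
$\Phi_K \propto (\eta-z_K)\,\sigma((\eta-z_{Ca3})/R_K)$.  Signs in the
voltage equation follow the charge carried: voltage-gated Ca²⁺ entry and
Cl⁻ efflux below its reversal depolarize; K⁺ efflux and the electrogenic
exchanger repolarize.  γ (V µM⁻¹) converts net ion movement into a
potential rate.

The tabulated reference parameters (see `cell_params()`) place the
intracellular oscillator in a relaxation regime: CICR bursts (cytosolic
activation half-point 0.9 µM, quartic) discharge the store, SERCA (half
point 4.4 µM) recaptures, and the membrane sits near −34 mV.  At the
baseline influx of the intervention protocols (0.8 µM s⁻¹) a single cell
shows sustained χ oscillations with a period near one minute; at the
phenylephrine endpoint (4.2 µM s⁻¹) the fixed point stabilizes at an
elevated χ, i.e. strong tonic activation.

Gap-junctional coupling is linear in the state differences over the
face-sharing neighbour graph, $\tilde J_i = \alpha\sum_{j\in N(i)}(s_j-s_i)$
with diffusivities $\alpha_C$, $\alpha_V$ (s⁻¹, presupposing uniform cell
size).  The summed form (no division by the neighbour count) makes the
currents exactly conservative over the network, which the suite asserts.
Boundary cells simply have fewer neighbours; there are no ghost cells.

**Units** are kept exactly as tabulated (µM, V, s, kPa, mm) with no internal
conversion, so parameter sets are copy-verifiable.  One consequence is that
forces come out directly in mN (kPa × mm²).

# Cross-bridge kinetics

The four fractions obey linear kinetics on the transition graph

* phosphorylation $\tau_1(\chi)$: $n_M \to n_{Mp}$ and $n_{AM} \to n_{AMp}$,
* dephosphorylation $\tau_2$: $n_{Mp} \to n_M$ and $n_{AMp} \to n_{AM}$,
* attachment $\tau_3$: $n_{Mp}\to n_{AMp}$; detachment $\tau_4$: reverse,
* latch release $\tau_5$: $n_{AM}\to n_M$,

the classical identification in which phosphorylation and dephosphorylation
act identically on free and attached myosin.  The rate matrix is built from
a declarative edge list (`cb_rate_matrix()`) so the graph is auditable.
The Ca²⁺ dependence is a saturating quartic,
$\tau_1 = \theta\,\tau_0\,\chi^4/(\chi^4+\chi_0^4)$, reflecting the
four-site cooperativity of calmodulin activation; θ is the protocol-level
"enhancement" coefficient and enters only here, multiplicatively.
$n_M$ is eliminated algebraically ($n_M = 1 - n_{Mp} - n_{AMp} - n_{AM}$),
which makes conservation structural: it holds to the last bit at every step
of every simulation, not as a numerical property.  The forward-Euler update
guards against fractions leaving $[0,1]$ instead of clamping them.

# Contractile unit

At each Gauss point the relative filament sliding $u_{fs}$ (normalized to
the reference CU length, negative in contraction) splits into a chemical
component $u_{fs}^c$ driven by the power stroke and a mechanical component
$u_{fs}^m$.  The average elastic CB elongation is
$\bar u_e = \lambda - 1 - u_{fs}$ with CU stretch
$\lambda = \sqrt{\bar I_4}$.  The filament-resistance (first
Piola–Kirchhoff) stress is
$P_a = \mu_a\,L(u_{fs})\,(n_{AMp}+n_{AM})\,\bar u_e$, with the parabolic
overlap function $L(u) = \max\{0,\,1-((u+u_{opt})/s)^2\}$ whose optimum is
reached while contracting (vertex at $-u_{opt}$) and which is clamped at
zero where the parabola would be negative, since a negative overlap
fraction is unphysical and destabilizes $P_a$.  The driving stress has a
contraction/extension case split: cycling phosphorylated bridges drive
contraction ($P_c = \kappa_{AMp} n_{AMp}$); in extension the latch bridges
additionally bear force ($P_c = \kappa_{AMp} n_{AMp} + \kappa_{AM} n_{AM}$).
The chemical sliding evolves by the force balance
$\dot u_{fs}^c = (\beta_a/\alpha_a)(P_a - P_c)$ with a stick–slip selection
between the two branches; the selected rate is continuous in the driving
quantities, and the stick region prevents spurious reversal.

Two modelling choices deserve note.  First, the mechanical sliding
component is kept as a tracked field but is identically zero here: all
protocols are isometric, the external length never changes after the
loading phase, and the closure $u_{fs} = u_{fs}^c + u_{fs}^m$ is asserted.
Second, the CU sees the stretch of the *previous* converged continuum step
(lagged coupling, no sub-iteration), matching the segregated architecture.

The active free energy is
$\Psi_a = \tfrac{\mu_a}{2} L(u_{fs})(n_{AMp}+n_{AM})(\lambda-1-u_{fs})^2$,
and its analytic first and second derivatives with respect to the isochoric
fourth invariant (chain-ruled through λ) are what the continuum consumes;
the suite checks them against central finite differences at relative
1e−6.

# Tissue model and finite elements

The free energy splits into volumetric and isochoric parts, the latter into
the active CU energy and a passive part
$$\Psi_p = \tfrac{\mu_p}{2}(\bar I_1 - 3) + \tfrac{c_{p1}}{2c_{p2}}
\left[e^{c_{p2}\,s(\bar I_4-1)^2} - 1\right],$$
a neo-Hookean matrix plus one exponential fibre family aligned
circumferentially (the SMC direction; media-only model, no diagonal
adventitial families).  Both fibre invariants use the deviatoric
$\bar C = J^{-2/3} C$.  The fibre term is tension-only: $s(x) =
x^3/(x^2+\varepsilon^2)$ for $x>0$ (else 0), a C²-smooth positive-part ramp
with $\varepsilon = 0.02$ on the $\bar I_4$ scale.  The smoothing matters
numerically: at the stress-free reference *every* Gauss point sits exactly
on the tension/compression boundary, and a hard switch makes the Newton
active set flicker.  The volumetric part is the log-barrier penalty
$\Psi_{vol} = \tfrac{\kappa}{4}(J^2-1-2\ln J)$, zero and stress-free at
$J=1$ and unbounded in compression, so crushing an element costs unbounded
energy — the quadratic $(J-1)^2$ form, by contrast, has finite compression
resistance and lets severely loaded elements collapse.

The tabulated bulk modulus (κ = 4 kPa) is of the same order as the passive
moduli, so incompressibility at the defaults is weak: converged preload
states show per-element $|J-1|$ up to tens of percent.  κ is exposed in the
configuration, and the suite verifies the penalty-method property that the
volume error decreases monotonically as κ is scaled ×10 and ×100.

Elements are 8-node hexahedra with trilinear displacement and
element-constant pressure and dilatation (Q1/P0 mean-dilatation style,
2×2×2 Gauss quadrature, so 8 CUs per element); the pressure is condensed at
element level, adding a rank-one term to the element stiffness.  Assembly
is total-Lagrangian with the analytic second Piola–Kirchhoff stress and
consistent material + geometric tangent.  The element kernel is implemented
twice — a reference R version and a compiled (RcppArmadillo) version — and
the two are cross-checked to round-off in the suite; production code uses
the compiled kernel.  The linear solves use sparse LU (Matrix) with
deterministic ordering.

## Newton solver

Equilibrium is found by Newton–Raphson with three robustness devices, each
needed by the floppy slack phase of the thin-walled ring:

* **Incremental displacement control.**  The remaining prescribed-dof
  increment is driven through the tangent solve rather than applied to the
  state: assembling a field with a raw boundary jump larger than an element
  edge inverts elements immediately.
* **Levenberg-style damping.**  In the slack (bending-dominated) regime the
  tangent can be indefinite near buckling modes; the diagonal shift is
  raised when a step is unproductive and dissolved on full steps.
* **Backtracking line search** on the residual norm, plus a documented
  stall tolerance: the smoothed fibre ramp keeps the residual C¹ but
  curvature can leave slow linear convergence at residual norms around
  10⁻³ of the internal force scale, which is accepted after stagnation
  (the hook-force readout needs ~10⁻³ mN resolution; the stall level is
  orders of magnitude below it).

## Geometry, loading and the hook force

The default geometry is the reference myograph ring: inner/outer diameters
0.7/0.8 mm, 2 mm axial width, 0.25 mm hooks.  Two-hook loading along x has
three mirror symmetries, so the default mesh is one eighth — a quarter
annulus times the half width — with symmetry-plane node sets and the hook
contact strip defined as the inner-surface nodes within the arc subtended
by the hook radius.  The hook patch translates rigidly (prescribed x, fixed
y: a no-slip hook); contact mechanics is deliberately out of scope since
the isometric force readout does not need it.  A full-ring generator with
wrap-around connectivity exists solely to validate the symmetry reduction
(agreement to better than 0.1%, observed ~10⁻⁵ relative).

The loading phase reproduces the myograph's resting-tension calibration:
hook displacement is marched with predictor continuation (secant predictor
on the displacement field, adaptive step, substepping on failure) and the
scalar force–displacement relation is bracketed and solved by regula falsi
to 0.5% of the 1 mN target.  The passive curve has a long soft phase —
the ring first ovalizes by bending at nearly zero force and stiffens
steeply once taut (fibre stretches reach λ ≈ 1.4 at the preload with the
default weak penalty).  The hook force is the sum of internal-force
x-components over the hook node set times the mirror factor (4 for the
one-eighth model), and equals the reaction a physical hook reads; global
equilibrium (Σ internal forces = 0) is asserted.

# Protocols

Interventions are linear parameter ramps on the cell population
(`make_protocol()`):

* **phenylephrine** — each cell's Φ_A is scaled ×7 over a dilution time of
  50 or 100 s (population mean 0.6 → 4.2 µM s⁻¹); multiplicative per-cell
  scaling preserves the population's coefficient of variation.
* **cpa** — SERCA inhibition as a B_SR ramp-down.  The two published
  figures disagree (400→350 µM s⁻¹ over 2000 s in the text vs 400→200 over
  1000 s in the table); both ship as named variants with `"text"` the
  default, and the enhancement coefficient θ must be given explicitly (its
  tabulated value is typographically ambiguous; candidates 30.0 and 0.0).
* **ryanodine** — CICR block: C_Ry ramps 1250 → 312.5 µM s⁻¹ over 2000 s
  starting 100 s after onset, with store-operated entry enabled
  (A_S = 0.1 s⁻¹) and θ = 0.5.

Population heterogeneity enters only through Φ_A, drawn from a seeded
normal distribution (s.d. 0.1 µM s⁻¹, negative draws redrawn), which
spreads the cells' natural oscillation frequencies.  Protocols start only
after a stationarity pre-roll (default 200 s of model time; the reference
experiments required stationary Ca²⁺ and CB states but state no duration).

# Orchestration and time integration

`run_simulation()` executes loading → pre-roll → protocol.  The cellular
ODEs advance on the Δτ₁ grid (`dt_cell`, default 1 ms) with an embedded
Cash–Karp Runge–Kutta 4(5) and PI step-size control inside each grid step
(tolerances rtol = 10⁻⁷, atol = 10⁻⁹); any embedded explicit scheme of
order ≥ 4 is an acceptable member of this family.  Neighbour states are
frozen at the step start and refreshed on the grid — the segregated design.
CB fractions and the chemical sliding use forward Euler (CB on Δτ₁, CU on
the solid step).  The continuum is solved every Δτ₂ (`dt_solid`, default
0.1 s; must be an integer multiple of Δτ₁, and CB states are consumed at
the aligned sample, the degenerate case of linear interpolation between
grids).  A refinement test (Δτ₂ = Δτ₁ vs 10·Δτ₁ on a four-element strip)
bounds the induced force-trace difference at 2% RMS.  Negative
concentrations are flagged as errors beyond −10⁻⁹ µM rather than clamped,
so transcription errors cannot hide; trial stages of the embedded scheme
may probe slightly negative values unguarded.

Determinism: the only random source is the population draw, which is
seeded and restores the session RNG state; identical configuration and
seed give bit-identical outputs.

# What the tests do and do not show

The synthetic fixtures (single cell, chains, strips, coarse rings) exercise
every operation against independent oracles: a second, independently typed
transcription of the flux algebra; deSolve and a fixed-step RK4 as
reference integrators; the matrix exponential and rate-matrix nullspace for
the CB cycle; finite differences of every analytic derivative; a
reduced-energy minimization for the uniaxial strip; and a full-ring model
for the symmetry reduction.  Problem sizes were chosen at desk scale: the
coarse 240-element ring (the published study used 5750 elements; the
resolution split is not stated there and is configurable here), 27–48-cell
populations for the coupling studies, and seconds-to-minutes of model time.

Passing these suites shows internal consistency and reproduction of the
study's quantitative anchors (population-ramp endpoints, the 1 mN preload
calibration) and qualitative findings (coupling synchronizes χ without
changing its amplitude by more than 20%; weakly coupled cell forces remain
uncoordinated while strong coupling restores a fluctuating global tone).
It does not validate the model against new experimental data: absolute
force traces depend on figure-level information (axes, durations) and on
biological variability that the generator does not emulate, and the
equation set itself is a reconstruction from the model's antecedent
literature (flux laws of the minimal arterial Ca²⁺ oscillator, classical
four-state CB kinetics, the filament-sliding CU model), pinned by the
tabulated parameters and reported behaviours rather than by a verbatim
equation listing.

# Worked example

A desk-scale phenylephrine run on a 24-cell ring:

```{r example, eval = FALSE}
cfg <- simulation_config(resolution = c(1, 12, 2),
                         protocol = "phenylephrine",
                         dt_cell = 0.02, dt_solid = 1,
                         t_end = 60, preroll = 40, seed = 3)
sim <- run_simulation(cfg)
print(sim)
plot(sim, "force")
```

The printed summary reports the calibrated preload (1 mN within 0.5%), the
onset force F0 and the final hook force; `sim$force_norm$ratio` is the
normalized trace comparable across rings.

# Known limitations

* The equation bodies are reconstructions (see above); where the published
  rendering was unavailable the antecedent-model form was chosen and every
  tabulated symbol bound to it.
* Endothelial feedback, InsP₃-receptor release (lumped into Φ_A),
  fluid flow, inertial dynamics, residual stresses and adventitial fibre
  dispersion are out of scope by design.
* The hook is a rigidly translating node patch, not a contact problem; the
  local stress field near the patch edge is not meaningful, only the
  resultant force is.
* With the default weak penalty the volumetric response is soft;
  per-element J is reported so users can judge (and raise κ) when local
  volume fidelity matters.
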