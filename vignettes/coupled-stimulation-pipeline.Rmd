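---
title: "Coupled magnetoelectric and piezoelectric stimulation in a hydrogel: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled magnetoelectric and piezoelectric stimulation in a hydrogel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical model

The pipeline simulates a composite designed for bone-repair scaffolds: a
soft alginate hydrogel carrying core–shell magnetoelectric nanoparticles
(MENPs: cobalt-ferrite core, radius 45 nm; barium-titanate shell, thickness
25 nm) and a piezoelectric hydroxyapatite (HAP) particle, with a human cell
resting on the gel. A static magnetic flux density of 300 mT along z — a
field strength routinely used in magnetic-stimulation studies — drives the
chain

magnetization → magnetostriction → shell piezoelectricity → electric field
in the gel → HAP piezoelectricity → mechanical stress on the matrix and the
cell.

Every constitutive law is linear and static:

* **Magnetostatics.** Reduced scalar potential,
  `div(μ₀μᵣ(H₀ − ∇φ)) = 0` with `H₀ = B/μ₀`, grounded (φ = 0) on the outer
  boundary. Magnetization is the linear-susceptibility branch with a hard
  cap at saturation, `M = min((μᵣ−1)|H|, Mₛ) · Ĥ`. At 300 mT the 45 nm core
  sits essentially at its (nanoparticle-grade) saturation magnetization.
* **Magnetostriction.** Quadratic isotropic small-signal eigenstrain
  `ε_me = (3/2)(λₛ/Mₛ²)(M⊗M − |M|²I/3)`, traceless by construction, applied
  as a stress-free strain body load in the core. The coupling is one-way
  (no inverse magnetostriction): the study chain is one-directional and the
  strain magnitudes (~10⁻⁴) are far below any magnetic feedback scale.
* **Piezoelectricity (stress–charge form).**
  `σ = c_E ε − eᵀE`, `D = e ε + ε₀ε_rs E`, assembled as one symmetric
  indefinite block in (u, V); symmetry is asserted after assembly. Voigt
  ordering is fixed package-wide to (11, 22, 33, 23, 13, 12) with
  engineering shear strains — the single largest silent-corruption risk in
  piezoelectric finite elements, pinned once in `R/voigt.R` and exercised by
  brute-force tensor-rotation oracles in the tests.
* **Stationary conduction.** `div(σ_c ∇V) = 0` with Dirichlet dipole
  surfaces and a grounded outer boundary. For stages (ii)–(iv) each MENP is
  reduced to its far-field signature: a circular/spherical surface of radius
  70 nm carrying `V₀ cosθ` (θ from the field axis). This is the
  individual-dipole reduction of the single-particle solution, and it is
  what makes the 225-particle concentration study tractable.

The conduction → piezoelectric coupling in stages (iii) and (iv) is
sequential and one-way: the gel/cell conduction solution (HAP treated as
insulating, conductivity ~10⁻¹² S/m) provides the potential trace on the
HAP boundary, which enters the piezoelectric solve as a Dirichlet condition;
the mechanical problem is solved on the particle plus its elastic
neighbourhood. This mirrors the causal chain of the study design (the
current distribution is *detected* by the particle and converted into
force) and avoids an ill-posed monolithic conduction–dielectric interface.

## Material parameters

No tabulated parameter file accompanies the source study, so the fixtures
(`inst/extdata/materials/*.yaml`) transcribe standard literature values,
with the provenance of every constant recorded in the fixture comments:

| material | key values | source rationale |
|---|---|---|
| CFO core | cubic c₁₁/c₁₂/c₄₄ = 286/173/45.3 GPa; μᵣ = 1.25; Mₛ = 5.5·10⁴ A/m; λₛ = −110 ppm | classic single-crystal elastic set; effective permeability and nanoparticle-grade saturation consistent with the reported core magnetization at 300 mT; measured polycrystalline magnetostriction |
| BTO shell | poled-ceramic set: c₁₁ = 150.4 GPa, e₃₃ = 17.36 C/m², ε₁₁/ε₃₃ = 1115/1260 | the set shipped by commercial FEM material libraries |
| HAP | hexagonal c (Katz & Ukraincik); d₃₃ = 2.0, d₃₁ = −0.5, d₁₅ = 1.0 pC/N converted to e = d·c_E; εᵣ = 10 | c-axis-dominant piezoelectricity of hydroxyapatite |
| alginate | E = 30 kPa, ν = 0.45, σ_c = 0.1 S/m, εᵣ = 80 | soft ionically crosslinked encapsulation gel |
| cell | E = 4.5 kPa, ν = 0.45, σ_c = 0.5 S/m, εᵣ = 70 | homogenized osteoblast; cytoplasm-dominated DC conductivity |

Poisson ratios of the soft media are set to 0.45 rather than a
nearly-incompressible 0.49+ because linear simplex elements lock
volumetrically as ν → 0.5; the reported stress quantities change only
mildly. The BTO shell is poled uniformly along z (the field axis), which
reproduces the ± pole-potential pattern of the single-particle solution;
radial poling is the other candidate the study leaves open. The HAP c-axis
is aligned with the particle's long axis; `rotate_material()` applies the
Bond-matrix transformation for the orientation sweep.

A consequence of the conductivity choices: the cell is more conductive than
the dilute gel, so the rod portion facing the gel sees the larger field in
the interface configuration — the ordering the study reports.

## Meshing

No meshing library exists for R, so the package generates structured
simplex meshes itself:

* **Star-ray blocks (2D).** A region between an inner star-shaped curve
  (particle circle, HAP rectangle) and an outer rectangle is meshed by rays
  through matched boundary points with geometrically graded layers
  (default growth 1.35, ~5 nm elements at particle surfaces, ~50 nm in the
  far gel). Multi-block meshes draw their shared-edge nodes from common
  cut-line tables and are conforming by construction; rectangle corners are
  sampled exactly, so the HAP area is exact.
* **Axisymmetric particle meshes.** Polar lattices over θ ∈ [0, π] with the
  domain corners inserted as rays; used for the single-MENP model and for
  the dielectric/magnetizable-sphere benchmark oracles.
* **3D tensor grid with particle shells.** Grid cells away from particles
  become 12 tetrahedra (centroid cone over min-index face triangulations,
  which conform automatically); blocks around each particle are replaced by
  star-ray shells onto the sphere/hexagonal-prism surface. Sphere interiors
  are holes carrying the dipole condition; the prism interior is coned to
  its centroid. At 13 nm rod resolution the meshed prism volume is within
  2% of the closed form and the full mesh holds ~320k tetrahedra; the stage
  default of 16 nm (~200k tetrahedra) keeps a configuration in single-digit
  minutes on one CPU.

`mesh_audit()` checks positive measures, absence of orphan nodes and
complete boundary tagging on every generated mesh; the audits run in the
test suite.

## Numerical choices

* Linear (P1) simplex elements throughout; axisymmetric forms use the 2πr
  measure with centroid quadrature. Degenerate inputs (floating potentials,
  unconstrained rigid modes, under-resolved shells) raise errors rather
  than warnings.
* The coupled (u, V) block is equilibrated (the two diagonals differ by
  many decades) and solved by sparse LU; conduction and magnetostatic
  systems are SPD and solved directly.
* Mechanical boundary conditions: the outer gel boundary is fixed; the
  study text does not state its conditions, and at 1 μm domain scale the
  choice is a documented sensitivity knob rather than a result driver.
  Electrostatic outer boundaries are grounded.
* In stage (iii) the gel stress maximum is reported outside a 5 nm layer
  around the HAP surface: re-entrant corners of the rectangle produce
  mesh-dependent singular peaks, and the exclusion radius is part of the
  reported quantity.
* The stage-(iv) mechanical solve is restricted to a box around the rod
  (±0.2 μm footprint) with clamped cut faces: elastic fields decay within a
  few particle lengths, and a doubling of the box moves the reported maxima
  by far less than the 3D tolerance tier.
* Element-wise P1 gradients carry pointwise sampling noise near strong
  sources; all reported field statistics are therefore integral quantities
  (area/volume-weighted averages, exceedance fractions) or extrema over
  subdomains, and the analytic-oracle tests compare ring averages, not
  point values.
* Problem sizes are chosen for a single desktop CPU: the axisymmetric stage
  solves in seconds at h = 5 nm; the full coverage table takes a few
  minutes; a 3D configuration at the default 16 nm rod resolution runs in
  single-digit minutes. One-step mesh refinement changes the axisymmetric
  stage scalars by <5% and the 3D rod-average field by ~3%.

## The synthetic geometry as study conditions

The generators default to the study's stated conditions: 45/25 nm
core/shell, 1 μm (stage i, iii) and 10 μm (stage ii) gel squares,
concentrations expressed through the printed inter-particle spacings
(1.40…0.65 μm), 50 nm wide HAP particles of length 100–400 nm, a hexagonal
rod of 50 nm across-flats diameter ("edge-to-edge" read as across flats,
side a = 50/√3 nm) and 100 nm length, and a 0.05 μm clearance below the
gel–cell interface in the embedded configuration. The rod straddles the
interface at mid-height in the interface configuration, with the sphere
centres on the plane, and the spheres flank the rod laterally along x at
the 0.65 μm spacing — the relative placement is shown only pictorially in
the source, so both are configuration knobs. Randomised placements
(jittered grids) are seeded and reproducible.

Two printed inputs are internally inconsistent in the source and are
resolved in the particle-spacing direction: the spacing column, not the
coverage percentage, defines the arrangements (the printed coverage cannot
be recomputed from the stated area definition), and the recomputed area
coverage and 3D volume fractions are reported alongside the printed labels.

## What the pipeline does and does not reproduce

With the documented parameter set the single-particle stage lands on the
reference chain within a few percent (core magnetization, interface stress
concentration, ±1.4 mV shell potential, both α_ME estimators), and all
qualitative orderings of the 3D stage hold (interface > embedded cell
stress; gel-side > cell-side rod field; embedded distribution more
uniform).

The absolute field levels of the downstream stages do not reproduce the
reference tables, and the package reports this openly rather than
calibrating it away. With the stated dipole amplitude (±1.36 mV on a 70 nm
surface) the field one decade of distance away is bounded near
10²–10³ V m⁻¹, which caps the achievable coverage fractions at the higher
thresholds; an analytic superposition bound — independent of the
finite-element machinery, and agreeing with it — gives the same numbers.
Reproducing the printed coverage table (e.g. 30.9% of a 10 μm square above
10⁴ V m⁻¹ at 1.40 μm spacing) would require an effective source strength
roughly an order of magnitude larger than the stated amplitude, and the
same multiplicative gap (×5–7) recurs in the 3D rod-field averages. The
2D HAP stress sweep additionally depends on shear piezoelectric
coefficients of HAP that no accompanying table fixes; with the
c-axis-dominant literature set adopted here, the size and orientation
orderings come out differently from the reference (the near-field drive
grows with particle length instead of shrinking). Both gaps are reported
by `compare_to_reference()` and left visible in the acceptance tests.

## Limitations

Static fields only (no AC drive or frequency dependence); no ferroelectric
hysteresis or nonlinear magnetics; homogeneous single-compartment cell; no
fluid environment or protein corona; one HAP particle per scene; linear
elasticity in all media. These match the declared scope of the study the
pipeline mirrors.

## Repository shape

The package exposes every step as a function (`run_menp_stage()`,
`run_concentration_stage()`, `run_hap_stage()`, `run_3d_stage()`,
`run_all()`); the numbered scripts under `analysis/` are thin narrative
drivers over those functions and write their tables under `results/`. They
are the intended command-line entry points; no additional CLI wrapper is
provided.
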