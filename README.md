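# magnetopiezo

Finite-element simulation pipeline for **coupled electrical and mechanical
stimulation of bone cells by magnetoelectric nanoparticles (MENPs) and
piezoelectric hydroxyapatite (HAP)** in an alginate hydrogel.

A core–shell MENP (CoFe₂O₄ core, BaTiO₃ shell) converts an applied DC
magnetic field into a surface electric potential: the magnetized core strains
magnetostrictively, the strain loads the piezoelectric shell, and the shell
polarizes. Arrays of such particles act as "nanoelectrodes" that set up an
electric-field landscape in the gel; a nearby HAP particle — itself
piezoelectric, strongest along its crystal c-axis — converts that field back
into a localized mechanical stress that can reach an adjacent cell. The
package implements the full chain as four analysis stages:

1. **Single particle** (axisymmetric r–z): magnetostatics with a reduced
   scalar potential, magnetization capped at saturation
   `M = min((μᵣ−1)H, Mₛ)`, quadratic magnetostrictive eigenstrain
   `ε_me = (3/2)(λₛ/Mₛ²)(M⊗M − |M|²I/3)`, and the monolithic piezoelectric
   block in stress–charge form

   σ = c_E ε − eᵀE,  D = e ε + ε₀ε_rs E,

   yielding the shell surface potential and the magnetoelectric coefficient
   α_ME (V cm⁻¹ Oe⁻¹) by both conventional estimators.
2. **Concentration study** (10 μm gel): each particle reduced to a dipole
   surface carrying `V₀ cosθ`; a conduction solve gives the |E| field and the
   area fractions above thresholds 10…10⁵ V m⁻¹ per concentration.
3. **MENP pair + HAP particle** (1 μm gel, plane strain): the conduction
   potential traced onto the HAP boundary drives a one-way coupled
   piezoelectric solve; size (100/200/400 nm) and orientation
   (vertical/45°/horizontal) sweeps report von Mises stresses in the particle
   and the gel.
4. **3D gel/cell model**: the same chain with a hexagonal HAP rod and two
   MENP spheres at, or 0.05 μm below, the gel–cell interface; reports the
   field on the rod (split by surrounding medium) and the stress transmitted
   to the cell.

All meshes are generated programmatically (structured star-ray triangle and
tetrahedral meshes); assembly and solves use sparse linear algebra (Matrix).
No external input data are required.

## Worked example

```r
library(magnetopiezo)
res <- run_menp_stage()   # stage (i) at the default 300 mT
print(res)
#> <me_result> B = 0.3 T
#>   max core |M|      : 55000 A/m
#>   max von Mises     : 9910950 Pa in shell
#>   shell surface |V| : 1.437 mV
#>   alpha_ME (field)  : 0.1164 V/cm/Oe
#>   alpha_ME (potent.): 0.0673 V/cm/Oe
```

The 45 nm core magnetizes to its saturation value (5.5 × 10⁴ A m⁻¹ at
300 mT); the magnetostrictive strain concentrates ~10⁷ Pa of von Mises
stress at the core–shell interface, and the shell develops ±1.4 mV on its
surface — a magnetoelectric coefficient of ~0.07–0.12 V cm⁻¹ Oe⁻¹ depending
on the estimator. Downstream stages take this surface potential as the
dipole amplitude:

```r
cov <- run_concentration_stage(0.65e-6)  # densest studied arrangement
round(100 * cov$area_fraction_above, 2)
#>     E>10    E>100   E>1000  E>10000 E>100000
#>   100.00    99.98    72.18     4.06     0.00
```

The whole pipeline, with per-stage outputs under `results/`, runs as

```sh
Rscript analysis/01_single_menp.R
Rscript analysis/02_concentration.R
Rscript analysis/03_hap_sweep.R
Rscript analysis/04_cell_3d.R
Rscript analysis/05_report.R      # consolidated comparison table
```

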