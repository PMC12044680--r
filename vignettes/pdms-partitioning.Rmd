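---
title: "Modeling organic partitioning at PDMS-water interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling organic partitioning at PDMS-water interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pdmslab)
```

pdmslab implements, at desk scale, a molecular-simulation study of how
small phenolic and aromatic-alcohol compounds partition between water
and a polydimethylsiloxane (PDMS) layer — the physical process behind
stir bar sorptive extraction. This vignette is the package's own
account of the model, its assumptions, the tunable parameters, what
the synthetic generators do and do not emulate, and the numerical and
design choices a maintainer would want written down.

## The model

### Interactions

The potential energy is the usual sum of bonded and nonbonded terms:

* harmonic bonds `E = K (r - r0)^2` and harmonic angles
  `E = K (theta - theta0)^2`. The *K*-convention (no factor 1/2)
  matches the large MD engines operating in "real" units; the 1/2-K
  convention is accepted through `bonded_terms(half_k = TRUE)`.
* a four-term cosine (OPLS) dihedral series.
* 12-6 Lennard-Jones plus short-range Coulomb interactions between
  all site pairs separated by three or more bonds; 1-2 and 1-3 pairs
  are excluded, 1-4 pairs are scaled by 0.5 (the OPLS convention,
  configurable via `scale14`).

Units are Angstrom, femtosecond, amu, kcal/mol and elementary charge;
the Coulomb prefactor is 332.064 kcal Å/(mol e²) and k_B =
0.0019872 kcal/mol/K (`pdms_constants`).

### PDMS

PDMS is represented with united-atom sites: Si, siloxane O, and a
single CH3 site per methyl group. The 12-6 parameters come from an
explicit pair table (the tabulated pairs are authoritative and
deliberately do *not* follow Lorentz–Berthelot mixing for sigma), with
the methyl diameter inflated by 3.49% (`apply_ch3_sigma_modification`)
— the refinement that brings the simulated liquid density of PDMS in
line with experiment; the unrefined parent model overestimates density
by roughly 8%. A `build_pdms_oligomer(n)` chain has (n+2) Si, (n+1) O
and 2n+6 methyl sites; n = 1, 2, 3 are octamethyltrisiloxane,
decamethyltetrasiloxane and dodecamethylpentasiloxane. The coating is
modeled as the 80:20-by-weight mixture of n = 1 and n = 2 — 75 and 14
molecules respectively give a weight fraction of 0.803.

### Water and the organics

Water is rigid three-site SPC (O–H 1.0 Å, H–O–H 109.47°), held rigid
during dynamics by SHAKE distance constraints (the H–H distance closes
the triangle). The five organics — phenol, 2-chlorophenol, guaiacol,
benzyl alcohol, phenethyl alcohol — are OPLS-style all-atom templates
built from a hexagonal aromatic scaffold plus substituents.

Cross interactions use Lorentz–Berthelot mixing (geometric mean
epsilon, arithmetic mean sigma) except that every water–organic pair
has its epsilon scaled by 1.20. That factor was originally fitted on
water–phenol transport and is applied to all organics by default
(`pdms_forcefield(scale_all_organics = FALSE)` restricts it to
phenol's site kinds); treating it as universal follows the view that
the same cross-interaction deficiency affects every structurally
similar solute.

Partial charges for PDMS and the organics are documented package
defaults (Si +0.30, O −0.30, CH3 0; SPC charges for water; OPLS-style
charges for the organics). Every partitioning-arithmetic result in the
package is charge-independent; the charges matter only for the
dynamics, where physically reasonable values suffice at this scale.

### Electrostatics

The reference study used a particle-mesh Ewald-family solver. That is
engine-scale machinery with no effect on the package's observable
surface, so the short-range electrostatics here are damped-shifted-force
(Wolf/Fennell form, default, damping `dsf_alpha = 0.2 /Å`) or a
conducting-boundary reaction field, both of which vanish smoothly at
the 12 Å cutoff and reduce to direct Coulomb at short range as the
damping goes to zero. The Lennard-Jones tail is force-shifted by
default so that energy *and* force are continuous at the cutoff —
this is what makes the NVE drift of the integrator negligible
(≈ 1e-6 kcal/mol per site over 10⁴ steps in the shipped check, versus
the 1e-4 bound).

## Dynamics

`run_ensemble()` integrates velocity-Verlet at `dt = 1 fs` (default).
Temperature control is a Nosé–Hoover chain of length 3 (coupling time
100 fs); a Langevin thermostat (`gamma = 0.01 /fs`) is the recommended
fallback for very small systems, where chain thermostats are poorly
ergodic. Pressure control is deliberately *not* an extended-Lagrangian
barostat: at the particle numbers used here (10²–10³ sites) those are
fragile, so NPT uses Berendsen-style weak coupling acting on the
periodic axes only (walls fix x in slab geometries). The compressibility
prefactor is the standard 4.57e-5 /atm; the default coupling time in
the annealing path is 50 fs so that the volume of a tiny box actually
relaxes within a desk-scale dwell. Weak-coupling pressure control does
not generate a rigorous NPT distribution — for the density-trend
observables computed here that bias is irrelevant.

SHAKE projects positions back onto the constraints after each drift
(relative tolerance 1e-8, momentum-conserving), and RATTLE removes
constraint-violating velocity components after the force half-kicks.

The annealing protocol (`anneal`, `anneal_schedule`) dwells at each
temperature from 408.15 K down to 298.15 K in 10 K decrements — 12
levels — reporting per-level mean density and potential energy over
the second half of each dwell.

Pair interactions are evaluated with a cutoff-aware O(N²) double loop.
A cell-linked neighbor list was considered and rejected: at ≤ ~2000
sites the double loop costs a few microseconds per step in compiled
code and keeps the kernel simple enough to audit against the
brute-force R oracle in the test suite.

## The slab system

`build_slab_system()` constructs the two-phase geometry: a PDMS slab
(default 28 Å thick, 40 × 40 Å cross-section) between two 48 Å aqueous
phases, 1 Å interface allowances and 1 Å edge gaps, for a 128 Å box —
water spans 1–49 Å, PDMS 50–78 Å, water 79–127 Å. (The component
widths 48+28+48 = 124 Å and the quoted 128 Å box cannot both be taken
literally; the package resolves this with explicit configurable gap
widths that reproduce the quoted box length and the nominal 50/78 Å
interface positions.) Frozen single-layer FCC(100) wall patches sit at
both x extremes; they interact through a purely repulsive truncated
Lennard-Jones (WCA) potential with PDMS sites only, so the polymer is
confined while water and organics pass freely. x is non-periodic, y
and z periodic. Organic molecules are loaded at the aqueous solubility
limit, `floor(n_water * s/(100 - s))` for a solubility of s mol %
(mole percent is taken as authoritative; the literature mg/L values
are not mutually consistent with the mol % values under any single
density assumption), and are placed in the 10 Å of water adjacent to
each PDMS face so that diffusion toward the interface does not
rate-limit equilibration.

Packing is sequential random insertion with random rigid rotations;
molecules are kept contiguous across periodic boundaries (the minimum
image is applied in distance checks, not to stored coordinates), large
molecules are placed first, and a close-packing bound rejects
impossible requests up front.

## Analysis chain

* `density_profile()` — half-open 1.5 Å bins anchored at the box lower
  edge; each molecule is represented by the x-coordinate of the site
  nearest its centre of mass (ties to the lowest site index), so the
  coordinate always belongs to a physical site.
* `locate_interfaces()` — the interface is where the polymer profile
  crosses 50% of its plateau mean (linear interpolation between bin
  centres); nominal positions can be supplied to reproduce fixed
  reference geometry.
* `partition_counts()` — per frame, each molecule is polymer-phase
  (within the interfaces, margins inclusive: boundaries are closed on
  the polymer side), water-phase, or excluded interfacial (within 3 Å
  of an interface, a margin that removes interfacial-adsorption
  artifacts from the concentrations).
* `log_p()` / `molar_solubility()` — concentration ratio and mol/L
  conversion. Phase volumes are nominal geometric volumes between the
  interfaces (28 and 2 × 48 Å widths at the reference geometry); the
  margin-trimmed volumes are also available but the nominal convention
  is what reproduces the reference solubilities.
* `log_p_sem()` — first-order propagation of the block-averaged count
  standard errors; block averaging (`block_sem`) is the package's
  uncertainty estimator for autocorrelated series throughout.
* `msd()` / `diffusion_coefficient()` — multiple-time-origin MSD of
  molecular centres of mass on unwrapped coordinates;
  `D = slope/(2n)`, converted to cm²/s (1 Å²/fs = 0.1 cm²/s).
* `logp_convergence()` — running log P, declared converged when the
  last-20%-window drift is below 0.05 log units.

## Synthetic generators and oracles

`make_partition_trajectory()` draws trajectories from a
`partition_scenario()`: each molecule carries a two-state
(water/polymer) label, positions are uniform inside the assigned phase
and strictly clear of the exclusion margin, so the analysis chain must
recover the prescribed counts *exactly*, and a prescribed-occupancy
log P to arithmetic precision. Relaxation toward equilibrium is a
two-state Markov jump process per molecule — the simplest process with
the saturating exponential shape of a real approach to equilibrium.
The generator emulates the statistical structure of a slab trajectory
(occupancies, interface softness, exclusion zone); it does not emulate
molecular correlations, interfacial adsorption peaks, or slow
collective dynamics, so passing round trips validate the bookkeeping
and arithmetic of the analysis, not force-field realism.

`make_brownian_trajectory()` draws independent Gaussian displacements
with variance 2 D dt per axis. Because the walk has no ballistic
regime, the low-lag MSD window is unbiased and has the smallest
estimator variance; the D-recovery checks fit lags up to 20% of the
series and recover D to well within 5% at 300 particles × 400 steps.

`widom_log_p()` is the independent thermodynamic oracle:
`mu_ex = -kT ln <exp(-dU/kT)>` from uniform ghost insertions (the two
phases reuse one insertion stream, so swapping the phase arguments
flips log P exactly — an identity the tests assert). In the dilute
limit it reproduces the second-virial form
`mu_ex ≈ 2 kT B2 rho`. Insertions are single-site (the package's
solutes in the toy systems are single LJ sites); multi-site insertion
with orientational averaging was considered and left out as
unnecessary for the oracle's role.

### The counting-vs-insertion experiment

`toy_counting_vs_widom()` is the package's cross-method consistency
experiment on `make_toy_two_phase_system()`: two immiscible LJ fluids
(identical self-interactions epsilon = 0.3 kcal/mol, sigma = 3.4 Å,
cross epsilon 0.03) as adjacent slabs in a periodic box, with dilute
solutes whose attraction to phase A exceeds that to phase B by a
configurable contrast.

Three lessons from building it are worth recording:

1. **The slab pattern drifts.** In a fully periodic box nothing pins
   the two-phase pattern, so fixed counting windows mix phases over a
   long run. Frames are therefore recentred on the circular mean x of
   the phase-A solvent before any counting or insertion.
2. **Mobile solvents equilibrate their mutual solubility slowly.**
   Counting runs and insertion runs of different lengths then sample
   *different* media, which shows up as an apparent systematic
   disagreement. The clean experiment quenches the medium: a
   solvent-only slab is equilibrated and frozen, solutes random-walk
   through it by Metropolis MC, and ghost insertions probe the same
   frozen configuration. Both routes then estimate the identical
   quantity.
3. **Local moves are not ergodic in a frozen dense medium** (solutes
   get trapped in disconnected pockets), so the solute MC mixes local
   displacements with symmetric whole-box teleport moves
   (`jump_prob = 0.2`), a valid Metropolis mixture proposal.

Study conditions — contrast 1.7, solvent 42 particles per 14 Å phase,
16 solutes of sigma 2.6 Å, kT = 0.45 kcal/mol — were chosen once so
that *both* estimators are inside their validity regimes: counting
needs both phases populated and frequent crossings; insertion needs
modest attraction (at strong contrast the Boltzmann average is
dominated by rare deep-energy pockets and converges too slowly).
Agreement is asserted within a pre-registered band of three combined
standard errors; across seeds the typical discrepancy is a few
hundredths of a log unit against a combined SE of ~0.02–0.03.

## Problem sizes and checks

The production systems behind the reference results (6418 waters,
65–100 ns) are cluster-scale. The package's checks run the same code
paths at desk scale, with sizes chosen as the smallest that make each
property measurable:

* integrator: 125-site LJ fluid, 10⁴ NVE steps (drift bound
  1e-4 kcal/mol/site; measured ≈ 1e-6); dt² error scaling checked at
  0.5/1/2 fs.
* rigid water: 12–32 molecules, 2–8 ps NVT (SHAKE deviation ≤ 1e-8
  per projection; thermostat mean within 2% of target).
* annealing: 8 + 2 oligomers, 4 ps per level across the 12-level
  schedule; the observable is the thermal-expansion *sign*,
  density(298 K) > density(408 K). Absolute desk-scale densities
  (≈ 0.5–0.7 g/cm³) sit below the experimental liquid because a
  ~140-site box over picosecond dwells neither reaches full cohesion
  nor samples the true liquid structure; only the sign is asserted.
* slab: 5 + 1 oligomers, 80 waters, 4 phenols, 3 ps NVT for the
  water-in-polymer bound (< 1% of total water).

## Known limitations and non-reproducing values

* Two reference log P values — benzyl alcohol (printed 0.97 ± 0.05)
  and phenethyl alcohol (printed 0.92 ± 0.06 at 298.15 K) — are *not*
  reproduced by the count-based arithmetic under any volume convention
  the package implements (the counts give 1.09 and 1.00); the
  corresponding narrative values disagree with the tabulated ones as
  well. The package treats the tabulated counts as authoritative,
  documents the discrepancy here, and does not assert those two rows.
* A printed water-in-PDMS figure of "12 (0.1%)" is internally
  inconsistent (12/6418 = 0.19%) and is not used; the 35/6418 = 0.55%
  row is.
* Weak-coupling NPT, desk-scale run lengths, and the O(N²) kernel are
  deliberate simplifications, as discussed above.
* Free-energy decomposition, hydrogen-bond analysis and viscosity are
  out of scope; cross-linked PDMS is not modeled.
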