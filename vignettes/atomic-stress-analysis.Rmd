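---
title: "Atomic-resolution virial stress analysis of MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atomic-resolution virial stress analysis of MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atomstress)
```

## The model

`atomstress` computes the per-atom virial stress of a classical
molecular-mechanics system. For atom $i$ the stress tensor is

$$
\sigma_i \;=\; \frac{1}{2 V_i} \sum_j \mathbf{r}_{ji} \otimes \mathbf{f}_{ij}
\;-\; \frac{m_i}{V_i}\, \mathbf{v}_i \otimes \mathbf{v}_i ,
$$

where $\mathbf{f}_{ij}$ is the pairwise force on $i$ due to $j$,
$\mathbf{r}_{ji} = \mathbf{r}_j - \mathbf{r}_i$, $V_i$ is the atom's
characteristic volume, and the kinetic term is optional (it vanishes in the
Lagrangian frame that moves with the atom, and most stored trajectories
carry no velocities). Only the **mean principal stress** — one third of the
trace — is ever computed:

$$
s_i \;=\; \frac{1}{6 V_i} \sum_j \mathbf{r}_{ji}\cdot\mathbf{f}_{ij}
\;-\; \frac{m_i\,|\mathbf{v}_i|^2}{3 V_i}.
$$

The trace is rotation-invariant, needs no off-diagonal tensor components,
and is additive over force-field terms, so the total stress decomposes
exactly into bond, angle, dihedral, Coulomb, van der Waals, generalized-Born
and kinetic contributions. The sign convention is mechanical: positive $s_i$
is tension, and the hydrostatic pressure is $p_i = -s_i$ (a stretched bond
gives negative pressure, an ideal gas positive pressure; both are pinned by
tests). Stresses are reported in kbar
($1\,\mathrm{kJ\,mol^{-1}\,nm^{-3}} = 16.6054$ bar).

### Pairwise decomposition of many-body terms

Angle and torsion potentials are three- and four-body, so their gradients
must be re-expressed as *central* pairwise forces before they can enter a
virial sum. The force set of one term instance has zero net force and zero
net torque, and therefore lies exactly in the span of the central-force
basis vectors of its atom pairs (3 pairs for an angle, 6 for a torsion —
exactly the dimension left after removing the rigid-motion constraints).
We recover the pair magnitudes with a minimum-norm least-squares solve and
verify the residual; a non-representable force set (collinear arms) raises
a degenerate-geometry error rather than silently corrupting the map. Any
central decomposition whose per-atom sums equal $-\nabla V$ yields the same
per-atom stress as published closed forms; per-pair attributions are not
unique, per-atom sums are.

Periodic torsions $V = k_\phi(1 + \cos(n\phi - \phi_s))$ are supported for
$\phi_s \in \{0, \pi\}$ only: for other phases the pairwise decomposition
of this functional form is singular at certain torsion angles, so they are
rejected explicitly.

### OBC generalized Born

Implicit-solvent stresses use the Onufriev–Bashford–Case model: HCT
pairwise descreening integrals $\Psi_i$, the OBC-II tanh rescaling
($\alpha, \beta, \gamma = 1.0, 0.8, 4.85$; offset 0.009 nm), and the
Still pair energy
$f_{GB} = \sqrt{r^2 + R_i R_j e^{-r^2/(4 R_i R_j)}}$ with self terms
$-f(1/\varepsilon_{in} - 1/\varepsilon_{solv})\,q_i^2/(2R_i)$. The energy
gradient contains chain-rule paths through every Born radius; each such
term involves exactly one pair distance $r_{kj}$ and is attributed to that
pair, keeping all GB stress contributions central. The full composition
(radii, energy, forces) is validated against an independent brute-force
reference and central-difference gradients. Dielectrics default to 1
(solute) and 80 (solvent) and are configurable, as is the cutoff. No
nonpolar surface-area term is included.

### Characteristic volumes

Theory requires $\sum_i V_i = V_{box}$ but does not fix per-atom volumes.
With a box, every atom gets $V_{box}/N$; without one (implicit-solvent or
vacuum trajectories), every atom gets a carbon-atom volume, by default a
1.7 Å van der Waals sphere, $(4/3)\pi(0.17\,\mathrm{nm})^3 \approx 0.0206$
nm³ (configurable). Volumes are fixed from the first frame. Because the
volume is a uniform scale factor, relative stress patterns — the quantity
of interest in visualization — do not depend on it.

### Cutoffs and exclusions

Nonbonded pairs (Coulomb, LJ, GB) are enumerated within a cutoff (default
1.0 nm) with minimum-image displacements for orthorhombic boxes; a cutoff
beyond half the shortest box edge is rejected. Bonded-term pairs are taken
from the topology regardless of the cutoff: bonded pairs essentially never
exceed 1 nm, and dropping one would silently break the gradient-consistency
property that validates the whole decomposition. Fully excluded pairs
contribute nothing; 1-4 pairs use the topology's scale factors. Long-range
(Ewald/PME) electrostatic virials are out of scope: the dominant stress
contributions are short-ranged, and the trailing tail mostly shifts the
uniform background.

## Statistics

Residue-level stress is the per-snapshot arithmetic mean over the
residue's atoms. Such averages cannot be re-summed into the system virial
without re-deriving per-residue local frames — they are a visualization and
comparison device, and are documented as such. For time series we report:

* **MSF**, the mean square fluctuation, with population ($1/N_s$)
  normalization;
* **statistical inefficiency** $g = 1 + 2\sum_\tau (1 - \tau/N_s)\rho(\tau)$,
  the autocorrelation sum truncated at its first zero crossing and clamped
  to $\ge 1$;
* **SEM** $= \sqrt{\hat\sigma^2 g / N_s}$, the standard error of a
  correlated mean, with the unbiased ($1/(N_s-1)$) variance inside;
* **difference maps** between two conditions, with SEMs combined in
  quadrature (no SEM is attached to MSF differences).

The SEM is computed on the full series with $g$-corrected variance rather
than on a series thinned by $g$; both are standard, the former wastes no
data.

## The synthetic-data generators

All test inputs are built in code. The micro-structure catalog (1–5 atoms)
provides configurations whose stresses are tractable by hand: equilibrium
and stretched diatomics, a bent triatomic, torsion quadruples at stationary
and generic angles, charged and LJ pairs, and a 5-atom system exercising
every term including GB. The independent oracle is a central-difference
gradient (step $10^{-6}$ nm) of the term energies, which never touches the
decomposition code.

The graphene builder produces honeycomb ribbons (armchair or zigzag edges)
and nanotubes with all bonded terms, exclusions and 1-4 pairs enumerated
from connectivity. Aromatic-carbon parameters are embedded constants from
the GAFF 1.4 "ca" type, converted to the internal
$V = \tfrac12 k (b - b_0)^2$ conventions (bond $k = 400\,325$ kJ/mol/nm²,
$b_0 = 0.1387$ nm; angle $k = 562.2$ kJ/mol/rad², $\theta_0 = 120.02°$;
torsion $k_\phi = 15.17$ kJ/mol, $n = 2$, $\phi_s = \pi$; LJ
$\sigma = 0.33997$ nm, $\varepsilon = 0.3598$ kJ/mol; AMBER 1-4 scales).
Partial charges are zero. A FIRE minimizer relaxes the lattice before
dynamics: under the LJ interactions the honeycomb relaxes to slightly
stretched bonds (~0.139–0.140 nm), and skipping this step superimposes a
global relaxation transient on any stress map. A velocity-Verlet NVE
integrator (with an optional weak harmonic restraint that acts on the
dynamics but never enters the stress) and Maxwell–Boltzmann initialization
complete the mini-MD stack.

What these generators emulate is the mechanics of bonded lattices and
simple fluids under the supported force field terms. What they do *not*
emulate: solvated proteins (no explicit water, no PME), constraint
dynamics (SHAKE virials are out of scope; use unconstrained data), or
conformational heterogeneity of real biomolecular trajectories. Passing
tests therefore demonstrate correctness of the stress calculus, not
biological realism of any particular application.

## The stress-wave experiments

The wave experiments excite an energy-minimized, 1 K-thermalized armchair
sheet (~8×8 nm, ~2 500 atoms) by overwriting the velocities of the ~10
central atoms with 20.5 km/s pulses (1 km/s = 1 nm/ps), then integrate NVE
at 0.05 fs steps, saving every 10 fs. An in-plane radial pulse launches
the longitudinal experiment (0.5 ps); an out-of-plane pulse launches the
transverse one (0.7 ps). These durations cover the time until each front
reaches 80% of the sheet half-extent — the fit cap — after which edge
reflections invalidate a radius-versus-time fit; longer runs only add
contaminated frames. The front radius per frame is the largest distance
from the excitation center among atoms whose metric (|mean principal
stress| for the tensile front, |out-of-plane displacement| for the
transverse wave) exceeds 0.25 of that frame's maximum; the speed is the
least-squares slope of radius versus time (nm/ps ≡ km/s).

Measured on this implementation, the **transverse** deformation front
travels at ≈ 5–7 km/s (threshold-dependent: the flexural ripple is
dispersive and decays as it spreads, so higher relative thresholds track a
slower amplitude contour; the default 0.25 gives ≈ 5.2 km/s). The
**longitudinal** tensile front travels at ≈ 16–19 km/s depending on sheet
size and fit window — the LA sound speed of this force field, consistent
with the experimental graphene sound speed of ~21 km/s. This is
substantially faster than the ~12 km/s sometimes quoted from visual
tracking of the strong tensile band in color-mapped snapshots: in our maps
that high-amplitude band stays near the excitation region while the leading
(weaker) front runs ahead at the sound speed, and no threshold choice makes
the leading front move at 12 km/s. We report the leading-front speed and
document the discrepancy rather than redefining the measurement to match.
The ordering "longitudinal strictly faster than transverse" is robust in
every configuration tested.

## Numerical choices and limitations

* Finite-difference validation uses relative tolerances of $10^{-6}$
  (analytic terms) and $10^{-5}$ (GB composition, which stacks more
  floating-point cancellation).
* The decomposition least-squares residual must be below
  $10^{-8}\,\max(1, \lVert F\rVert)$; otherwise a degenerate-geometry error
  names the term. Degenerate inputs (coincident atoms, collinear angle
  arms, collinear torsion backbones) always raise errors — silent zeros
  would corrupt stress maps invisibly.
* Pair enumeration uses a cell list above 200 atoms and brute force below;
  the two are tested for exact agreement.
* Only orthorhombic boxes are supported; solutes in periodic explicit
  solvent must be pre-wrapped and centered.
* The kinetic term defaults to the raw atomic velocities; an optional
  center-of-mass removal implements a minimal local-frame reference.
  Velocity-free trajectories simply omit the kinetic term.
* B-factor PDB output clamps values to ±999.99 (the %6.2f column width);
  a scale flag accommodates Mbar-scale nanomaterial stresses.
* Problem sizes in the test-suite wave block (6×6 nm sheet, 0.3/0.5 ps)
  and the reproduction script (8×8 nm, 0.5/0.7 ps) were chosen as the
  smallest systems on which the front fits are clean (R² ≳ 0.95) for at
  least ten frames; wave speeds are material properties and do not require
  the original sheet sizes, for which no published dimensions exist.

## A worked micro-example

```{r worked}
cats <- build_test_structures()
e <- cats$bond_stretched         # 0.12 nm bond, b0 = 0.1 nm, kb = 1000
st <- frame_atom_stress(mdframe(e$x), e$top,
                        stress_options(carbon_volume = 0.02))
st[, c("atom", "bond", "total", "hydrostatic_pressure")]
```

The stretched bond pulls both atoms toward each other with 20 kJ/mol/nm;
each atom's mean principal stress is
$20 \times 0.12 / (6 \times 0.02) = 20$ kJ/mol/nm³ $= +0.332$ kbar of
tension, i.e. $-0.332$ kbar of hydrostatic pressure.

```{r residue}
frames <- list(mdframe(cats$combined5$x, 0),
               mdframe(cats$combined5$x * 1.01, 0.5))
df <- atom_stress(cats$combined5$top, frames)
residue_average(df)[, c("frame", "resid", "total", "n_atoms")]
```
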