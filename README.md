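# atomstress

Atomic-resolution virial stress analysis of molecular-dynamics
trajectories, in R.

Mechanical stress — tension and compression — is a fundamental quantity in
macroscopic mechanics but is rarely computed for biomolecules and
nanomaterials, even though proteins, molecular machines and graphene
constructs are routinely discussed in mechanical terms. `atomstress`
post-processes classical MD snapshots into per-atom stresses, for
structural biologists and nanomaterials modelers who want to see where a
molecule is under tension or compression, which force-field term is
responsible, and how those patterns fluctuate and differ between
conditions.

## The quantity computed

For atom *i* with characteristic volume *V<sub>i</sub>*, the mean principal
virial stress (one third of the stress-tensor trace) is

    s_i = 1/(6 V_i) * sum_j  r_ji . f_ij   -   m_i |v_i|^2 / (3 V_i)

where **f**<sub>ij</sub> is the pairwise force on *i* due to *j* and the
kinetic term is optional (off for the usual velocity-free trajectories).
Many-body angle and torsion gradients are decomposed into central pairwise
forces (an exact minimum-norm solve of the central-force representation),
so every force-field term — bond, angle, dihedral, Coulomb, van der Waals
and OBC generalized-Born solvation — contributes additively to the trace.
Positive stress is tension; hydrostatic pressure is its negative. Output
units are kbar (1 kJ/mol/nm³ = 16.6054 bar).

Alongside the stress engine the package provides residue averaging, mean
square fluctuations (MSF), autocorrelation-corrected standard errors
(statistical inefficiency), condition difference maps, PDB B-factor export
for visualization, a portable text topology/trajectory format with a
GROMACS-style `.ndx` reader, and a mini-MD stack (graphene ribbon/nanotube
builder with embedded aromatic-carbon parameters, FIRE minimizer,
velocity-Verlet NVE integrator, wavefront-speed measurement) used for the
stress-wave experiments and as a fixture generator.

## A worked example

A diatomic with a harmonic bond (k = 1000 kJ/mol/nm², b0 = 0.1 nm)
stretched to 0.12 nm, with per-atom volume 0.02 nm³:

```r
library(atomstress)
e  <- build_test_structures()$bond_stretched
st <- frame_atom_stress(mdframe(e$x), e$top,
                        stress_options(carbon_volume = 0.02))
st[, c("atom", "bond", "total", "hydrostatic_pressure")]
#>   atom     bond    total hydrostatic_pressure
#> 1    1 0.332108 0.332108            -0.332108
#> 2    2 0.332108 0.332108            -0.332108
```

The bond pulls each atom inward with 20 kJ/mol/nm, so each atom carries
20 · 0.12 / (6 · 0.02) = 20 kJ/mol/nm³ = **+0.332 kbar of tensile stress**
(equivalently −0.332 kbar of hydrostatic pressure). Compressing the bond
flips both signs.

## Command-line use

The same pipeline runs from a shell on the portable text formats
(`exec/atomstress`, a thin Rscript wrapper around `run_cli()`):

```sh
Rscript exec/atomstress --topology sys.top --trajectory sys.trj \
        --output-prefix out --split
```

writes `out_stress.dat` (per-frame, per-atom stress table in kbar; shown
below for a 5-atom fixture), four PDB files whose B-factor columns carry
the mean and MSF per atom and per residue, and, with `--split`, the same
set for every term plus the bonded/nonbonded sums:

```text
  time_ps atom    bond coulomb       vdw       gb   total
1       0    1 -0.5836 -0.5541  -0.08387  -2.6879  -6.802
2       0    2 -0.9475 -4.8045  -0.19518 -10.7341 -15.843
3       0    3 23.0104  1.2496 -24.39038  -0.5415   6.463
```

Optional flags: `--index file.ndx --group NAME` (atom selection),
`--velocities` (include the kinetic term), `--cutoff` (nm, default 1.0),
`--no-gb`, `--carbon-volume`, `--bfactor-scale`, `--log-level`. Exit codes:
0 success, 1 configuration/parse error, 2 numerical degeneracy.

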