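---
title: "Modeling pyrethroid binding in sodium channel structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling pyrethroid binding in sodium channel structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrenav)
```

## The problem

Pyrethroid insecticides act by binding voltage-gated sodium channels of
insects and stabilizing their activated (open) state. Two receptor sites are
established: PyR1 at the lipid-facing interface of domains II/III (linker
helix IIS4-S5, outer helix IIS5, inner helix IIIS6 and the IIP region) and
PyR2 at the I/II interface. Knockdown-resistance (kdr) mutations cluster in
and around these sites; many others lie far away and are thought to act
allosterically, by distorting the packing between the segments that build the
sites.

`pyrenav` is a desk-scale toolkit for this structural analysis: universal
residue nomenclature and its mapping to native numbering, structure
superposition, a reduced molecular-mechanics model with Monte Carlo
minimization in internal coordinates, multi-start ligand docking with
energy-window filtering and contact-driven pose selection, targeted
transformations between gating states, geometric interaction detection, and
a machine-readable atlas of kdr mutations. Everything runs on synthetic,
fully specified fixtures, so the pipeline is testable end to end without
external structure predictions or cryo-EM templates.

## Universal residue labels

A label such as `2k11` addresses domain II, segment `k` (the S4-S5 linker
helix), position 11; segments `o`, `p` and `i` are the outer helix S5, the
P-loop and the inner helix S6. The dual notation `M918/2k11` couples the
label to the native house fly numbering used by the resistance literature.

The mapping between native numbers and universal labels is anchor data, not
an algorithm: for each (domain, segment) span the annotation records which
native residue carries universal index 1. The packaged house fly annotation
was solved from the dual labels of the curated mutation tables themselves,
and reproduces every one of them exactly:

```{r}
atlas <- load_kdr_atlas()
mm <- atlas$mutations[!is.na(atlas$mutations$universal), ]
lm <- assign_labels(mm$native, housefly_annotation(), aa = mm$wt)
sum(lm$label[match(mm$native, lm$resno)] != mm$universal)  # mismatches
```

Two printed sub-regions (the second P-loop half of domain II, and the deep
cytoplasmic end of IS6) are offset by one residue relative to their
neighbors; the annotation therefore allows several non-overlapping sub-spans
per segment, each with its own anchor, rather than forcing one origin per
segment. Universal indices must stay unique within a (domain, segment);
violations are load-time errors.

Site membership of the PyR1/PyR2 sites is likewise per-label data compiled
from the tables, never derived from segment identity — IIS6, for instance,
contributes its shallow positions (2i12-2i16) to PyR2 and its deep positions
(2i18-2i26) to PyR1.

## Superposition

Structures are compared after rigid superposition of the P1-helix C-alpha
atoms, the most conserved part of P-loop channels. The fit is the standard
SVD-based Kabsch solution with the reflection correction; pairing is by
identical universal label plus atom name, and unpaired atoms are dropped
with a message (superposing across different channels routinely leaves
unmatched spans). An independent quaternion-based implementation serves as
the test oracle.

## The reduced energy model

The energy model is deliberately small and fully documented, a named and
swappable component rather than a transferable force field:

* 12-6 Lennard-Jones with Lorentz-Berthelot combining (united-atom heavy
  atoms; sigma chosen so contact minima fall at 3.1-3.8 A);
* Coulomb electrostatics with the distance-dependent dielectric
  eps(r) = 4r, a common implicit-membrane surrogate, with the constant
  332.0637 kcal A/(mol e^2) and an 8 A cutoff without switching;
* a 10-12 hydrogen-bond well (optimum 2.9 A, depth 3 kcal/mol) between
  donor and acceptor heavy atoms, replacing their Lennard-Jones term, with
  donor/acceptor *saturation*: candidate pairs are matched greedily so each
  donor donates once and each acceptor accepts once, the rest reverting to
  Lennard-Jones. Without saturation a single hydroxyl could "bond" several
  acceptors at once, which rewards unphysical poses;
* an explicitly directional halogen-bond term for C-X...A sigma-hole
  contacts (X in Cl/Br/I; A in S/O/N): a 10-12 well at the van der Waals
  radius sum minus 0.25 A, depth 3.5 kcal/mol, attenuated by the squared
  deviation of the C-X...A angle from linearity and gated at 150 degrees.
  This makes bromine-sulfur contacts energetically favorable, not merely
  geometrically detectable;
* three-term cosine torsions on declared rotatable bonds; harmonic angle
  terms only where declared elastic (e.g. proline rings); harmonic
  positional restraints `k |x - x0|^2` as the morphing mechanism.

Degrees of freedom are generalized coordinates: torsion rotations about
declared bonds and rigid-body moves of mobile units; bond lengths and
angles never change. Backbones are fixed by default; side-chain chi
torsions and ligand torsions plus the ligand rigid body are mobile.

Local minimization is derivative-free block coordinate descent (cyclic line
searches with shrinking windows), exactly reproducible. Monte Carlo
minimization alternates random moves in the generalized coordinates with
local minimization under greedy acceptance (Metropolis optional), so the
accepted-energy sequence is non-increasing by construction. On a rugged
two-torsion toy the minimizer reaches the exhaustive 5-degree grid optimum
from random starts in at least 95 of 100 seeds.

## Docking protocol

Docking follows the multi-start recipe: `n` random starting poses (uniform
position in a box derived from the site residues' side-chain centroids,
uniform orientation, uniform torsions), Monte Carlo minimization of every
pose against the rigid receptor, collection of the poses whose
ligand-channel interaction energy lies within 5 kcal/mol of the apparent
global minimum (the best energy found — no claim of converged global
optimality), and selection of the pose contacting the largest number of
known sensing residues, ties broken by lower energy. The interaction energy
is the sum of receptor-ligand cross terms, identical to
E(complex) - E(receptor) - E(ligand).

Refinement is hierarchical: every start receives a light minimization; the
low-energy subset is then run to convergence, including systematic
180-degree flips about the ligand inertia axes, because elongated ligands
have near-degenerate flipped binding families whose basins are only
reachable from the right side. The pose reported per start is the visited
candidate with the lowest interaction energy (the start included), so
refinement never worsens a pose. Receptor side chains are held fixed during
pose refinement; the synthetic fixtures plant side chains at relaxed
positions, and receptor relaxation is available through the general MCM
machinery when needed.

Both binding orientations of the ester axis relative to the pore axis are
reported per pose and never merged: the two families are a real feature of
pyrethroid binding, with comparable energies, and the pipeline does not
pretend to discriminate them beyond the stated selection rule.

## Targeted state transformations

Gating transitions are emulated by driving selected C-alpha atoms stepwise
toward template coordinates: at step t of n the targets are the linear
interpolation start + (t/n)(target - start). Monte Carlo minimization is
performed with fixed backbones, so by default the restrained C-alphas are
*pinned* at the interpolated positions (their residues translate rigidly)
while side chains relax; this makes the null transformation an exact
identity and the distance-to-target decay exactly linear on clash-free
fixtures. Harmonic restraints with constant k (default 10 kcal/mol/A^2)
drive the backbone instead when `relax_backbone = TRUE`. Relaxation is
restricted to residues actually displaced, and bound ligands are refined and
scored at every step. Non-convergence (final selected-C-alpha RMSD above the
0.5 A tolerance) raises a warning and flags the trajectory, never silently.

Voltage-sensor deactivation shifts the S4 C-alphas of one domain along the
pore axis (oriented from the selectivity filter to the gate, i.e.
extracellular to cytoplasmic) by a configurable displacement (default
4.5 A — an operational value, not a biophysical claim), with the N-end of
that domain's S4-S5 linker soft-restrained at k/10 so it follows the sensor.

## Interaction criteria

All geometric thresholds live in one place (`interaction_criteria()`):
contacts at 4.0 A (boundary inclusive, side-chain heavy atoms by default,
since binding-site figures draw side chains; any-atom mode by flag);
hydrogen bonds at D...A <= 3.5 A with D-H...A >= 120 degrees (hydrogens
inferred along D->A when absent, which satisfies the angle clause
trivially); halogen bonds at X...A within the van der Waals sum + 0.2 A and
C-X...A >= 140 degrees; salt bridges at any carboxylate-O to basic-N
distance <= 4.0 A (missing side chains give NA, never FALSE); "weakened"
contacts at a distance increase above 0.5 A; pi stacking reported
descriptively at ring-centroid distance <= 5.5 A, with no energy term.
These are standard literature values; the source analyses name the
interactions but not their criteria.

## The synthetic fixtures

The mini-channel is a test instrument, not a channel model: four
pseudo-symmetric domains of ideal helices (k, o, i of 12 residues; an
8-residue P-loop hairpin whose first five residues are the P1 helix), two
gating states sharing P1 exactly and differing only by a prescribed 3 A
radial shift of the inner-helix cytoplasmic halves plus a 1.5 A cytoplasmic
drop of the linker helices, and an optional S4 helix per domain carrying
three arginines for voltage-sensor fixtures.

A lipid-facing pocket at the II/III interface hosts a toy Type II ligand
(ester core, strongly dipolar nitrile-like group, two bromine sigma-hole
donors, an aromatic ring, four rotatable torsions; the Type I variant swaps
chlorines in and the nitrile out). Host residues on 2k/2o/3i are assigned
automatically: a hydrogen-bond donor for each ligand acceptor (placed with
exact two-link inverse kinematics where reachable), a sulfur/oxygen acceptor
on each halogen's sigma-hole axis, an arginine against the nitrile dipole,
and hydrophobic sleeve arms at van der Waals contact for shape
complementarity; remaining positions are alanine. Structural pairs (an
intersegment hydroxyl-hydroxyl hydrogen bond in domain I, and an
Asp-Arg salt bridge between the IIS5 top and the IIS4 sensor when S4 is
included) exercise the corresponding detectors.

`make_docking_truth()` relaxes the planted pose to the bottom of its
designed well through converged line-search refinement plus in-basin Monte
Carlo kicks, verifies by the brute-force contact oracle that the relaxed
pose realizes a sensing contact set spanning k, o and i segments, checks
that re-refinement displaces it by under 0.3 A (a genuine local minimum),
and computes which contacts the inactivated state loses or weakens.

What the fixtures do *not* emulate: realistic sequences or helix packing,
membrane and water, entropic effects, and — importantly — a uniquely
recoverable global binding pose. The reduced landscape retains several
near-degenerate pose families 0.2-1 kcal/mol and a few Angstrom apart,
which is faithful to the modeled system (pyrethroid docking yields two
orientation families of comparable energy that cannot be discriminated),
but it means that independent 200-start runs recover one specific planted
placement far less often than they recover its contact fingerprint. Tests
of single-pose recovery at 1.5 A therefore fail under the default
conditions and are retained as an honest negative result; the
contact-level and exact (oracle) properties of the protocol all hold.

## Problem sizes and numerical choices

Test runs use scales chosen to keep the suite quick:
the default mini-channel (176 residues, ~740 atoms), 200 docking
starts per run with the low-energy 30 poses refined to convergence,
10-seed repetitions of the stochastic docking properties, 10-step morphs,
100-seed repetitions of the cheap Monte Carlo optimality property, and
50-100 random fixtures for each oracle-equality property. Random number
use is always seeded; fixtures are bit-identical across builds. Ties in
line searches resolve toward the incumbent (moves are applied only when
they strictly improve), and degenerate inputs (empty selections, collinear
point sets, missing parameters, unresolvable labels) raise typed errors
rather than silent results.

## Known limitations

The force field is a reduced surrogate: no explicit solvent or lipid, no
entropy, simple electrostatics; energies are rough enthalpy estimates at
best. Side-chain geometry in the fixtures is schematic (near-linear arms
with exact tips). Docking treats the receptor as rigid during pose
refinement. The atlas transcribes four curated tables and does not extend
them. Pose-level docking reproducibility is limited by the landscape
degeneracy discussed above.
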