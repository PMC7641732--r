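---
title: "Structural analysis of protein-RNA aptamer interfaces"
author: "aptaface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural analysis of protein-RNA aptamer interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptaface)
```

## Scope

Nucleic-acid aptamers bind their protein targets through folded 3D
structures whose recognition determinants — buried surface, hydrogen-bond
networks, extruded ("flipped-out") bases inserted into protein pockets —
are read off deposited crystal structures. `aptaface` implements that
reading as a reusable toolchain: solvent accessibility and buried surface
area, interface residues, crystal-packing contacts, hydrogen bonds and
base stacking across an interface, Leontis–Westhof base-pair annotation
with stems, loops and flipped-out bases, apo/holo RMSD comparison,
centroid clustering of conformational ensembles, and batch survey
statistics over many complexes. Every stage is testable without external
data through deterministic synthetic generators that carry their own
ground truth.

## Solvent accessibility and buried surface area

`compute_sasa()` implements the Shrake–Rupley quadrature: each heavy atom
is assigned a van der Waals sphere (Bondi radii; configurable), expanded
by the probe radius (1.4 Å, a water molecule), and sampled with a
deterministic Fibonacci-spiral lattice of `n_points` quadrature points
(default 960). A point survives if it lies outside every neighbour's
expanded sphere; the accessible area is the surviving fraction of the
expanded sphere's area. The lattice is deterministic, so results are
exactly reproducible — there is no RNG anywhere in the SASA path. At 960
points an isolated sphere is reproduced to machine precision and the
two-sphere spherical-cap closed form to ~0.4%; halving the error requires
roughly four times the points, and the 960/4000-point totals differ by
well under 1% on fixtures.

Buried surface area follows the standard convention

$$\mathrm{BSA} = \mathrm{SASA}(A) + \mathrm{SASA}(B) - \mathrm{SASA}(AB),$$

computed over the two chain partitions with waters and ligands excluded.
Interface residues are identified either by ΔSASA (a residue losing more
than 0.1 Å² on complexation — the small positive threshold conventional
interface services use) or by distance (any heavy atom within 5 Å of the
other partition); both criteria are exposed because published interface
counts rarely state which rule produced them. The per-side "fraction of
surface buried" is the area that side loses divided by its free-state
SASA, which normalises per molecule and reproduces the way interface
percentages are quoted for each binding partner.

`enumerate_crystal_interfaces()` generates symmetry mates from the cell
and operator list (parsed from the file where present, otherwise from a
small built-in table covering triclinic, monoclinic, orthorhombic and the
tetragonal 4<sub>1</sub>/4<sub>3</sub> screw groups), within ±1 unit-cell
translation by default. Each contacting asymmetric-unit/mate chain
pairing is scored by BSA; the symmetric duplicate of every interface (the
mate's view of the same contact) is removed by canonicalising each
(operator, lattice shift, chain pair) against its inverse operator.

## Hydrogen bonds and stacking

Deposited crystal structures carry no hydrogens, so `find_hbonds()` uses
heavy-atom criteria: a donor is an N, O or S atom that chemically bears a
polar hydrogen (per-residue tables for amino acids and nucleobases), an
acceptor is an N, O or F atom with a lone pair, and a bond requires
2.4 Å ≤ d(D···A) ≤ 3.5 Å together with an angle of at least 90° at the
donor between its covalently bonded heavy-atom antecedent and the
acceptor — the usual proxy for D–H···A linearity when hydrogens are
absent. Fluorine is admitted **only** as the ribose 2′-F acceptor of
2′-fluoro-modified nucleotides, reflecting the chemistry of
nuclease-stabilised pyrimidines; each bond is labelled by the nucleic
moiety involved (nucleobase, phosphate backbone, or ribose — the latter
two merged to "backbone" in survey statistics, matching the
nucleobase/backbone dichotomy used in comparative analyses).
`find_water_bridges()` emits one record per (polar atom, water, polar
atom) triple whose two legs each satisfy the direct-bond distance rule.

`find_stacking()` detects π-stacking between nucleobase rings and
Phe/Tyr/Trp/His side-chain rings with three thresholds: ring-centroid
distance ≤ 5.5 Å, inter-plane angle ≤ 30°, lateral centroid offset ≤
2.5 Å perpendicular to the mean ring normal. Contacts against
non-aromatic side chains (e.g. an alanine methyl packing under a base)
define no ring plane and surface instead through
`find_nonpolar_contacts()` (carbon–carbon ≤ 4.5 Å).

## Base pairs, secondary structure, flipped-out bases

`detect_base_pairs()` screens nucleotide pairs geometrically — base ring
centroids within 12 Å, base planes within 40°, centroid *stagger* (offset
along the mean normal) ≤ 2.0 Å — and requires at least one inter-base
polar contact in the hydrogen-bond window whose direction makes ≥ 50°
with both base normals. The stagger and in-plane angle criteria are what
separate coplanar pairing from stacking: a stacked neighbour sits one
helical rise (~3 Å) along the normal, a paired base essentially in plane.
Surviving pairs receive Leontis–Westhof classes: the interacting edge of
each base (Watson–Crick, Hoogsteen, or Sugar) is assigned from which edge
atom group contributes the bonding atoms (ties resolved WC > Hoogsteen >
Sugar), and the cis/trans orientation from whether the two sugars lie on
the same side of the axis through the glycosidic nitrogens. The side
vectors run from each ring centroid to its C1′ atom rather than along the
short N–C1′ bond, which keeps the sign stable under coordinate noise. A
pair is *canonical* when both edges are Watson–Crick, the orientation cis
and the bases complementary (A–U, G–C, and G–U wobble by default,
configurable).

`derive_secondary_structure()` builds stems as maximal runs of
consecutive nested pairs; an isolated noncanonical pair flanked on both
sides by canonical pairs is absorbed into its stem, so a mismatch in the
middle of a helix does not split it. Loops are classified from the gap
topology (hairpin, internal, bulge), with the convention that loop
nucleotides are the unpaired residues between stem boundary pairs — the
closing pair belongs to the stem. A dot-bracket string is emitted with
bracket tiers for crossing pairs and a pseudoknot flag.

`detect_flipped_out()` flags a nucleotide as flipped out when (a) it is
unpaired, (b) its base centroid lies farther from the local helical axis
than the mean paired-base distance plus 2.5 Å, and (c) it stacks on
neither sequence neighbour. The local axis is anchored on the nearest
stem pairs (two on each side by default). One axis point per stem pair is
taken as the midpoint of the two partners' base-ring centroids, which
lies close to the true axis; the C1′–C1′ midpoint does not (it is
displaced toward the minor groove) and a line through such points tilts
badly when few pairs are available. With three or more axis points a
principal-axis line is fitted; with fewer, the direction is the
sign-aligned mean base normal of the selected pairs — base planes are
perpendicular to the helix axis, so this stays stable where a two-point
line fit would not. A chain with no stems at all falls back to distances
from the global C1′ centroid, with a warning.

## Conformational comparison

`compare_conformations()` matches holo and apo structures atom-by-atom
(chain mapping defaults to shared ids, falling back to pairing the
longest chains of each polymer class), superposes the apo structure once
on the **global Cα match**, and reports four RMSDs in that single frame:
global and interface-restricted, each over Cα and over all heavy atoms,
plus per-residue Cα displacements. One shared frame is essential to the
comparison's logic: quoting an interface RMSD larger than the global one
as evidence of localised change only makes sense if both numbers are
measured in the same reference frame. Unmatched atoms are dropped
symmetrically and counted, so the denominators behind every RMSD are
visible in the report.

## Ensemble clustering

`cluster_ensemble()` implements energy-cutoff-plus-clustering reduction
of a conformational ensemble. First the lowest-energy fraction (default
10%, `ceiling(f·N)` members, energy ties broken by lower model index) is
selected. Two selected members are *neighbours* when their pairwise RMSD
is strictly below the threshold (default 5.0 Å); RMSD is computed after
optimal superposition by default, since trajectory snapshots are not
pre-aligned (flag exposed). The member with the most unassigned
neighbours (ties: lower model index) becomes the next centroid; the
centroid plus its unassigned neighbours form the next cluster; the
procedure repeats on the remainder until everything is assigned or
`max_clusters` (default 10) is reached, leftover members being reported
as singleton overflow. A member is not counted as its own neighbour, and
a neighbour-free member forms a singleton cluster, so the clusters always
partition the selection and the ranked sizes are non-increasing by
construction. The module contains no RNG; identical inputs give identical
results.

## Synthetic fixtures: what they do and do not emulate

The generators produce structures whose ground truth is known by
construction and re-verified from the emitted coordinates before they are
returned:

* `build_aform_duplex()` places standard base reference-frame geometries
  on ideal A-form helical parameters (rise 2.81 Å, twist 32.7° per step);
  the complementary strand is the 180° rotation about the pair x-axis, so
  every Watson–Crick pair carries its textbook 2.85–3.0 Å hydrogen bonds.
  Optional isotropic Gaussian noise is redrawn (bounded, seeded retries)
  until the planted pairs remain measurable and no unplanted pair-like
  contact appears, keeping the declared truth exact.
* `build_hairpin()` closes such a stem with an unpaired loop on a spiral;
  designated loop positions are extruded far from the axis and laterally
  offset from their neighbours (planted flipped-out bases), the rest stay
  near the axis extension.
* `build_toy_complex()` pairs the hairpin with a poly-alanine helix and
  realises each planted hydrogen bond, water bridge, and stacking contact
  with probe residues placed along the first of a deterministic set of
  candidate directions that keeps every other polar atom out of the
  detection window (serine hydroxyls at the exact requested distance,
  phenylalanine rings parallel to the target base, waters with both legs
  at the requested distance).
* `build_toy_crystal()` positions an elongated molecule in a P2₁ cell so
  that exactly one screw-axis mate makes contact.
* `build_planted_ensemble()` draws well-separated reference conformations
  (pairwise superposed RMSD above the separation, re-sampled until
  satisfied), populates clusters with Gaussian jitter, and optionally
  adds high-energy decoys so that the energy filter retains exactly the
  planted members.

These fixtures are geometric, not physical: the ribose/phosphate backbone
is schematic (no sugar pucker, no realistic torsions), bases are rigid
ideal plates, helices carry no sequence-dependent deformation, probe
"residues" are minimal, and ensemble energies are labels rather than a
force field. Passing tests therefore demonstrate that the detectors
recover geometry they are specified to recover — distances, planes,
neighbour counts — not that thresholds are optimal for experimental
coordinates with refinement artefacts, alternate conformers or missing
atoms. Thresholds follow field conventions precisely so that the step to
real structures is a change of input, not of method.

## Numerical choices and problem sizes

All detectors are deterministic; randomness exists only in generators and
is always seeded, with the caller's RNG state restored. Coordinate
round-trips are asserted to 10⁻³ Å (PDB fixed-column precision).
Alternate conformers are reduced at parse time to the highest-occupancy
altloc (ties: alphabetically first), and all geometric criteria operate
on heavy atoms only. The test and acceptance workloads use small problem
sizes chosen to exercise every code path — duplexes of 2–8 pairs,
hairpins of 13 nucleotides, 20-member oracle ensembles, and a
1680-member ensemble whose 10% energy filter retains 168 members in
planted clusters of 69/61/38 — which keep the full suite in the
tens-of-seconds range on one CPU.

## Known limitations

* The built-in space-group table covers the groups used here; other
  groups need operators supplied in the file (mmCIF symop loop or
  PDB REMARK 290).
* Edge assignment ties on sparse hydrogen-bond evidence default to the
  Watson–Crick edge; borderline noncanonical pairs may differ from
  curated annotations by one class.
* The heavy-atom hydrogen-bond test cannot distinguish donor from
  acceptor when both atoms are chemically ambidextrous; the reported
  orientation then follows the partition order while the bond count does
  not.
* `read.cif` support rides on bio3d's reader (beta); unusual mmCIF
  dialects may need conversion to PDB.
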