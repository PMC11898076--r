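---
title: "GRAIL-based interaction fingerprints: models, parameters and design choices"
author: "gradeFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GRAIL-based interaction fingerprints: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradeFP)
```

## The descriptor model

gradeFP turns a receptor structure plus a ligand pose into a fixed-length
floating-point vector. Unlike bit-string interaction fingerprints, every
pose-dependent entry is a *quality-weighted* aggregate of feature-pair
scores

$$FIS_{ij} = C_{ij}\, DS_{ij}\, AS_{ij},$$

with $DS, AS \in [0,1]$ distance and angle kernels and $C_{ij}$ a
weighting factor that is 1 for all types except hydrophobic–hydrophobic
pairs, where it is the product of the two per-atom logP increments. Two
aggregates are stored per scored type pair: the plain double sum and the
"max sum" $\sum_i \max_j FIS_{ij}$, which counts each ligand feature's
best partner once and is therefore bounded by the double sum. Coverage
entries apply the same distance kernel between receptor H-bonding
features and ligand heavy atoms that *cannot* form the complementary
interaction, quantifying receptor H-bond capacity buried by the pose. The
physics block adds unscaled Coulomb sums $\sum q_i q_j / r_{ij}^x$
($x \in \{1, 2\}$) and a Morse van der Waals split

$$E_{rep} = \sum D_{IJ} e^{-2\alpha (r - x_{IJ})},\qquad
  E_{attr} = -2 \sum D_{IJ} e^{-\alpha (r - x_{IJ})},$$

whose total reaches its minimum $-D_{IJ}$ exactly at $r = x_{IJ}$ — a
softer and more forgiving shape than a Lennard-Jones 6–12 around
crystallographic-quality distances.

Assumptions worth stating plainly: poses are taken as given (no docking,
no minimisation); explicit hydrogens are trusted (an optional rule-based
protonation pass exists but defaults to off); the electrostatic terms are
deliberately not permittivity-scaled, because downstream models reweight
each descriptor element anyway; and the binding site is the set of whole
receptor residues with a heavy atom within a cutoff of the ligand.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| binding-site cutoff | 7.0 | Å | covers the longest-range scored interactions (ionic/π at ≤ 5.5 Å) with margin |
| Morse well width α | 1.1 | – | the method's stated constant |
| hydrophobic threshold | 0.15 | logP units | per-atom increment at or above which an H feature is emitted; also fixed by the method |
| charge scheme | `mmff94` | – | MMFF94 via the OpenBabel CLI; falls back per molecule to an internal PEOE implementation with a warning |
| interaction parameter table | see below | Å, ° | editable YAML (`writeInteractionParams()` / `readInteractionParams()`) |

The shipped interaction windows follow standard pharmacophore geometry:
H-bonds 2.5/2.8–3.2/3.8 Å with a D–H···A constraint (ideal 180°,
tolerance 50°); hydrophobic contacts 3.0/3.5–4.5/5.5 Å with no angle
term; aromatic stacking 3.0/3.3–4.0/5.5 Å with plane-angle and offset
constraints; cation–π 3.0/3.4–4.5/5.5 Å with an axial constraint; halogen
bonds 2.8/3.0–3.6/4.0 Å with a C–X···A constraint (ideal 165°, tolerance
45°). Every number can be overridden wholesale from a config file without
touching code; the kernel *shapes* (below) are the package's fixed
numerical contract.

## Numerical choices

**Kernels.** The distance kernel is a plateau with cubic smoothstep
ramps: 1 on the ideal window, 0 outside the support, $3t^2 - 2t^3$ in
between, so ramp midpoints score exactly 0.5 and the descriptor is $C^1$
in the coordinates. Angle kernels take the value 1 at zero deviation and
smoothstep to 0 at the tolerance. Angles involving a ring normal are
folded to [0°, 90°] because a plane normal has no sign. A pair whose
required geometry (donor hydrogen, ring normal, halogen-bound carbon) is
missing drops that constraint with a warning rather than failing.

**Ties and degeneracies.** `max_j` is a plain maximum — ties carry no
information since only the value enters the vector. An empty binding site
yields an all-zero pose-dependent block, not an error. Coincident
ligand/receptor atoms (r = 0) are an error naming the pair. Coverage uses
the distance kernel only: a bare carbon defines no donor axis, so no
angle term is meaningful.

**Charges.** MMFF94 charges come from the OpenBabel executable
(SDF → MOL2 conversion with `--partialcharge mmff94`). The fallback is an
in-package PEOE (Gasteiger–Marsili) iteration: 6 damped rounds, formal
charges as seeds, exact total-charge conservation. Receptor fragments
read from PDB carry no formal charges, so under PEOE an aspartate
carboxylate is neutral-by-construction; the electrostatic terms keep
their sign and ordering but shrink in magnitude. Tests that assert exact
values therefore pin the deterministic PEOE path.

**Lipophilicity.** Hydrophobic placement needs *per-atom* increments, so
the package ships a compact atomic-contribution table
(`inst/extdata/logp_increments.csv`) keyed on element, hybridisation,
hydrogen count, aromaticity and heteroatom attachment. It is a deliberate
simplification of full atomic-contribution logP schemes: lipophilic
carbons (aliphatic CH₂/CH₃, aromatic C, halogens except F on carbon)
clear the 0.15 threshold, polar atoms go negative. The table is part of
the configuration: swapping in any other per-atom scheme changes weights,
not architecture.

**UFF parameters.** Within UFF the nonbond well depth and equilibrium
distance depend only on the element, not the hybridisation-level atom
type, so the bundled table (`inst/extdata/uff_params.csv`) is keyed by
element and covers all 103 naturally occurring elements. Polar hydrogens
(H on N/O/S) have their $x$ halved *before* geometric-mean combining.

## The X-GRADE layout

The 31-entry ligand block resolves the generic HBD/HBA counts by the
Sybyl subtype of the parent atom (8 donor classes, 10 acceptor classes,
with an OTHER class completing each partition, so subtype counts always
sum to the generic totals). For the 146 pose-dependent entries the
package generates a systematic, fully documented expansion of the basic
layout:

* coverage enumerated over the full 13-class subtype vocabulary
  (12 Sybyl types + OTHER) for both receptor HBA and HBD — 52 entries.
  Using the uniform vocabulary keeps both coverage blocks the same shape;
  a handful of slots (e.g. an O.co2 donor) are chemically impossible and
  are structural zeros by construction;
* the HBD↔HBA and HBA↔HBD score pairs expanded once over the *ligand*
  feature subtype (9 + 11 type-correct classes) and once over the
  *receptor* feature subtype (11 + 9) — 80 entries, so a model can see
  both "which ligand donors engage" and "which receptor acceptors are
  engaged";
* the five non-H-bond pairs and the four physics terms unchanged — 14.

A hard assertion (`52 + 80 + 14 = 146`, total 177) guards the expansion:
any edit that breaks the published shape fails loudly. The family order
follows the basic layout's backbone, and every max-sum entry sits
directly after its sum entry in both variants.

## What the synthetic fixtures emulate — and what they do not

`makePanel()` builds seven single-interaction complexes from chemically
valid capped fragments (serine-, leucine-, phenylalanine-, amide- and
aspartate-like receptor pieces; methanol, propane, benzene,
methylammonium and bromobenzene ligands): hydrogen bond, hydrophobic
contact, aromatic stack, cation–π, halogen bond, a salt-bridge-geometry
control (which verifies that no ionic interaction slot exists in the
layout), and a far-apart null complex whose pose-dependent block must be
identically zero. Gaussian coordinate jitter (σ = 0.05 Å, seeded)
exercises kernel continuity without leaving the score plateaus, and the
fixtures are written/re-read as standard PDB + SDF to cover the I/O
path.

These fixtures are *unit geometries*, not binding pockets: they contain
single residues, no water networks, no conformational strain, no
crowding, and their "receptor" fragments are far smaller than a real
site. A green suite therefore demonstrates that the descriptor computes
its published shape and scores its declared geometries correctly — it
says nothing about predictive performance on real protein–ligand data,
which depends on training data and models outside this package's scope.
Problem sizes were chosen accordingly: panels of 7 complexes, oracle
sweeps of 100 random configurations, and 10 random rigid transforms per
invariance check.

## Known limitations

* Pharmacophore perception is rule-based on the input structure: no
  tautomer enumeration, and pH-dependent protonation is only available as
  a crude optional pass. Structures lacking explicit polar hydrogens
  under-report donors.
* Receptor bonds are perceived from covalent radii with a minimal
  carbonyl refinement; unusual ligands embedded in the receptor file
  (covalent modifications, exotic cofactors) may be mistyped.
* The internal lipophilicity table is compact by design; increments for
  heavily functionalised carbons are coarser than a full published
  scheme.
* Grid-based precalculated interaction maps are out of scope — all
  scoring is direct pairwise evaluation over the extracted site, which is
  the right trade-off at binding-site scale (hundreds of atoms) but not
  for whole-protein scans.
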