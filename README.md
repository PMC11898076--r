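# gradeFP

Fixed-length interaction-fingerprint descriptors for protein–ligand
complexes, for anyone building structure-based machine-learning models
(binding-affinity regression, complex visualisation, 3D-QSAR) who needs a
compact, floating-point featurisation of a receptor + ligand pose.

Most interaction fingerprints record interactions as bits or integer
counts. GRADE instead scores every putative nonbonding contact with a
bounded, geometry-aware quality term. For a ligand pharmacophoric feature
*i* and a binding-site feature *j*,

    FIS_ij = C_ij · DS_ij · AS_ij

where DS and AS are distance- and angle-dependent kernels in [0, 1] and
C_ij = 1 except for hydrophobic pairs, where it is the product of the two
features' per-atom logP increments. Per interaction type *A–B* the
descriptor stores two aggregates:

    IS_sum     = Σ_i Σ_j FIS_ij
    IS_max.sum = Σ_i max_j FIS_ij      (always ≤ IS_sum)

The full vector combines:

* a **pose-independent ligand block** — pharmacophoric feature counts
  (PI, NI, AR, H, HBD, HBA, XBD, XBA), heavy atoms, rotatable bonds,
  total hydrophobic weight, XlogP-type lipophilicity, TPSA;
* **binding-site H-bond coverage** — pseudo H-bond scores between
  receptor HBA/HBD features and ligand heavy atoms that cannot reciprocate
  (Cov_sum and Cov_max.sum per receptor type);
* **seven GRAIL interaction-score pairs** — PI↔AR, AR↔PI, H↔H, AR↔AR,
  HBD↔HBA, HBA↔HBD, XBD↔XBA (ligand type listed first);
* **physics terms** — unscaled Coulomb sums Σ q_i q_j / r_ij^x for
  x = 1 (potential) and x = 2 (pairwise force sum), plus a Morse-potential
  van der Waals split with UFF parameters,
  E_rep = Σ D_IJ e^(−2α(r−x_IJ)), E_attr = −2 Σ D_IJ e^(−α(r−x_IJ)),
  α = 1.1, with the UFF x halved for polar hydrogens.

Two variants share this anatomy: **GRADE** (35 = 13 + 22 elements) and
**X-GRADE** (177 = 31 + 146), which resolves every H-bond-related family
by the Sybyl subtype of the parent atom (N.3, N.ar, O.co2, …).

## Worked example

The package ships a synthetic-fixture generator, so a complete run needs
no external data. An idealised hydrogen bond (serine-like receptor
fragment, methanol ligand, donor–acceptor distance 2.9 Å, D–H···A angle
180°):

```r
library(gradeFP)
cplx <- makeHbondFixture(distance = 2.9, angle = 180)
v <- assembleDescriptor(cplx, variant = "GRADE")
vals <- descriptorValues(v)
round(vals[vals != 0], 4)
#>                    HBD feature count                    HBA feature count
#>                               1.0000                               1.0000
#>                    XBA feature count                     heavy atom count
#>                               1.0000                               2.0000
#>                                XlogP                                 TPSA
#>                              -0.5600                              20.2300
#>                     HBA coverage sum                HBA coverage max. sum
#>                               0.2212                               0.2212
#>                     HBD coverage sum                HBD coverage max. sum
#>                               0.2212                               0.2212
#>                HBD <-> HBA score sum           HBD <-> HBA score max. sum
#>                               1.0000                               1.0000
#>              electrostatic potential sum of pairwise electrostatic forces
#>                              -0.0160                              -0.0188
#>                       VdW attraction                        VdW repulsion
#>                              -3.9275                               7.3579
```

Reading it: methanol offers one donor, one acceptor (XBA mirrors the
acceptor set); the ideal geometry gives the HBD↔HBA pair a perfect score
of 1.0 (sum = max-sum: a single partner); the methyl carbon partially
covers the receptor hydroxyl (0.22); and the close contact shows up as a
net-attractive electrostatic term with the expected Morse
attraction/repulsion balance. Zero entries (aromatic, ionic, halogen and
hydrophobic slots) are genuinely absent interactions, not missing values.

Batch mode consumes a CSV manifest (`id,receptor_path,ligand_path`) of
PDB/mmCIF receptors and SDF/MOL2 ligand poses:

```r
manifest <- writeFixturePanel("panel", seed = 1)   # 7 synthetic complexes
batchCompute(manifest, "descriptors.csv", variant = "XGRADE")
#> computed 7/7 complexes (success rate 100.0%)
```

or from a shell: `exec/gradefp batch panel/manifest.csv --variant=XGRADE`.

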