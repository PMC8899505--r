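# chemtk

An integrated cheminformatics and machine-learning toolkit for ligand-based
drug discovery in R. `chemtk` covers the everyday loop of a virtual-screening
project inside one package: reading and standardizing molecules, computing
composable descriptors, measuring substructure similarity, building feature
datasets, and training/evaluating QSAR models under cross-validation.

## What it does

* **Molecular graphs and SDF I/O** — MDL SDF V2000 reading and writing
  (gzip transparent), hydrogen saturation, charge neutralization,
  smallest-set-of-smallest-rings perception, Hückel aromaticity, kekulized or
  explicit-aromatic output, and valence validation.
* **Molecule applications** — sequential property/substructure filtering,
  duplicate removal at four comparison levels (constitution, configuration,
  conformation, exact), descriptor-based reordering, fragment splitting
  (Murcko scaffolds, rings, chains, rigid parts, MCS fragments), and
  coordinate utilities.
* **Descriptor framework** — a small "code object" language over named
  properties: `Combine`, `Define`, `Less`/`Greater`, `Multiply`, `Constant`,
  `MoleculeSum` and friends; Lipinski/Veber druglikeness; Gasteiger–Marsili
  sigma charges; Ertl TPSA; Mannhold logP; and signed 2D/3D autocorrelations.
  For an atomic property *P*, the autocorrelation accumulates
  `A(r_a, r_b) = sum_i sum_j delta(r_a <= r_ij < r_b) P_i P_j`
  over all ordered atom pairs, binned by bond-count (2DA) or Euclidean (3DA)
  distance and sub-binned by the sign pair of (P_i, P_j).
* **Similarity** — maximum common connected and disconnected substructures by
  partition-based branch and bound, with Tanimoto
  `TC = |A∩B| / (|A| + |B| − |A∩B|)` and Tversky indices, substructure
  containment, symmetry-corrected RMSD, Kabsch superposition, and scaffold
  alignment.
* **Datasets** — a self-describing header+binary `.bin` format, CSV
  interconversion, seeded randomization, contiguous chunking, column joins,
  minor-class balancing, PCA, and k-means row reduction.
* **Models and screening metrics** — dropout neural networks trained by
  backpropagation with momentum, decision trees with four split partitioners,
  Cholesky ridge regression, Kohonen self-organizing maps with
  applicability-domain scoring, ROC/AUC/logAUC, MCC, enrichment factors, and
  localPPV calibration, all orchestrated by a chunk-based cross-validation
  driver with prediction merging.

## Worked example

Compare the EGFR inhibitors gefitinib and afatinib by maximum common
substructure:

```r
library(chemtk)
gef <- builtin_molecule("gefitinib")   # 31 heavy atoms
afa <- builtin_molecule("afatinib")    # 34 heavy atoms

tanimoto(mcs(gef, afa, connected = TRUE))
#> [1] 0.4772727
tanimoto(mcs(gef, afa, connected = FALSE))
#> [1] 0.8571429
```

The connected MCS (21 atoms: the quinazoline core, the halogenated aniline
and one aryl ether) gives a Tanimoto coefficient of about 0.48; allowing a
union of disjoint common pieces raises the matched-atom count to 30 and the
coefficient to about 0.86 — the two drugs differ mostly in their solubilizing
tails.

Druglikeness properties through the descriptor language:

```r
evaluate_descriptor("Combine(Weight, NRotBond, TopologicalPolarSurfaceArea,
                             LipinskiViolations)", gef)
#> [1] 446.907   8.000  68.740   0.000
```

Gefitinib weighs 446.9 Da with 8 rotatable bonds, a TPSA of 68.7 Å², and no
violations of the rule of five.

A complete QSAR round on synthetic data:

```r
ds <- randomize(synthetic_qsar(400, 6, seed = 21), 99)
cv <- run_cv(ds, "NeuralNetwork(hidden architecture(16), steps per update = 20)",
             n_folds = 5, max_iterations = 15, seed = 7)
cv$pooled_score      # pooled AUC over the five independent folds
#> [1] 0.9795313
```

The same operations are available from a shell through the bundled `toolkit`
script (installed under `exec/`), e.g.

```sh
Rscript $(Rscript -e 'cat(system.file("exec","toolkit",package="chemtk"))') \
  molecule compare -files gefitinib.sdf afatinib.sdf \
  -method LargestCommonSubstructureTanimoto -output similarity.csv
```

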