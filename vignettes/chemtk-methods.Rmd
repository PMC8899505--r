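---
title: "Models and methods behind chemtk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chemtk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemtk)
```

`chemtk` is a cheminformatics and QSAR/QSPR toolkit: molecules come in as MDL
SDF records, are standardized and featurized through a composable descriptor
language, compared by common substructures, and fed into trainable models
evaluated with virtual-screening objectives. This vignette explains the
science implemented in each layer, the tunable parameters with their
defaults, the numerical choices, and what the bundled test surface does and
does not demonstrate.

## Molecular graphs and standardization

A molecule is a labelled graph: atoms carry element, formal charge,
coordinates (Å, as stored in the SDF) and an aromatic flag; bonds carry a
kekulé order in {1,2,3} plus aromatic, ring, amide and E/Z flags. Bond orders
are always stored kekulized, so writing a valence-explicit SDF requires no
re-derivation; explicit-aromatic output (MDL order 4) is available as a flag.

**Ring perception** finds ring bonds by bridge detection, then a smallest set
of smallest rings: the shortest cycle through every ring bond, deduplicated
and reduced to a GF(2)-independent basis of size `|E| − |V| + components`.

**Aromaticity** is assigned by the Hückel 4n+2 electron count over
sp2-eligible atoms, ring by ring and then over fused envelopes of rings that
fail individually. Electron contributions: an atom double-bonded within the
ring (or to any other ring atom, as at ring fusions) contributes one
electron; an exocyclic double bond to a non-ring atom (a ring carbonyl)
contributes zero; lone-pair donors (pyrrole-type N, furan-type O/S,
carbanions) contribute two. This is the de-facto standard model; exotic ring
systems (fulvenes, mesoionics) may be flagged differently by other toolkits,
which matters only at the margins of substructure comparison.

**Valences** come from a fixed table (C 4; N 3, 4 when protonated; O 2, 1
when anionic; S 2/4/6; P 3/5; halogens 1), with charge adjustments applied
symmetrically. Implicit hydrogens fill an atom up to the smallest allowed
valence; `add_hydrogens()` makes them explicit and is idempotent.

**Neutralization** is a best-effort rule table: anionic O/S are protonated,
cationic N loses a hydrogen when it has one, and adjacent +/− pairs (ylides)
are resolved by incrementing the bond order when both valences allow; nitro
and N-oxide groups and quaternary nitrogens are left intact. Schemes
`pH_only` and `bond_order_only` restrict to one mechanism. The rule set is
deliberately conservative — anything it cannot fix retains its charge.

**Kekulization** of explicit-aromatic input solves a perfect matching over
the atoms that need one double bond, by backtracking. An aromatic nitrogen
without an explicit hydrogen is assumed pyridine-type: the MDL order-4
convention cannot distinguish pyrrole-type N without an explicit H or a
valence annotation, which is a known limitation of that convention.

## The descriptor language

Descriptors are operator trees over named properties, written in a plain-text
grammar that mirrors the command line: `Combine(Weight, LogP)`,
`Define[VeberDruglike = Less(lhs = LipinskiViolationsVeber, rhs = 1)]`,
`2DASmoothSign(property = Atom_SigmaCharge)`. Parentheses, brackets and
braces are interchangeable; keyword keys are matched ignoring case, spaces
and underscores; `@file` splices descriptor files. Aliases live in an
explicit evaluation context so several strings can share definitions.
Evaluation is pure: repeated calls are bit-identical, molecule properties
yield fixed-length vectors, atomic properties one value per atom. Names not
found in the registry fall back to the molecule's MDL data block, which is
how experimental labels (e.g. `IsActive`) become model targets.

Key properties and their definitions:

* `Weight` — standard atomic weights including implicit hydrogens.
* `HbondDonor` — N/O atoms carrying at least one hydrogen, counted once per
  heavy atom (not per hydrogen); `HbondAcceptor` — all N and O atoms.
* `NRotBond` — non-ring single bonds between heavy atoms of heavy-degree ≥ 2,
  excluding amide C–N bonds (a common convention).
* `TopologicalPolarSurfaceArea` — the Ertl fragment-contribution table for N
  and O environments; the molecular value is defined as the sum of the
  per-atom contributions, so `MoleculeSum(Atom_TopologicalPolarSurfaceArea)`
  agrees with it identically. S/P contributions are excluded by default.
* `LogP` — Mannhold's atom-count formula `1.46 + 0.11·nC − 0.11·nHet`, a
  deliberately simple closed-form estimate.
* `Atom_SigmaCharge` — Gasteiger–Marsili partial equalization of orbital
  electronegativity: charge flows along each bond from the less to the more
  electronegative atom with damping 0.5^k over six iterations, seeded by the
  formal charges. Implicit hydrogens are resolved as temporary explicit atoms
  so that charges on fully explicit molecules sum to the total formal charge.
* `LipinskiViolations` counts failures of HBD ≤ 5, HBA ≤ 10, MW < 500,
  logP < 5; `LipinskiViolationsVeber` of TPSA < 140 Å² and NRotBond ≤ 10;
  `LipinskiDruglike` is 1 below two Lipinski violations.

**Signed autocorrelations.** For a per-atom property *P*, every ordered atom
pair (i, j) — including i = j — contributes `P_i P_j` to the distance bin
containing r_ij, measured in bonds (2DA, unit bins, 11 by default) or in
Ångström (3DA, 0.25 Å bins to 6.0 Å). Each distance bin holds three sign
sub-bins (−/−, +/+, and pooled mixed signs); zero values count as positive so
the partition is deterministic, and the sub-bins sum exactly to the unsigned
autocorrelation. The 3DA smooths each pair's contribution over neighbouring
bins with a triangular kernel of half-width one bin, whose weights sum to one
— the precise smoothing used by other implementations is not published, so
the conformance tests rely on the unsmoothed identity and on invariances
(atom permutation and conformer change for the 2DA, rigid motion for the
3DA) rather than on the kernel shape. Extending 3DAs much beyond 6 Å mostly
adds conformational noise in flexible molecules, which is why the default
range stops there.

## Substructure similarity

Comparison types define atom and bond equivalence: `ElementType` matches by
element, `AtomType` adds hybridization inferred from bond orders and
aromaticity; bond levels range from exact order matching through
`BondOrderOrAromatic` (the default: aromatic bonds match aromatic bonds
regardless of kekulé assignment) to an amide/isometry/ringness-aware code.
Hydrogens are excluded from all substructure comparisons.

The **maximum common substructure** is found with a McSplit-style partition
branch and bound: vertices of both graphs live in label classes split by
their bond codes to each newly mapped pair, and the bound is the mapped count
plus the sum of `min(|class A side|, |class B side|)`. The connected variant
restricts branching to classes adjacent to the current mapping. Tie-breaks
are deterministic (smallest atom index first), and a search budget guards
against pathological inputs — exceeding it is an error, never a silent
truncation. An independent maximum-clique search on the modular product graph
is kept in the test suite as an oracle and must agree exactly on all small
fixture pairs.

The **disconnected MCS** is computed by iterated extraction: find the
connected MCS, remove the matched atoms from both molecules, and repeat on
the leftovers — single-atom pieces included — until either leftover graph has
fewer than two atoms or nothing matches. The first piece is the connected
MCS itself, so the disconnected matched-atom count (and hence its Tanimoto
coefficient) never falls below the connected one. We chose this termination
rule over two alternatives we implemented and measured — a minimum piece size
of two, and the unconstrained maximum common induced subgraph — because the
extraction-to-exhaustion semantics reproduces the worked-example similarity
of the bundled gefitinib/afatinib pair (21 + 5 + 3 + 1 = 30 matched atoms,
TC ≈ 0.857) while the alternatives under- or over-count (0.81 and 0.71
respectively); the induced variant also penalizes pieces for cross-piece
adjacency, which has no chemical motivation when the pieces are meant to be
independent fragments.

Similarity scores follow the Tanimoto ratio of matched to unmatched heavy
atoms and its Tversky generalization. `symmetry_rmsd()` minimizes the
in-place coordinate RMSD over graph automorphisms enumerated under
aromatic-aware bond codes (kekulé-sensitive codes would break the 60°
rotational symmetry of benzene); the enumeration is capped at 5000
automorphisms with a documented fallback to identity order.
`align_to_scaffold()` superimposes each molecule onto the scaffold over its
MCS atoms (or the scaffold's largest rigid component, or explicit atom lists)
with the Kabsch algorithm — a proper rotation from the SVD of the
cross-covariance with a determinant correction.

## Feature datasets

The `.bin` format is a plain ASCII header (magic line, id label and width,
feature and result labels, row count) followed by fixed-width ASCII ids and
little-endian float32 payload, row-interleaved; missing results are stored as
NaN. Storage is float32 (screening-scale datasets dominate memory), all
in-memory arithmetic is double, and both bin and CSV round trips are lossless
at their respective precisions (CSV is written with 17 significant digits).

Transformations keep ids and rows aligned. Chunks are contiguous — block b of
k gets rows `floor(bn/k)+1 … floor((b+1)n/k)` — so the cross-validation idiom
is "randomize once, then chunk". `combine_datasets()` joins feature columns
over identical id sequences (the typical case of two encodings of the same
molecules); row stacking is a separate flag. Balancing oversamples the minor
class in seeded cycling order to a target minor/major ratio with a per-row
repeat cap; PCA eigendecomposes the covariance of centered features and keeps
the smallest leading set reaching the requested variance fraction; k-means
row reduction uses Lloyd iterations with k-means++ seeding, re-seeding empty
clusters from the farthest point (written in-package because the empty
cluster policy and bit-level seeding determinism are part of the format
contract).

## Models

All models share input scaling (`AveStd` for continuous features, `MinMax`
for sparse/discretized ones), seeded determinism (two runs with the same seed
are bit-identical), and a self-describing JSON text serialization that
round-trips predictions exactly.

**Neural networks.** Forward propagation is `z(l+1) = w(l+1) y(l) + b(l+1)`,
`y(l+1) = f(z(l+1))` with sigmoid or (leaky) rectifier hidden transfers; the
output layer is linear, which serves classification targets in [0, 1] under
an MSE loss as well as regression targets (a saturating output would pin
rectifier-network regressions). Training is backpropagation with classical
momentum, `Δw(t) = −η ∇ + α Δw(t−1)` (defaults α = 0.5, η = 0.05),
mini-batches of `steps_per_update` rows (0 = full batch). Dropout multiplies
each layer's outputs by Bernoulli masks redrawn every batch at per-layer
rates p (input layer first); at test time the corresponding weights are
scaled by 1 − p instead, and p = 0 reproduces test mode exactly. Missing
result entries contribute zero gradient, which is what makes sparse multitask
result matrices trainable. The model returned is the one with the best
monitor score; there is no early termination (dropout is the regularizer),
and a monitor chunk on which the objective is undefined (single-class AUC)
simply does not participate in model selection.

**Decision trees.** Greedy recursive partitioning on midpoint thresholds
between consecutive sorted unique feature values. Partitioners:
`InformationGain` (entropy, base 2), `Gini`, `ROC` (the local split AUC
`max((sens+spec)/2, 1−(sens+spec)/2)`), and `Sequence` (only splits leaving a
pure child). Node scores rank candidate splits (`SplitRating` by default);
ties break to the lowest feature index, then lowest threshold. Recursion
stops when a node's incorrect count is at most `min_split` or no admissible
split remains; leaves predict the active-class fraction. `dt_to_logic()`
prints the tree root-first and exports an exactly equivalent descriptor
expression built from `Add`/`Multiply`/`Less`/`GreaterEqual` over the feature
descriptors — `Add` is a small extension to the operator set, required
because products alone cannot merge two mutually exclusive branches.

**Linear regression.** `(XᵀX + λI)β = XᵀY` by Cholesky factorization, the
intercept unpenalized; a singular system at λ = 0 is an error advising
positive smoothing.

**Self-organizing maps.** Nodes on a rectangular (non-toroidal) grid,
initialized from randomly chosen training rows. The neighborhood radius
follows `radius(t) = radius₀ (1 − (t+1)/(4·length))`, clamped at zero — with
radius₀ = 7.5 and length = 140 it starts at 7.48661 and reaches exactly zero
at t = 559. (The schedule's prose description elsewhere — that the radius
reaches zero after `length` iterations — contradicts the formula; the formula
is implemented.) Winners are best matching units under squared Euclidean
distance; weights update as `w ← w + α β (x − w)` with β = 0.8 for the winner
and 0.2 for other in-radius nodes, α = 1 (Bubble) or a Gaussian in the grid
distance. Batches accumulate mean updates per node before applying; with
radius 0, Bubble kernel and batch size 1 the procedure reduces exactly to
winner-only online k-means at rate 0.8, which the tests assert against a
hand-rolled loop. The **applicability domain** score of a compound is the
fraction of training rows whose own closest-node distance is strictly smaller
— one pooled distance distribution shared by all nodes — so a score of 0.90
means farther from the map than 90% of the training set, scores of training
rows are approximately uniform, and far-outside points score near 1.

## Screening objectives and calibration

Contingency metrics (accuracy, PPV, MCC) return 0 with a warning on
degenerate denominators. ROC curves sweep unique prediction values with ties
grouped; AUC is the trapezoidal integral of TPR over FPR restricted to
[min_fpr, max_fpr] and normalized by the span. The logAUC integrates the
piecewise-linear TPR(FPR) exactly on a log₁₀ FPR axis over [0.001, 0.1] (the
early-enrichment window) and normalizes by the log-span; the diagonal
classifier then scores `(0.1 − 0.001)/ln 100 ≈ 0.0215`, which the tests pin.
The enrichment factor is the PPV among the top x% ranked rows over the
prevalence. localPPV calibrates raw model outputs to local positive
predictive values by a sliding-window PPV over prediction-sorted rows
(window = 1% of rows, at least 50 — the window size is a package choice, not
a published value) made monotone by pool-adjacent-violators; evaluation
interpolates linearly and clamps to [0, 1].

## Cross-validation driver

`split_cv()` makes chunk f both the monitoring and the independent set and
trains on the rest, so across folds the independents partition the dataset;
this reuse is appropriate precisely because monitoring is not used for early
termination. `run_cv()` trains one seeded model per fold, stores
`model000000…` files, pools the per-fold independent predictions (same-id
rows averaged, disjoint ids concatenated), reports per-fold and pooled
final-objective scores, and can fit a localPPV calibration stored beside the
models. `PredictionMean` and `PredictionInfo(..., metrics(LocalPPV))` expose
stored model ensembles as descriptor properties, so composites like "mean
prediction where the local PPV exceeds 0.5" are ordinary descriptor
expressions; the feature specification is stored next to the models so a
molecule can be featurized consistently at prediction time.

## The synthetic test surface

The bundled structures are canonical literature constitutions with synthetic
3D coordinates; they exercise the full chemistry path (perception,
descriptors, similarity) at the scale of real drugs. The synthetic QSAR
generator draws standard-normal features, scores them with a hidden linear
(optionally tanh-squashed) rule, thresholds at a quantile for class labels
with optional label noise, and returns the ground truth for recovery tests;
class imbalance mimics the sparse-active regime of screening data at reduced
scale (hundreds to thousands of rows — the vignette's and tests' problem
sizes are chosen so the whole suite runs in minutes on one core). What
passing tests show is that the machinery is correct: gradients, invariances,
recovery of planted parameters, format round trips. What they cannot show is
performance on real assay data — real descriptors are correlated and heavy
tailed, real labels are noisy in structured ways, and real actives cluster in
chemotypes; conclusions about model quality on such data require external
benchmarks.

## Known limitations

* Aromaticity and neutralization are rule tables; exotic ring systems and
  unusual charge patterns may be perceived differently from other toolkits.
* Tetrahedral parity and E/Z are perceived from 3D coordinates only (no wedge
  bonds), and parity is skipped at centers with symmetry-equivalent
  neighbours.
* The conformation-identity tolerance (best-match RMSD < 1e-4 Å after
  superposition) for duplicate removal is a choice; toolkits differ on
  whether superposition is applied at all.
* V3000 SDF records are rejected; SMILES input is out of scope (structures
  enter via SDF or the fixture registry).
* The MCS budget makes worst-case searches fail loudly rather than run
  unboundedly; extremely symmetric molecule pairs may need a larger budget.
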