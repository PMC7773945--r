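---
title: "Pose-invariant binding free energy estimation: models, descriptors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pose-invariant binding free energy estimation: models, descriptors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science inside `raspdplus`: the regression
model and its assumptions, the descriptor definitions down to the atom
level, every tunable parameter with its default and rationale, the
numerical and design choices made where the method description leaves
room, and what the synthetic test bed does and does not establish.

## 1. The regression problem and its assumptions

The package estimates the binding free energy ΔG (kcal/mol) of a
protein–ligand complex from 20 physicochemical descriptors, none of which
depends on a docked pose. The underlying assumptions are:

* Binding strength is dominated by bulk interaction capacity — van der
  Waals contact area (tracked by molar refractivity, molecular weight and
  the Wiener index), hydrogen-bonding capacity (donor/acceptor counts on
  both partners) and the hydrophobic effect (logP) — rather than by the
  precise geometry of any single interaction.
* The binding-site position is known or assumed (a co-crystallised
  ligand's centre of mass, or a user-supplied point). The query ligand
  influences the protein side of the featurization only through one
  scalar, maxD (its maximal extent from its centre of mass), which sets
  the radii of the selection spheres. This is what makes the descriptors
  pose-invariant: two conformers of equal maxD featurize identically.
* Metal coordination is not modelled. Training complexes with a metal ion
  within 2.1 Å of the ligand are excluded (`filter_metal_contacts()`,
  plain centre–centre distances, strict-inequality discard so an atom at
  exactly the cutoff keeps the complex).

Experimental affinities are converted by ΔG = RT ln K at T = 298.15 K
with R = 1.9872×10⁻³ kcal/(mol·K), treating Kd, Ki and IC50 identically.
The sign convention is chosen so that K = 1 M maps to exactly 0 and
stronger binders (smaller K) get more negative ΔG, matching how affinity
data are reported; ΔG is strictly increasing in K. Mixing IC50 with true
dissociation constants is a known source of label noise that the model
simply inherits. When one complex carries several measurements the
precedence is Kd > Ki > IC50 (decreasing thermodynamic directness), then
the smallest value.

## 2. Ligand descriptors

`ligand_descriptors()` returns MASS, D, A, logP, MR, W plus maxD.

* **MASS** sums standard atomic weights, counting implicit hydrogens
  inferred from standard valences (C4, N3, O2, S2, P3, halogens 1,
  charge-adjusted) so SMILES-derived and hydrogen-stripped inputs agree.
* **D and A** count donor and acceptor *atoms*, not hydrogens: D = N/O
  atoms bearing at least one hydrogen; A = all N/O atoms except
  nitro-group N and O and aromatic N–H (pyrrole-type, whose lone pair is
  in the ring π system). The rule set is deliberately simple and fixed;
  it classifies an amide as one donor (N) and two acceptors (carbonyl O
  and N). Chemically the amide N is a poor acceptor, but a fixed
  documented rule beats an undocumented sophisticated one for
  reproducibility, and the same rule is applied consistently at training
  and screening time.
* **logP and MR** are sums of the published Wildman–Crippen atomic
  contributions. The contribution *values* are the published constants;
  the atom *typer* is a procedural classifier over the package's
  molecular graph (element, aromaticity, neighbours, bond orders,
  charges) covering C/H/N/O/S/P/halogens plus metal fallback classes.
  Implicit hydrogens contribute as hydrogens typed by their parent atom.
  The typer is validated against an independent reference implementation
  on fixture molecules (methane, ethanol, benzene, n-butane, cyclohexane,
  acetamide, an aspirin-like fixture) to 10⁻³ in both logP and MR.
* **W**, the Wiener index, is the sum over unordered heavy-atom pairs of
  shortest-path lengths in bond counts (hydrogens excluded, standard
  definition — including hydrogens would make W depend on preparation).
  Shortest paths come from igraph; the test suite checks the
  closed form n(n²−1)/6 for path graphs and brute-force BFS on 200
  random connected graphs. Disconnected heavy-atom graphs sum within
  components, with a warning.
* **maxD** is the maximum distance from any atom to the mass-weighted
  centre of mass over all atoms present. Mass weighting follows the
  phrase "centre of mass" literally; using the geometric centre would
  shift maxD by well under the 0.9 Å selection margin for typical
  ligands.
* **Salts**: multi-component inputs are reduced to the largest
  heavy-atom component (by total mass, ties to lowest atom index) before
  description, since screening libraries carry counter-ions.

## 3. Pocket descriptors

`select_pocket()` draws two concentric spheres around the site centre:
residues enter by centre of mass within maxD + 0.9 Å (for the MR/logP
sums), atoms within maxD + 3.0 Å (for the hydrogen-bond counts). Both
boundaries are inclusive; residue centres of mass are mass-weighted over
the atoms actually present in the file. The two extensions are the
method's fixed constants, exposed in the configuration (`res_ext`,
`atom_ext`) but not meant to be tuned.

**MR/logP sums.** Because crystal structures lack hydrogens, per-residue
Wildman–Crippen contributions are precomputed from ACE/NME-capped
template graphs of the twenty amino acids (`residue_crippen()`): each
heavy atom's contribution includes its template hydrogens, so a
hydrogen-free PDB sums correctly, and missing side-chain atoms simply
drop their share. Templates use physiological protonation (Asp⁻/Glu⁻,
Lys⁺/Arg⁺, neutral His with the proton on NE2). The aromatic residue set
is {Phe, Trp, Tyr, His}. Unknown residue types contribute backbone
counts only, with a warning.

**Donor/acceptor groups.** A shipped mapping table
(`donor_acceptor_map()`) assigns each (residue, atom name) to at most one
of the five donor groups and at most one of the four acceptor groups.
Within each family the groups are disjoint at atom level — no double
counting — but a single atom may be both a donor and an acceptor (Ser/Thr
hydroxyls), which is chemically right and produces the expected strong
correlation between the hydroxyl donor and neutral-acceptor features.
Decisions the table encodes:

* Backbone N is a donor for every residue except proline; backbone O is
  always an acceptor. Terminal OXT is deliberately unassigned.
* Lysine NZ sits in the positively charged donor group only, although
  the group naming would also admit it among the neutral amines; a
  single assignment avoids silent double counting.
* Neutral histidine donates through NE2 and accepts through ND1 (the
  common tautomer); HID reverses the two, HIP puts both ring nitrogens
  in the charged donor group. Without explicit hydrogens a plain "HIS"
  is treated as the neutral NE2-H tautomer — protonation states simply
  cannot be read from a hydrogen-free PDB, so the conservative neutral
  assignment is the default.
* Protonated Asp/Glu (residue names ASH/GLH) move the hydroxyl oxygen
  into the hydroxyl donor group and count the carbonyl oxygen as a
  neutral acceptor; plain ASP/GLU are charged acceptors on both
  carboxylate oxygens.

**Scaling.** The 13 residue-derived values are divided by maxD,
normalising pocket content by ligand size; PVol is *not* scaled, because
it is not residue-derived and already carries volume units.

**PVol** is a grid-probe stand-in for cavity-analysis tools: count grid
points (default spacing 0.5 Å) inside the maxD sphere lying farther than
(Bondi vdW radius + 1.4 Å water probe) from every protein heavy atom,
times the voxel volume. It converges to analytic values as the grid
shrinks — the tests require ≤ 2 % error against the empty-sphere volume
at 0.25 Å and ≤ 5 % against a half-space fixture — and halving the grid
moves realistic-pocket estimates by under 5 %. The default 0.5 Å trades
~1 % accuracy for a ~8× speedup; spacing and probe radius are exposed.

## 4. Learning protocol

`raspd(dG ~ . - id, data, ...)` runs the nested cross-validation:

* 10 outer replicates, each holding out round(0.125 n) rows (seeded).
* The remaining pool is shuffled into 6 near-equal folds (sizes differ
  by at most one).
* For every hyperparameter combination, one model per fold is trained on
  the other five folds; the combination with the highest mean validation
  Pearson r wins. Ties break to the simplest model (fewest trees,
  largest k, strongest regularisation), then grid order, so selection is
  deterministic.
* Feature scaling (median/IQR, `robust_scale_fit()`) is fitted on each
  model's own training rows; validation and test rows are transformed
  with stored parameters only — no leakage. Zero-IQR columns are centred
  but not divided, with a warning.
* The six winning fold models are evaluated on the replicate's test set:
  10 × 6 = 60 test-set metric vectors per method, reported as mean ± sd.

Metrics are RMSE, Pearson r, Spearman ρ, R² around the test mean, and
QF3². The printed form of the QF3² formula in circulation is ambiguous;
the default here is the Consonni definition,
QF3² = 1 − [Σ_test(ŷ−y)²/n_test] / [Σ_train(y−ȳ_train)²/n_train],
with the alternative test-set denominator available via
`qf3_variant = "test_denominator"`. Constant test targets yield NA
correlations rather than errors, mirroring how a null model's output is
reported.

**Learners and grids.** Defaults (all config-exposed through
`default_grids()`):

| method | implementation | grid |
|---|---|---|
| null | training mean | — |
| lr | OLS (QR; minimum-norm SVD fallback on singular designs, with warning) | — |
| knn | caret::knnreg | k ∈ {1,3,5,7,11,15,21} |
| lsvr | e1071::svm, linear kernel | C ∈ {0.1,1,10,100}, ε ∈ {0.01,0.1,0.5} |
| svr | e1071::svm, RBF | + γ ∈ {scale, 0.01, 0.1} |
| rf | randomForest | trees ∈ {100,200}, mtry ∈ {p, √p} |
| erf | ranger, extratrees splitting, no bootstrap, 1 random split/feature, min node 1 | trees ∈ {100,200}, mtry ∈ {p, √p} |
| dnn | in-package two-hidden-layer tanh network, full-batch Adam, early stopping | units ∈ {32,64}, dropout ∈ {0,0.2} |

The forest grids stop at 200 trees: 200 is the canonical configuration
for the extremely randomised forest in this setting (unrestricted leaves,
which deliberately overfit the training set while winning on validation),
and a 500-tree arm multiplies the cost of the 60-fits-per-combination
protocol several-fold for no observed selection benefit on the synthetic
tables. Users can pass `grids = list(erf = list(ntree = c(100, 200, 500),
...))` to widen the search. The "scale" γ is 1/(p·mean column variance),
matching the common heuristic. The DNN is a deliberately small
feed-forward network (two tanh hidden layers, the second half the width
of the first, targets standardised internally); it is optional and no
acceptance property depends on it.

Seeding: one base seed drives the split plan; per-model training seeds
are derived deterministically from (replicate, fold, grid index), so the
whole report is reproducible bit for bit and independent of the order in
which methods are listed.

`predict()` for a fitted object averages the six stored fold models of a
replicate (each applying its own scaler) — the same averaging used to
score screening libraries; `store_models = "first"` (default) keeps only
the first replicate's models to bound memory.

## 5. Importance, ablation, screening

Permutation importance shuffles one feature column at a time *within the
test set* (the model is never retrained), five seeded replicates per
feature, and reports the mean and sd of the drop in Pearson r; positive
values mean the model relied on the feature. Shuffling happens on the
unscaled features before the model's scaler is applied, which is
equivalent to shuffling the scaled column (the scaler is columnwise).
Importances are not additive and are asserted only to stay below the
baseline plus sampling tolerance. Ablation retraining
(`ablation_models()`) reruns the identical protocol on named subsets:
MR only, MASS only, ligand only (6), protein only (14), all (20).

Screening featurizes each query ligand with its own maxD at the fixed
centre, averages fold predictions per method, and ranks by predicted ΔG
(lower is better). The enrichment factor at x % selects
⌈x/100 · n⌉ molecules (ceiling guarantees a nonempty selection at 1 % for
small libraries; ties at the cutoff break by stable molecule id) and
divides the active fraction in the selection by the active fraction
overall. EF is exactly 1 at 100 % and invariant under monotone score
transforms. Union ensembles pool the per-method top sets — presets:
all methods, all without kNN, and the {LR, lSVR, SVR} trio — computing EF
on the union with its own size as the selection count. A diagnostic flag
marks pockets containing non-water hetero atoms (cofactors), a known
failure mode of the descriptor scheme; surface-site detection is out of
scope.

## 6. The synthetic test bed

`make_toy_complex()` builds pockets from idealised residue coordinate
templates (eight residue types, crude but clash-checked geometry) placed
with centres of mass at exact requested distances in seeded random
orientations, paired with fixture ligands whose graphs are small enough
to verify by hand. Expected values shipped with each fixture come from
code paths independent of the descriptor implementation: a brute-force
BFS Wiener index, hand-tabulated donor/acceptor counts per residue, and
analytic sphere volumes.

`make_feature_table()` generates feature tables on the exact 20-column
schema with plausible marginals (lognormal MASS around 350 g/mol,
Poisson donor/acceptor counts, MR correlated with MASS, gamma pocket
counts, PVol uniform in 150–1500 ų) and a planted linear target with
optional interaction terms and Gaussian noise, defaulting to moderate
negative weights on MR, MASS, PA(Amide-O) and PlogP(Non-Arom) — the
features that carry most signal in real affinity data. The standard
study conditions used by the tests and the acceptance script are n = 600
rows, noise sd 1 kcal/mol, intercept −7 kcal/mol, and one MR × PA(D+E)
interaction of weight 1.5, chosen to give a realistic signal-to-noise
ratio (null RMSE ≈ 2.5 kcal/mol, comparable to real affinity spreads)
while letting tree ensembles demonstrably beat linear models.

What passing these tests shows: the descriptor pipeline computes exactly
what it claims on known inputs, the protocol trains and evaluates the
advertised 60 models without leakage, and the learners recover planted
structure. What it does not show: performance on real crystal
structures and measured affinities — synthetic features are independent
draws, whereas real descriptors are strongly collinear; synthetic
pockets are idealised fragments, not folded proteins; and the planted
target is far cleaner than experimental ΔG labels.

## 7. Known limitations

* The hydrogen-bond rule sets (ligand and protein) are fixed
  conventions; tautomer- or pKa-aware assignment is out of scope.
* Protonation variants (HIP, ASH, GLH) are honoured only when the input
  names them; a plain hydrogen-free PDB yields the neutral defaults.
* The grid-probe PVol measures free volume in the maxD sphere, not a
  topologically delimited cavity; for surface sites it approaches the
  half-space value rather than a pocket volume.
* Pose invariance is a modelling trade: ligands binding away from the
  assumed centre, cofactor-occupied pockets and water-mediated contacts
  are systematically mis-featurized (flagged, not fixed).
* The affinity conversion treats IC50 like an equilibrium constant;
  assay-condition effects are absorbed into label noise.
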