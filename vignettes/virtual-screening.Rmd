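---
title: "Ligand-based virtual screening with topscreen: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-based virtual screening with topscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topscreen)
```

## Overview

`topscreen` implements a ligand-based virtual-screening workflow for
binary activity classification, developed around the problem of
recognising small-molecule inhibitors of human topoisomerase I (Top1), a
nuclear enzyme that relaxes DNA supercoils and a validated anticancer
target. The workflow is: standardize molecules, compute a fixed registry
of molecular descriptors, train a classifier on a labelled
inhibitor/non-inhibitor collection, evaluate it with confusion-matrix
statistics and ROC/AUC, then score a compound library and retain
candidates whose relative probability score exceeds a cutoff, optionally
followed by a filter on externally computed docking binding energies.

Every statistical component — the CART/random-forest ensemble, the
RBF-kernel SVM, k-NN, the gain-ratio decision tree, and all descriptor
algorithms — is implemented in this package rather than delegated, so
the exact voting, tie-break and out-of-bag (OOB) conventions are under
the package's control and documented below. Reference libraries
(`randomForest`, `kernlab`, `pROC`, `rpart`) appear only as independent
oracles in the test-suite.

## Molecule handling

SMILES and V2000 SDF parsing is delegated to ChemmineR/ChemmineOB
(OpenBabel). Because OpenBabel emits kekulized connection tables,
aromaticity is re-perceived internally with an explicit rule: a simple
ring of 5–7 atoms, all C/N/O/S, none a saturated carbon, is aromatic
when its Hückel count is `4k + 2`, where an atom with an in-ring double
bond contributes 1 π electron, a heteroatom without one contributes its
lone pair (2), and a carbon whose only double bond points out of the
ring (quinones) contributes 0. This covers benzenoids, pyridines,
pyrroles, furans and thiophenes; exotic systems (tropylium, azulene
dipolar forms) are out of scope and perceived non-aromatic.

Standardization keeps the largest connected fragment (counter ions and
salts are dropped; an exact size tie is broken by the lexicographically
smaller canonical SMILES so the rule is deterministic), neutralizes
charges that a single protonation change can fix (carboxylates gain a
proton, ammoniums lose one; quaternary centres and true zwitterions are
left intact), and re-perceives aromaticity. The operation is idempotent.

Molecules without 3D coordinates can be given a surrogate geometry by
classical multidimensional scaling of the topological distance matrix
scaled to 1.52 Å per bond. This embedding involves no random numbers,
so it is trivially reproducible; it is a coarse shape proxy adequate for
the grid-based geometric descriptors, not a force-field conformation —
users with real conformers should supply them via SDF.

## The descriptor registry

Version 1 of the registry defines 85 descriptors in six families; the
row order of the registry *is* the feature-column order everywhere
downstream, which is why the registry is versioned rather than mutable.

* **simple** (14): monoisotopic weight, atom-class counts, cyclomatic
  ring count, rotatable bonds, H-bond donors/acceptors.
* **topological** (4): Wiener index, Balaban pruning centric index
  (`Tcent`), first and second Zagreb indices. `Tcent` deletes all
  degree-1 vertices per step and sums squared deletion counts; a
  leaf-free terminal core of *c* vertices contributes *c*², so a lone
  vertex adds 1 and a lone edge 4. This generalizes the classical
  acyclic rule to fused-ring cores deterministically.
* **connectivity** (30): Kier–Hall chi indices — paths of order 0–6,
  clusters (stars) 3–6 and chains (simple cycles) 3–6, each in simple
  and valence form. The valence degree uses the second-row convention
  `δv = Zv − h` throughout, matching the worked examples the engine is
  tested against (pyridine N: δv = 5; ethanol O: δv = 5). Each simple
  cycle of a fused system counts once in the chain terms.
* **shape** (6): kappa 1–3 with the parity-dependent third-order form,
  plus α-modified variants using covalent-radius ratios against sp³
  carbon. Degenerate denominators (molecules too small to contain the
  required paths) yield masked values, not errors.
* **estate** (27): per-atom electrotopological states
  `S = I + ΔI` with intrinsic state `I = ((2/N)² δv + 1)/δ` and
  distance-damped perturbations, summed by Kier–Hall atom type. The sum
  of perturbations is exactly zero by antisymmetry — the suite checks
  this to machine precision on every test molecule. `SaaCH`, the
  aromatic-CH type sum, is the descriptor the originating descriptor
  program numbered S(27).
* **geometric** (4, require 3D): rugosity (`Rugty`), solvent-accessible
  surface area, grid volume and radius of gyration.

Rugosity is defined here as the ratio of the solvent-expanded molecular
surface area to the surface area of the sphere of equal molecular
volume, which makes it a dimensionless "molecular folding" measure that
is exactly 1 for a single sphere. The surface is estimated
Shrake–Rupley-style on a deterministic 256-point Fibonacci sphere per
atom and the volume on a 0.4 Å grid with a 1.4 Å probe; both use the
solvent-expanded radii so the single-atom limit is exact up to
discretisation. Spacing, probe and point count are arguments.

The quantum-chemical descriptor family present in the original
descriptor program is deliberately absent: it requires an
electronic-structure engine and none of the named headline descriptors
belongs to it.

## Classifiers

All four classifiers consume a `labeled_dataset` (features in registry
order, labels `+1` active / `−1` inactive). Missing descriptor values
are imputed with training-set medians; distance-based models (k-NN,
SVM) additionally require z-scoring with training-set statistics —
`standardize_features()` enforces the train-only-parameters contract and
drops zero-variance columns from both sets consistently.

**Random forest.** Unpruned CART trees grown to purity (minimum node
size 1) on bootstrap samples, Gini splits over `M_try` uniformly
sampled candidate features per node. Vote fraction for the active class
is the *relative probability score*; the label is the majority vote
with exact ties resolved to −1, the conservative choice for screening
(a tied compound is not promoted). Each tree draws its randomness from
a private stream seeded by a fixed function of (forest seed, tree
index), which makes a forest bit-reproducible *and* makes an N-tree
forest the exact prefix of a larger one at the same seed — the
`N_tree` tuning stage exploits this to evaluate a whole grid from one
forest. OOB error uses only votes of trees whose bag excluded the
sample; never-OOB samples leave the denominator.

**Tuning.** `tune_rf()` scans `M_try` at a fixed reference forest size
and then `N_tree` at the winning `M_try`, minimising the test-set
prediction error rate; ties are broken by the lower training-set OOB
error, then by the smaller parameter value (a larger forest only costs
computation). The reference forest size defaults to 500 and is an
argument. The full scan table is returned for plotting.

**Feature importance** is Breiman-style permutation importance: per
tree and feature, the drop in OOB accuracy when that feature is
permuted among the tree's OOB samples, averaged over trees. It is the
default because "contribution" measures based on impurity decrease are
biased toward high-cardinality features; the permutation count is an
argument for users who want smoother estimates.

**k-NN** uses the Euclidean metric on standardized features; distance
ties resolve to the lower training index, vote ties to the class of the
nearest neighbour, and the score is the active fraction among the k
neighbours. The default k = 6 follows the tuned comparison setting.

**C4.5-style tree**: binary threshold splits on continuous features by
gain ratio, then pessimistic pruning with a Clopper–Pearson-style upper
confidence bound on the leaf error rate (default confidence 0.25).
Scores are Laplace-smoothed leaf purities.

**SVM**: soft-margin dual with RBF kernel
`k(x, y) = exp(−‖x − y‖²/(2σ²))` (so `k(x, x) = 1`; the default
σ = 0.2 follows the tuned comparison setting), solved by sequential
minimal optimization. The working pair is chosen deterministically —
first KKT violator in index order, partner by decreasing `|E_i − E_j|`
with fall-through past degenerate pairs (η = 0 arises for duplicated
rows) — so fits are reproducible without an RNG. Exceeding the
iteration cap raises an error rather than returning a half-converged
model. The score is a logistic map of the decision value, used for
ranking only.

## Evaluation

`se`, `sp` and `q_total` report percentages; `mcc` uses the standard
denominator `√((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. A zero marginal masks
the statistic with a warning instead of dividing by zero.
`classification_metrics()` rounds half-up to the conventional printed
precision. ROC curves sweep the unique scores in descending order and
process tied scores as a single threshold step (a diagonal segment),
which makes the trapezoidal AUC equal the Mann–Whitney pair statistic
with half-credit for ties; the suite verifies this identity on 1000
random instances.

## Diversity

The diversity of a compound set is the mean dissimilarity over ordered
pairs, `D(A) = Σ_{i≠j} diss(i, j) / (N(N−1))`, a number in [0, 1]. The
default `diss` is 1 − Tanimoto over hashed linear-path fingerprints
(path lengths 1–7 bonds, 2048-bit space, direction-canonical path
strings, deterministic string hashing); any user-supplied dissimilarity
matrix is accepted, because no single pairwise measure is canonical and
published diversity values depend on the (often proprietary) compound
sets and measure used. The qualitative behaviour — an analog series
around one scaffold scores far below a set of unrelated drug-like
molecules — is what the statistic is for, and is what the tests pin
down.

## Screening

`screen_library()` retains compounds whose score is strictly greater
than the threshold (default 0.7) and ranks them by descending score;
`filter_by_energy()` retains hits with imported binding energy strictly
below the cutoff (default −10.0 kcal/mol) sorted most-negative first.
Both cutoffs are strict by convention and configurable. Docking itself
is out of scope: energies arrive as a CSV produced by an external
docking program, and `docking_box_config()` exports the receptor
grid-box parameters for users who run one. Raising the score threshold
can only shrink the hit list, and filtering the score-retained set by
energy equals filtering first by energy on the same subset; both
properties are tested.

## Synthetic fixtures

Because the original training collections are proprietary, the package
ships a generator rather than data. `gen_dataset()` draws two
multivariate normal classes, the active class shifted by `d` pooled
standard deviations on exactly `informative` features, with identity or
equicorrelated covariance and an optional heavy-tailed (t, df = 5)
variant. The Gaussian design gives closed-form ground truth: with one
informative feature the Bayes error is `pnorm(−d/2)`, so at the
benchmark setting d = 4 (Bayes error ≈ 2.3 %) a well-implemented forest
must reach ≥ 95 % test accuracy. `gen_library()` enumerates substituted
analogs of a scaffold (attachment marker `{R}`), emulating the scaffold
redundancy of real screening libraries.

What the generator does *not* emulate: discrete/zero-inflated
descriptor distributions, inter-descriptor correlation structure of real
chemistry, activity cliffs, or class imbalance. Passing the synthetic
benchmarks therefore demonstrates algorithmic correctness of the
learners, not predictive performance on real Top1 data.

### Benchmark problem sizes

The standard benchmark used by the tests and the acceptance script is
500 compounds per class, 10 features, one informative at d = 4, split
2/3–1/3 with stratification; the forest uses `M_try = 3 ≈ √10` with 200
trees for the accuracy check and 500 trees for the OOB-agreement and
importance checks. Ten features were chosen as a realistic
post-feature-selection width; the checks hold unchanged at larger
widths with `M_try = √p`.

## Numerical choices and edge cases

* Vote ties (RF even forests, k-NN even k, SVM decision value exactly
  0) resolve to −1; scores strictly above 0.5 imply label +1.
* CART split ties resolve to the first candidate feature in the
  sampled order, then to the lowest threshold; thresholds are midpoints
  between adjacent distinct values.
* Split sizes per class are `round(fraction × n_class)`, clamped so
  neither side is empty; each class needs ≥ 2 members.
* A single-class training set yields a constant forest with a warning,
  not an error, so degenerate subsets fail soft in pipelines.
* χ of order 0 assigns weight 1 to an isolated vertex (single-atom
  molecule); kappa values with vanishing path counts are masked (NA).
* Descriptor vectors never contain silent non-finite values: an
  unsupported element (outside C, N, O, S, P, halogens, H) raises an
  error naming the molecule, and 3D-dependent descriptors are masked
  when no geometry is available.
* Fingerprint hashing uses a fixed polynomial string hash, so bit
  collisions are possible but deterministic and identical across
  platforms.

## Known limitations

* The registry is a documented subset of the larger descriptor space
  used historically with this workflow; adding descriptors requires a
  new registry version to preserve column order.
* Aromaticity perception and neutralization are intentionally simple;
  tautomer enumeration and stereochemistry-aware standardization are
  out of scope.
* The SMO solver targets the small-to-medium problems of this workflow;
  it is O(n²) per pass and not intended for tens of thousands of
  compounds.
* Probability scores of the non-forest models are ranking devices, not
  calibrated probabilities.

## A worked micro-example

```{r example, eval = FALSE}
mols <- standardize(read_smiles(c("CCO", "c1ccccc1"), c("ethanol", "benzene")))
compute_all(mols[[2]])["Tcent"]

d <- gen_dataset(synth_spec(n_per_class = 200, p = 10, d = 4, seed = 1))
parts <- split_dataset(d, 2/3, seed = 2)
rf <- train_random_forest(parts$train, M_try = 3, N_tree = 200, seed = 3)
1 - test_per(rf, parts$test)            # test accuracy
rf_oob_error(rf)                        # internal OOB estimate
```
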