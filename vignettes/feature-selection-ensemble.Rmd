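---
title: "From residue-level representations to a soft-voting DBP classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From residue-level representations to a soft-voting DBP classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbpFSE)
```

## The problem and the model

DNA-binding proteins (DBPs) are routinely predicted from sequence alone.
Two families of residue-level representations dominate: the alignment-based
position-specific scoring matrix (PSSM), an $L \times 20$ table of
substitution log-odds $s_{i,j}$ produced by iterative profile search, and
per-residue embeddings from pretrained protein language models, an
$L \times d$ matrix (e.g. $d = 1280$ for a large transformer). Both are
residue-level objects; a classifier needs one fixed-length vector per
protein. dbpFSE implements a unified pooling scheme that treats both
sources identically, so their information content can be compared fairly.

Every representation is first squashed entrywise with the logistic sigmoid,
$r_{ij} = 1/(1+e^{-x_{ij}})$, then pooled by four averaging operators over
the rows $\mathbf R_1,\dots,\mathbf R_L$:

* **Avg** — the mean over all residues ($d$ features);
* **Sep(k, s)** — the mean over residues $s, s+k, s+2k, \dots$ for
  $k \in \{2,3\}$, $s \in 1..k$ ($5d$ features); the $k$ subsets for fixed
  $k$ partition the chain, so their size-weighted mean recovers Avg — a
  conservation identity the tests assert to $10^{-10}$;
* **AA(t)** — the mean over residues of amino-acid type $t$ for the 20
  standard letters ($20d$ features); the same conservation identity holds
  over types. A type absent from the chain contributes a zero vector, which
  keeps the block at exactly $20d$ for every protein;
* **Corr($\varphi$)** — the mean of $(\mathbf R_i - \mathbf R_{i+\varphi})^2$
  (componentwise) for lags $\varphi \in \{1,2,3\}$ ($3d$ features), the
  pseudo-PSSM-style sequence-order term.

Together: $29d$ features — 580 for a PSSM source and 37 120 for a
1280-dimensional embedding. Feature names follow a fixed grammar
(`avg_j`, `sep_k{k}_s{s}_j`, `aa_{T}_j`, `corr_phi{p}_j`, 0-based dimension
index), with the AA block ordered by the PSSM column alphabet
`A R N D C Q E G H I L K M F P S T W Y V` for both sources; no ordering is
canonical in the literature, so one published order is fixed and recorded
in the names.

## The selection-and-evaluation protocol

Tables are MinMax-normalized per feature (training ranges only; constant
columns map to 0; test values are deliberately not clipped). The default
normalizes the full training table once before cross-validation, which
mirrors the classical protocol but leaks fold ranges; `crossValidate(...,
normalize = "per-fold")` refits the normalizer inside each fold for honest
estimates. CV is stratified 5-fold; pooled metrics come from the union of
held-out predictions because ACC/MCC/SN/SP are defined on counts, and
pooled counts are unambiguous. When any MCC/SN/SP denominator is zero the
metric is reported as 0 and flagged.

Stage 1 ranks features six ways — variance, the chi-squared mass statistic,
the maximal information coefficient (MIC), and the embedded importances of
ridge-logistic regression, a linear SVM, and a random forest (impurity
importances, normalized to sum to 1) — and sweeps nested top-percent
subsets (10–80 % by 10; subset sizes use the *ceiling* rule, which
reproduces counts such as 1485 = 4 % of 37 120, where flooring would not).
If a sweep optimum sits at the 10 % boundary, a fine 1–9 % sweep triggers
automatically. Sparse supports come from lasso, elastic-net (mixing 0.5)
and a least-angle-regression lasso implemented in the package (`larLassoPath`;
its knots are cross-checked against coordinate descent in the tests); each
penalty is chosen by internal 5-fold CV and recorded in the provenance.
Stage 2 refines the best linear-ranker subsets by recursive feature
elimination: coefficients are refitted each round, `step` lowest-ranked
features are dropped, every size is scored by CV accuracy of the
Gaussian-kernel SVM (the protocol's evaluation classifier), and ties keep
the earliest (largest) size.

All embedded rankings are fitted once on the whole normalized table, not
per fold — the protocol produces one ranking per feature set. The `lr`
classifier and ranker is ridge-penalized logistic regression with
$\lambda = 1/n$ (the conventional unit-cost analogue), because tables here
routinely have far more features than samples and an unpenalized fit is
not defined. The `gbdt` roster entry is gradient boosting with the
regularization terms set to zero; `xgb` keeps the library defaults.

### MIC implementation notes

MIC is computed from the characteristic matrix over all grids with
$n_x n_y \le B(n) = \max(n^{0.6}, 4)$ (the floor of 4 keeps the $2\times2$
grid admissible at small $n$). One axis is rank-equipartitioned with ties
kept together; the other is optimized exactly by dynamic programming over
contiguous clump partitions; both orientations are searched, making the
statistic symmetric. The tests compare the DP against exhaustive
enumeration of all bin boundaries on tiny inputs, case by case.

## The soft-voting ensemble

Each trained selection model becomes a member with weight
$w_i = \mathrm{ACC}_i / \sum_k \mathrm{ACC}_k$ from its pooled 5-fold CV
accuracy, and the ensemble probability is $p_c = \sum_i w_i\, p_{i,c}$ — a
convex combination, so the vote can never leave the span of its members.
In the faithful configuration the registry holds 34 members: four full
feature sets (two PSSM sources' 29d sets, the embedding average set and
the embedding 29d set) each contribute a no-selection model, three
regularizer supports, the two best stage-1 linear-ranker subsets and their
two RFE refinements (8 each), plus the two 20-feature PSSM average sets'
baseline models. Every member applies its own normalizer and feature
subset to the raw descriptor columns (members were trained on different
subsets, so per-member preprocessing is the only consistent contract), and
a tie at $p_1 = 0.5$ goes to the positive class — positives are the class
of interest; the rule is documented rather than canonical.

## What the synthetic generator emulates — and what it does not

Real benchmark collections (curated PDB chains with PSI-BLAST profiles and
language-model embeddings) are not shippable or recomputable offline, so
the generator plants a controllable class signal instead: raw entries are
$\mathcal N(0, \sigma^2)$, and positives receive a mean shift $\delta$ on
$m$ informative dimensions *before* sigmoid normalization, so the
nonlinearity is exercised. Sequences are drawn uniformly over the 20
letters, independent of the matrices, which turns the AA(t) operators into
a randomized partition — exactly what the conservation identity checks.
Defaults are the validation conditions used throughout: 200 proteins per
class, lengths 50–100 (matching the length-50 input filter), $d = 50$,
$m = 5$, $\delta = 3\sigma$, $\sigma = 1$.

The generator does **not** emulate evolutionary profile structure,
residue-composition biases, length–class correlations, or the strong
inter-feature correlations of real embeddings. Passing tests therefore
demonstrate that the machinery is correct and that the pipeline recovers a
known signal at a realistic size — not that any particular accuracy will
be achieved on real proteins.

Two consequences of the planted-shift design matter for interpretation.
First, Corr($\varphi$) features are differences of neighbouring rows, so a
constant shift cancels: informative dimensions are invisible in the
correlation block by construction, and recovery criteria are therefore
stated on the per-dimension average features. Second, because averaging
over $\ge 50$ residues shrinks within-class noise, a $3\sigma$ shift makes
the informative average features nearly separable — which is intended: the
recovery tests check that rankers agree on an unambiguous signal, and the
null-calibration tests ($\delta = 0$) check the other end.

## Numerical and degenerate-input choices

* Sigmoid saturates to exactly 0/1 in double precision for $|x| \gtrsim 37$;
  validity therefore checks the closed unit interval.
* $L \le \varphi$ yields a zero correlation vector with a warning (the
  length filter makes this unreachable on filtered data, but the library is
  total); $s > L$ in Sep is an error (empty subset).
* Ranking ties are broken by original column order (stable sort) so every
  selection is reproducible and diffable.
* Embedding files may be whitespace text or an RDS container, detected by
  extension; nothing in the format carries feature names, so row count is
  validated against the bound sequence.
* Nonstandard residues other than `X` (B, Z, U, O) survive the default
  filter but belong to no AA(t) subset; the AA conservation identity is
  asserted on standard-alphabet sequences.

## Problem sizes used by the test-suite and acceptance runs

Structural identities (feature counts, subset sizes, the 34-member
registry) are exact and run on small inputs. Statistical checks use the
generator's study conditions: null calibration averages pooled CV accuracy
over 50 seeds at $n = 400$, $d = 8$; signal recovery uses 20 seeds at the
full $d = 50$ conditions; the registry demonstration uses 60 proteins and
a coarse two-point percent grid with RFE step 10, which leaves the member
structure (and hence the count) unchanged while keeping the demonstration
compact.

## Worked example

```{r example, eval = FALSE}
ds <- generateDataset(syntheticSpec(nPos = 50, nNeg = 50, d = 20, seed = 1))
tab <- datasetToTable(ds)                       # 100 x 580 FeatureTable
ntab <- minmaxApply(minmaxFit(tab), tab)
rk <- scoreEmbedded(ntab, "lr", seed = 1)
sel <- selectTopPercent(rk, 20)                 # "LR20", 116 features
rfe <- rfeCV(ntab, sel, "lr", seed = 1)         # "LR20_RFE"
crossValidate(ntab[rfe@selectedNames, ], classifierSpec("svm"), seed = 1)
```

## Known limitations

The protocol's paper-faithful normalization and whole-table rankings leak
information across CV folds (the `per-fold` mode exists for honest use);
the LAR path solver targets the least-squares objective on 0/1 labels, as
is conventional for selection, not a classification likelihood; MIC uses
the equipartition-plus-DP approximation of the characteristic matrix, not
the exhaustive search, beyond tiny $n$; and no hyperparameter tuning is
performed anywhere — all classifiers run pinned defaults by design.
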