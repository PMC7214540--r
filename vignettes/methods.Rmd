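---
title: "Thermophilic protein recognition: models, parameters and design notes"
author: "ThermoRAAC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermophilic protein recognition: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ThermoRAAC)
```

# The problem and the model

Thermophilic organisms maintain folded, active proteins at temperatures
that denature most mesophilic proteins. The compositional correlates are
well documented: thermophilic sequences tend to be enriched in charged
residues (Arg, Lys, Glu) and depleted in thermolabile ones (Gln, Met),
and particular residue pairings matter beyond single-residue
composition. `ThermoRAAC` operationalizes this as a supervised
two-class problem: label 1 = thermophilic, 0 = non-thermophilic, and the
model is a staged pipeline

> mixed feature extraction → min-max normalization → correlation pruning
> → MRMD ranking and accuracy-driven truncation → PCA truncation →
> stratified k-fold evaluation.

Every stage is exposed as its own function returning an inspectable S4
object, because the intermediate artifacts (which features were pruned,
what the ranking looks like, how many components survive) are themselves
scientific outputs.

# Feature families

## Reduced gapped dipeptides

Dipeptide composition over the full 20-letter alphabet yields 400 types
per gap, many of them redundant because physicochemically similar
residues substitute freely. Recoding onto a reduced alphabet merges such
residues before counting. The default `susko19` scheme merges only
Ile/Val (representative V) — a minimal reduction derived from
substitution-model optimization — giving 361 types per gap; the
six-class Dayhoff grouping (`dayhoff6`) and the identity map
(`identity20`, used for the original-dipeptide ablation) are built in,
and custom partitions load from plain text via `readSchemeFile()`.

For gap $\lambda$, $y_\lambda(a,b)$ counts positions $i$ with
$s_i = a,\ s_{i+1+\lambda} = b$ and the features are the per-gap
normalized frequencies $f_\lambda(j) = y_\lambda(j) / \sum_j
y_\lambda(j)$. Two conventions are worth stating because they are easy
to get wrong:

* normalization is **within one gap block** (the denominator is
  $L - 1 - \lambda$), so each 361-block sums to 1; a global denominator
  would break that reading since the per-gap totals differ;
* a sequence too short to contain any $\lambda$-gap pair yields an
  all-zero block plus a warning rather than an error or a dropped
  record, keeping feature matrices rectangular without entangling
  extraction with dataset filtering.

Gaps 0–2 are the pipeline default (`maxGap = 2`); larger gaps are
supported but not exercised by the defaults.

## The 188D physicochemical descriptor

Twenty amino acid frequencies; then, for eight conventional property
partitions of the residues into three groups: group compositions
(8 × 3), distribution positions (8 × 3 × 5) and transition counts
(8 × 3). The distribution slots use the standard convention: the
*p*%-occurrence of a group with $n_g$ occurrences is its
$\lceil p\, n_g\rceil$-th occurrence, reported as a 1-based position
divided by $L$; the first occurrence fills the first slot, and an absent
group contributes five zeros. Transitions count adjacent residue pairs
whose groups differ, one feature per unordered group pair, normalized by
$L - 1$.

The eight properties and their 3-group splits are **conventions, not
fits**: the descriptor layout fixes only the counts (20 + 24 + 120 + 24
= 188). They ship as `inst/extdata/ctd_groups.tsv` and can be swapped
wholesale via the `groups` argument of `physchem188()` without touching
code.

## Auto-cross covariance (ACC)

Each sequence becomes $N = 3$ numeric traces by mapping residues through
per-residue scales (Kyte–Doolittle hydrophobicity, Hopp–Woods
hydrophilicity, side-chain mass in Da), each standardized to zero mean
and unit variance **over the 20 residues** so the three scales are
commensurate. For lags $g = 1..lg$ (default $lg = 2$):

$$AC(i,g) = \frac{1}{L-g}\sum_{j=1}^{L-g}
   (S_{i,j}-\bar S_i)(S_{i,j+g}-\bar S_i),$$

and $CC(i_1,i_2,g)$ analogously with two different traces, each centered
on its **own per-sequence mean** — per-sequence centering makes $AC$ a
true autocovariance of the trace (and exactly zero for any homopolymer).
The count is $N\,lg + N(N-1)\,lg = 18$. The denominator is $L - g$, the
number of summed products. ACC and the 188D descriptor are computed on
the *original* sequence; only the dipeptide family sees the reduced
alphabet, which is where the reduction has a combinatorial payoff.

# Reduction stages

## Normalization

Min-max per column, $(x - x_{\min})/(x_{\max} - x_{\min})$, onto
$[0,1]$. A constant column has no scale; it maps to all-zeros with a
warning instead of producing NaN, and the zero-variance convention
(correlation 0, with a warning) keeps such columns from ever driving a
pruning decision.

## Correlation pruning

All feature pairs are enumerated in a fixed canonical order (upper
triangle of the correlation matrix, row-major) and every pair with
$|\rho| > T$ (default $T = 0.85$; 0.90/0.95 are appropriate for datasets
whose features are more strongly coupled) passes through a five-rule
assignment table building a removed set D and reserved set R; see
`?correlationPrune` for the rules. Two details are deliberate:

* the first pair's assignment ("one to D, the other to R") is made
  deterministic — earlier column to R, later to D — since the choice is
  symmetric for the pair but must be reproducible;
* the rule table never revisits a pair whose members are both already
  assigned, so two reserved features can remain correlated. The default
  mode is faithful to that table; `strict = TRUE` adds one ordered
  clean-up pass that demotes the later member of any still-correlated
  reserved pair, after which no two retained features exceed $T$.

## MRMD ranking and truncation

$MR_i = |\rho(F_i, C)|$ (class labels as 0/1 reals) plus
$MD_i = \frac{1}{M-1}\sum_{k\ne i} \lVert F_i - F_k\rVert_2$, ranked by
$MR_i + MD_i$ descending with ties broken by name. Both terms are
computed on normalized columns. A scale caveat is inherent to this
definition: $MD$ grows like $\sqrt{n}$ with the sample count while
$MR \le 1$, so at $n$ in the hundreds the ranking is dominated by the
distance (non-redundancy) term. The accuracy-driven truncation
compensates: cross-validated accuracy of the working classifier is
evaluated on the top-$k$ features along the ranking and the smallest
evaluated $k$ achieving the maximum observed accuracy is kept.

The default evaluation schedule (`mode = "grid"`) visits every
$k \le 20$ and then geometrically spaced $k$ (factor 1.25) up to $M$,
taking the global maximum. The accuracy trace is a smooth function of
$k$ — in practice it can dip for small $k$ before rising again once
genuinely informative features enter — so a dense walk with a small
patience can stop inside a local dip, while a dense sweep over all
$M \sim 10^3$ subsets costs two orders of magnitude more for the same
answer. Dense `"sweep"` and `"patience"` modes remain available; the
internal evaluator uses 5-fold cross-validation with a fold assignment
independent of the final evaluation's, which limits (but cannot
eliminate — see Limitations) selection leakage.

## PCA truncation

Columns are centered and decomposed by SVD; component variances
$\lambda_1 \ge \dots \ge \lambda_m$ give cumulative contributions
$\rho_k = \sum_{i\le k}\lambda_i / \sum_i \lambda_i$, and the smallest
$k$ with $\rho_k \ge T'$ (default $T' = 0.95$) is retained, or a fixed
`kOverride` (e.g. 12) when the caller wants a set dimensionality. Axis
signs follow a fixed convention (largest-magnitude loading positive) so
projections are bit-reproducible across platforms.

# Evaluation

Folds are stratified — plain random folds at $n \sim 10^3$ would let
class imbalance between folds add avoidable variance to Sn/Sp — and the
assignment is a pure function of the seed. Confusion counts pool over
folds for the primary Sn/Sp/ACC figures (per-fold mean ± sd is reported
secondarily); ROC curves come from the models' continuous scores on
held-out observations, with tied scores forming a single threshold step
and area by the trapezoid rule. A class with no observations yields NA
for its recall rather than a silent 0. Model hyperparameters sit at
library defaults (RBF SVM with $C = 1$ and gamma $= 1/\text{dim}$;
100-tree forest; default tree and naive Bayes), all exposed through
`crossValidate()`'s model argument.

# The synthetic generator

`generatorSpec()` / `generateProteins()` emulate the study conditions of
a balanced two-class protein collection: class sizes, lengths uniform on
100–600, and a compositional separation knob $\delta$ that shifts the
base composition by $+\delta$ on K, R, E and $-\delta$ on Q, M for
positives (the opposite for negatives) before renormalization — the
direction matching the known thermophile signature. Positions are drawn
i.i.d., so *all* class signal is compositional by default; the optional
first-order `markov` coupling plants order structure that only the
dipeptide family can detect, which is useful for attributing which
family sees which planted signal.

The default base composition holds the five tilted residues at 0.08
each, with the remaining fifteen sharing 0.60 in proportion to natural
proteome background frequencies. The natural background itself (M at
~0.024) would leave the simplex under an opposite tilt as small as
$\delta = 0.024$; pinning the tilted residues at 0.08 keeps the entire
working grid $\delta \in \{0, 0.01, 0.03, 0.06\}$ feasible for both
classes while leaving the untilted residues realistic.
`expectedSeparation()` provides a closed-form normal approximation to
the Bayes accuracy of the log-likelihood-ratio classifier at the mean
length, used to sanity-check $\delta$ choices (50% at $\delta = 0$,
effectively 100% at $\delta = 0.06$ for these lengths).

What the generator does **not** emulate: homology structure, length/
composition coupling, secondary-structure or contact-driven signal, or
any property the 188D/ACC families specifically target. Passing tests
on generated data therefore demonstrate that the pipeline recovers
*compositional* class structure end-to-end and that every stage honours
its contracts — not that real thermophile collections will reach any
particular accuracy.

# Numerical choices and conventions

* Labels: 1 = thermophilic throughout; sensitivity is the thermophilic
  recall.
* Non-standard residues (B, J, O, U, X, Z) are rejected by default
  (`"strict"`), or dropped per record with a warning
  (`"drop-record"`); `*` and `-` are always rejected. Every descriptor
  is total only over the 20-letter alphabet.
* Normalization uses the min-max numerator $x - x_{\min}$: that is the
  unique affine form that actually lands in the stated $[0,1]$ target.
* Pearson correlation uses the $n-1$ sample convention; zero-variance
  input returns 0 with a warning.
* The MRMD distance term is kept exactly as defined (mean Euclidean
  distance between normalized columns) even though it dominates the
  relevance term at large $n$ — the truncation stage, not the ranking,
  carries the accuracy responsibility.
* One master seed expands into independent per-stage seeds
  (subsampling, selection folds, final folds) via a fixed draw, so any
  stage can be replayed in isolation; run directories include a
  manifest sufficient to replay the run bit-identically.
* Problem sizes in the test suite (e.g. 300 + 300 sequences for the
  end-to-end recovery checks, 10 × 8 matrices for ranking oracles) were
  chosen so each property is measured at the scale where its
  statistical claim is meaningful while the whole suite stays
  desk-runnable.

# Known limitations

* **Selection optimism at the null.** All reduction stages — including
  the accuracy-maximizing MRMD truncation — are fitted on the full
  dataset before cross-validation, per the staged design. Choosing the
  subset size by maximizing a cross-validated accuracy on the same
  observations leaves a small optimistic bias in the final
  cross-validated figures: on label-free data the end-to-end pipeline
  measures roughly 52–54% rather than 50%. Removing it entirely would
  require nested (per-fold) selection or external validation data;
  users comparing near-chance accuracies should keep this floor in
  mind.
* The accuracy-driven truncation assumes the trace over $k$ is smooth
  enough for a geometric grid; an adversarial ranking with isolated
  sharp optima would need the dense `"sweep"`.
* The eight CTD partitions and three ACC scales are conventional
  choices shipped as data files; alternative tables change the feature
  meanings (not the counts) and can be supplied per call.
* Statistical behaviour on real thermophile datasets (redundancy,
  homology clustering, length confounds) is outside what the generator
  can certify; the pipeline runs such data end-to-end but accuracy
  claims must come from the data itself.
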