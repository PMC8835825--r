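---
title: "Phylogenetic metrics for protein-domain mosaicity: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic metrics for protein-domain mosaicity: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicphy)
```

`mosaicphy` asks a single scientific question of a partitioned protein
alignment: do the partitions share one evolutionary history, or is the
domain a mosaic assembled from modules with different genetic pasts? This
vignette records the models the package implements, the assumptions they
make, the tunable parameters and their defaults, and the design decisions
taken where the methodology was genuinely open.

## The statistical model

### Likelihood

Sequence evolution is modelled as an independent continuous-time Markov
chain per alignment column (the usual "zeroth-order" assumption; no
covariation between sites) on a rooted binary time-tree with a strict
molecular clock fixed at rate 1, so node heights — and in particular the
root height, the *tree height* metric — are in expected substitutions per
site. The rate generator is the GTR-form protein model
$Q_{ab} = s_{ab}\pi_b$ built from published exchangeabilities $s$ and
stationary frequencies $\pi$ (WAG or LG, shipped as PAML-format text
files), row-normalized to one expected substitution per site. Among-site
rate variation is discrete-gamma: site rates take the $k$ per-category
means of a mean-one gamma distribution with shape $\alpha$ split at its
$k$-quantiles (Yang's mean-of-category discretization). The likelihood is
computed by Felsenstein pruning over site patterns in compiled code, with
per-node scaling so alignments of hundreds of taxa do not underflow; gaps
and unknown residues are missing data (partial-likelihood vectors of
ones). Category likelihoods carry equal weights and are combined by
log-sum-exp.

Choices we fixed where the reference methodology is silent:

* **k = 4 rate categories** (configurable) — the common default in
  Bayesian phylogenetics; the analysis compares partitions, and any fixed
  k does that comparably.
* **Model stationary frequencies**, not alignment-empirical ones — keeps
  WAG and LG runs comparable and matches default usage of the standard
  tree samplers.
* **No invariant-sites class** — rate variation is carried entirely by
  the gamma shape, which is itself one of the reported metrics; adding a
  second free variance component would make α unidentifiable exactly
  where we need it.
* **Mean-of-category, not median** discretization, the standard default.

### Priors and sampler

The tree prior is Yule (pure birth):
$\log p(T\mid\lambda) = (n-1)\log\lambda - \lambda\sum_i h_i$ over
internal node heights $h_i$, with $\lambda \sim \mathrm{Exp}(\text{mean }10)$
and $\alpha \sim \mathrm{Exp}(\text{mean }1)$. The reference analysis does
not state its priors; any proper prior preserves the *comparative* use of
the metrics across partitions, which is all the downstream regression
consumes. The two-taxon Yule density reduces to
$\lambda e^{-\lambda h}$, which the tests check in closed form.

The posterior over (topology, node heights, α, λ) is explored by
Metropolis–Hastings with a mixture of seven moves: a whole-tree scaler
(Jacobian $s^{m}$ for $m$ internal nodes), a root-height scaler, a uniform
slide of one internal node between its parent and its taller child, a
narrow (NNI-like) nephew–uncle exchange, a Wilson–Balding (SPR-like)
prune-and-regraft whose Hastings ratio is the ratio of the receiving to
the vacated height ranges, and multiplicative scalers for α and λ.
Root-edge regrafts are excluded; root height changes only through its
scalers. Default mixture weights favour the cheap topology moves
(3:3:2 slide/narrow/WB against 1 for each scaler).

Validity is tested three ways rather than argued: (i) with the likelihood
disabled the sampled α reproduces its exponential prior
(Kolmogorov–Smirnov); (ii) on data simulated at α = 0.5 (12 taxa, 300
columns) the 95% credible interval covers the truth in ≥ 8/10 seeds;
(iii) the pruning likelihood equals exhaustive enumeration over internal
states on 3–4 taxon trees to 1e-8, and agrees with an independent library
implementation.

Chains start from a UPGMA tree built on Jukes-Cantor-corrected Hamming
distances, which is ultrametric and therefore a valid time-tree state;
this shortens burn-in substantially compared with random starts. Retained
states are the post-burn-in thinned samples (defaults: 10% burn-in,
thin 20), and effective sample sizes for height and α are estimated by
Geyer's initial-positive-sequence truncation of the autocorrelation sum,
with a warning below ESS 100.

### The three metrics

* **Tree height**: posterior mean root height. Under a unit clock it
  measures realized divergence in substitutions per site, so a partition
  that mutated less (as the late-acquired module does in the reference
  data) shows a *lower* tree height.
* **Shape**: posterior mean α. Large α ⇒ uniform site rates
  (α = 1/CV² of site rates).
* **Clade support**: $S_i$ is the fraction of retained trees in which
  clade $i$ is monophyletic under the rooted convention (some node's
  descendant leaf set equals the clade exactly); $S$ is the mean over
  clades. Singleton clades count as monophyletic by convention. An
  unrooted, bipartition-based mode is available for externally supplied
  unrooted ensembles, since the reference analysis does not say which
  convention its support used.

### Conservation quality

The Clustal-style score maps each ungapped residue of column $j$ to its
row of a similarity matrix (the classic PAM250 integer log-odds table,
the ClustalW default, shipped as a text file), takes the
frequency-weighted consensus point, and sets
$Q_j = 100\,\max(0, 1 - \bar d_j/\mathrm{norm})$ where $\bar d_j$ is the
mean Euclidean distance of residue points from the consensus. Gaps are
excluded rather than scored as a 21st symbol — the scaffold alignments
the method targets are indel-free by construction. The normalization
constant defaults to the maximum $\bar d$ over the whole alignment,
computed once and reused for every partition so partition means share one
0–100 scale; it can be fixed absolutely for cross-dataset comparisons.
The exact scaling inside ClustalX is not recoverable from the reference,
so ⟨Q⟩ values are comparable *within* an analysis (orderings,
correlations with −log α) but not bit-for-bit against ClustalX output.

## The design matrix and regressions

Each partition contributes one row: metrics (S under WAG and/or LG, ⟨Q⟩,
tree height, shape) plus composition predictors A, B, C, CP1 (segment
units as configured, not recomputed residue counts — the reference design
matrix uses unit values that are not proportional to residue counts in
every row, e.g. a 20-residue subset drawn entirely from segment A carries
A = 4), NUMB (columns), and derived indicators: `urzyme` (any A/B/C
content) and `protozyme` (A > 0), with `protozyme_n` keeping A's numeric
value. A missing metric stays `NA` and the affected subset is dropped
row-wise when WAG and LG observations are stacked — stacking duplicates
composition columns and treats the two matrices' supports as independent
observations (20 observations for 10 complete subsets), a caveat recorded
here deliberately: the two supports are highly correlated by
construction.

The three reference models are reconstructed as explicit, named encoding
schemes rather than buried assumptions (`height`, `shape`, `support` in
`encode_predictors()`), because the reference table does not print its
urzyme/protozyme predictor columns. The reconstruction was validated by
requiring the printed equations to reproduce the tabulated responses; it
demands that CP1 enter the shape model *numerically* (value 2) but the
support model as an *indicator*, and both encodings are documented and
user-replaceable. Fitting is ordinary least squares via `stats::lm`
behind a reporting surface (β, σ, t, two-sided p on n−k−1 df, log-worth,
R², F); the F/R²/df identity is asserted in the tests.

Model selection, where wanted, is an exhaustive search over hierarchical
models (interactions only with both parents present) under AICc — chosen
over p-value-driven forward selection because it is deterministic and
seed-free, and because the reference's stepwise rules (a commercial
package's defaults) are not stated. The reproduction of the printed
equations never depends on the selector: those fits use the fixed term
sets.

Cross-correlations between metrics are squared Pearson correlations over
partitions, excluding the outlying CP1 row, as in the reference
(r² = 0.15, 0.10, 0.03 for height–shape, height–support, shape–support,
which the package reproduces at 2 decimals from the shipped table).

## The synthetic mosaic generator

The generator is the package's ground-truth instrument; its defaults are
the study conditions, not tuning knobs.

* **Base tree**: 10 clades × 20 taxa on a two-level tree — clade stems
  coalesce between `crown_frac` (0.25) and the root height (1.0 expected
  substitutions/site); within-clade radiations sit below the crown
  boundary. Every clade is monophyletic by construction.
* **Partitions**: A/B/C/CP1 = 46/17/20/20 columns (the urzyme analog
  being A∪B∪C = 83 and the scaffold 103; B and C individual widths are
  not published, so the 37 remaining urzyme columns split 17/20 by
  default and are configurable).
* **Rates and shapes**: urzyme-analog partitions evolve at rate 1 with
  α = 1.5; the CP1 analog at rate 0.5 with α = 4.5. These defaults encode
  the reference orderings (CP1: lowest divergence hence lowest tree
  height, most uniform rates hence highest shape); orderings, not
  absolute values, are the contract.
* **Transplants**: the CP1 analog evolves on a copy of the base tree in
  which 6 random leaves were pruned and regrafted across clade
  boundaries. This models "a different genetic history" directly and
  degrades monophyly specifically, unlike a mere rate change; partitions
  with 0 transplants share the base tree object exactly.
* **No indels**: the scaffold construction the method targets excludes
  loops and indels, so the simulator emits full-length sequences only.

What the generator does *not* emulate: structure-guided alignment error,
compositional heterogeneity across lineages, horizontal transfer beyond
the transplant device, and any coupling between partitions beyond sharing
a tree. Passing tests on synthetic data therefore demonstrate that the
pipeline *detects the signal it defines* — a transplanted, slow, uniform
partition separates from clean partitions in (height, shape, S) space —
not that the reference biological conclusion is re-derived; the
reference's absolute metric values are unattainable without its original
alignment, and only orderings are asserted anywhere in the package.

## Numerical choices and degenerate inputs

* Transition probabilities come from the symmetric eigendecomposition of
  $\mathrm{diag}(\sqrt\pi)\,Q\,\mathrm{diag}(1/\sqrt\pi)$; tiny negative
  entries from roundoff are clamped to zero and rows renormalized.
* Pruning uses per-node, per-pattern scaling with log accumulation;
  identical site patterns are collapsed once with multiplicity weights.
* α proposals are bounded to (1e-3, 500) to keep the gamma quantile
  function well-conditioned; the exponential prior makes the bound
  irrelevant in practice.
* Ultrametricity violations when importing external trees are absorbed
  by clamping tip heights to zero and enforcing a minimal parent–child
  gap (1e-8).
* An all-gap column has undefined quality and is excluded from partition
  means; a perfectly conserved alignment (norm 0) scores 100 everywhere.
* Column-index convention: 1-based inside R, 0-based half-open intervals
  in the on-disk partition config, converted on read.
* Collinear predictor sets are an error naming the offending columns,
  not a silent drop.

## Problem sizes used in the tests

The validation suite scales the study design down so the full pipeline
runs in minutes on one core: prior-sampling uses ~2,000 retained states;
parameter recovery uses 12 taxa × 300 columns × 10 seeds with 12,000-step
chains; mosaicity recovery uses 10 clades × 4 taxa with 5,000-step chains
over 5 seeds. At those sizes the mosaic separation (mean S near 1 for the
clean partition against ~0.1–0.4 for the transplanted one, with several
clades polyphyletic in most trees) is unambiguous in every seed. The
full-size default configuration (10 × 20 taxa) runs the same code
unchanged, only longer.

## Known limitations

* The strict clock is load-bearing: tree height is interpretable as
  divergence only because the clock rate is pinned to 1. Relaxed clocks
  would decouple height from rate and are out of scope.
* The sampler is a single chain without coupling or adaptive tuning;
  convergence is monitored by ESS and validated by prior-sampling and
  recovery tests, not by multi-chain diagnostics.
* Support values from short chains are noisy for weakly resolved clades;
  the package reports the ensemble size alongside S.
* The AICc search is exhaustive and intended for the handful of
  composition predictors used here, not for wide candidate sets.
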