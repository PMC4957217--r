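---
title: "Classifying proteins from g-gap dipeptide composition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying proteins from g-gap dipeptide composition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggapfs)
```

## The problem and the model

Many protein families — apolipoproteins are the motivating example — cannot
be recognized reliably by similarity search when candidate sequences are
remote homologs. `ggapfs` implements a sequence-only statistical
classifier for any two-class protein dataset, built from four stages:

1. **Features.** Each protein of length $L$ is represented by its *g-gap
   dipeptide composition*: the frequencies of all $20 \times 20 = 400$
   ordered residue pairs occurring at positions $(i,\ i+g+1)$, i.e.
   separated by $g$ intervening residues. $g = 0$ recovers the classical
   adjoining dipeptide composition; larger $g$ captures longer-range pair
   correlations such as the $i,\ i+4$ contacts of helical structure.
2. **Ranking.** Each feature $x$ is scored by the two-group one-way ANOVA
   F-statistic
   $$F(x) = \frac{m_p(\bar x_p - \bar x)^2 + m_n(\bar x_n - \bar x)^2}
   {\left[\sum_{i \in pos}(x_i - \bar x_p)^2 + \sum_{i \in neg}(x_i - \bar x_n)^2\right] / (m_p + m_n - 2)},$$
   the ratio of between-class to within-class variance across the $m_p$
   positive and $m_n$ negative samples. For two groups this equals the
   square of the pooled-variance t statistic, an identity the test suite
   asserts against base R's `t.test()`.
3. **Selection.** Incremental feature selection (IFS): the SVM is
   cross-validated on the top-1 feature, then top-2, ..., up to all 400,
   and the optimal subset is the smallest prefix maximizing overall
   accuracy.
4. **Classification.** An RBF-kernel SVM (libsvm via `e1071`), with $C$
   and $\gamma$ chosen by grid search over the canonical exponential grids
   $C \in \{2^{-5}, 2^{-3}, \ldots, 2^{15}\}$,
   $\gamma \in \{2^{-15}, 2^{-13}, \ldots, 2^{3}\}$, maximizing stratified
   5-fold cross-validated overall accuracy.

Performance is reported as sensitivity $Sn = n^+/N^+$, specificity
$Sp = n^-/N^-$ and overall accuracy $OA = (n^+ + n^-)/(N^+ + N^-)$, with
$OA$ algebraically the class-size-weighted mean of $Sn$ and $Sp$.

For enrichment analysis, raw F-scores are rescaled to
$$F_{norm}(x) = \mathrm{sgn}(\bar p^+ - \bar p^-)\,
\frac{F(x) - F_{min}}{F_{max} - F_{min}} \in [-1, 1],$$
so the strongest positively-enriched feature scores $+1$ and sign encodes
direction. Reshaped to $20 \times 20$ (first residue by row, second by
column) this gives the residue-preference matrix behind the usual
dipeptide heat map.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `g` | swept 0–9 | residues between the two pair positions; >9 allowed with a warning |
| `denominator` | `"positions"` | divide counts by $L-g-1$ (sums to 1) or by $L$ (`"length"`) |
| `folds` | 5 | stratified CV folds; jackknife (leave-one-out) available separately |
| `C_grid`, `gamma_grid` | libsvm-guide grids | hyperparameter search space |
| `seed` | 1 | fixes fold assignment and synthetic generation |
| `hyper` | `"global"` | IFS hyperparameter handling, see below |

## Design choices

**Composition denominator.** Dividing counts by the number of observable
pairs $L - g - 1$ makes each feature vector a probability distribution
(row sums exactly 1), which is what "frequency" should mean and what the
min-max-normalized scores implicitly assume. Because some descriptor
definitions divide by the raw length $L$ instead, that literal reading is
available via `denominator = "length"`; the two differ per sequence only
by the factor $(L-g-1)/L$, so rankings are nearly identical in practice.

**F-score conventions.** A feature constant within each class but
different between classes separates the data perfectly; it receives an
infinite score, ranks above all finite features (ties among such features
broken by larger class-mean gap, then name) and maps to $\pm 1$ after
normalization, with finite features scaled against the finite maximum so
the $[-1, 1]$ contract survives. A feature with zero between-class
variance — including one constant everywhere — scores 0. Ordinary ties
are broken by ascending dipeptide name, keeping ranks deterministic
without any seed.

**Hyperparameters during IFS.** The 400-point curve is computed with a
single $(C, \gamma)$, found once by grid search on the full feature set,
and a fold assignment fixed per seed and reused at every subset size.
Holding both fixed makes the curve a function of the feature subset
alone — differences between adjacent sizes cannot be fold-resampling or
search noise — and costs one grid search instead of 400. For users who
want the search repeated as the subset grows, `hyper = "per_step"`
re-optimizes at every size over a coarsened (every-other-point) grid.
The grid search itself is a single outer search scored by CV accuracy; a
fully nested (per-fold) search would give less biased accuracy estimates
but a different protocol from the one this pipeline mirrors.

**Class imbalance.** No class weighting is applied; imbalance enters only
through the OA objective. Compositions already live in $[0,1]$ on a
common scale, so no further feature scaling is done.

**Tie-breaks elsewhere.** Equal cross-validated OA during grid search
resolves to smaller $C$, then smaller $\gamma$ (weaker regularization
pressure, smoother kernel); equal OA along the IFS curve resolves to the
smaller subset (parsimony); equal best-OA across a g-sweep resolves to
the smaller g.

## The synthetic generator

`synth_spec()`/`generate_dataset()` produce two-class datasets in which
ground truth is known by construction. Sequences are i.i.d. draws from a
background residue distribution (uniform by default, keeping the null
analytically clean; any 20-vector may be supplied). Signal is planted
*positionally*: for each planted pair $(a,b)$ enriched in class $c$, every
valid start position of a class-$c$ sequence is overwritten with $(a,b)$ at
gap $g^\*$ with probability `effect`. Position injection (rather than
rejection sampling toward target frequencies) guarantees the pair
correlation lives exactly at $g^\*$; other gaps see the signal only through
the induced shift in single-residue usage, which is why the $g^\*$ curve
should dominate a g-sweep rather than uniquely succeed.

Defaults emulate a small curated benchmark: 53 positives vs 136
negatives, lengths uniform on $[100, 500]$, signal at $g^\* = 6$, and 20
planted pairs — ten over L/F/I/W enriched in positives and ten over
C/E/K/P enriched in negatives, matching the residue groups that dominate
the apolipoprotein preference map. The default `effect = 0.02` gives a
clearly detectable but not separable signal; validation scenarios use
0.05, which puts each planted pair near frequency 0.05 against a uniform
background of 1/400 and makes the classes nearly separable.

What the generator does *not* emulate: homology structure, realistic
amino-acid usage, length–class correlations, or compositional biases
beyond the planted pairs. Passing the recovery and calibration tests
therefore demonstrates that the pipeline's inference machinery is
correct, not that any particular real protein family is predictable at a
given accuracy.

## Numerical and degenerate-input behavior

* Compositions are exact ratios of integer counts; row sums are tested to
  1e-12.
* The vectorized ANOVA is tested to 1e-9 relative tolerance against
  `anova(lm(...))` and the squared-t identity.
* Normalization with all 400 F-scores identical is refused (it means the
  input carries no contrast at all).
* Sequences shorter than $g+2$ are errors at feature extraction and are
  dropped per-g (with a warning) during a sweep.
* Validation rejects anything outside the 20-letter alphabet — ambiguity
  codes B/J/O/U/X/Z, stop `*`, gap `-` — since composition is undefined
  for them; `read_fasta()` can reject, skip or strip.
* Jackknife evaluation contains no randomness; k-fold assignments are a
  pure function of (labels, k, seed).

## Problem sizes used in validation

The shipped tests run entirely on generated data at sizes chosen to
exercise every code path while keeping a full run inexpensive: oracle
equivalence on 100 random sequences across all gaps; type-I-error
calibration on 200 replicate null datasets of 100 sequences per class;
recovery of 20 planted pairs (100 per class, lengths 120–400, 5 seeds)
with a full IFS sweep over $g \in \{0, 3, 6, 9\}$; structural checks of
the 400/10-curve contracts on smaller sets. A complete 0–9 sweep at
benchmark scale is a few minutes of single-core work via `sweep_g()` or
the bundled CLI.

## Known limitations

* The IFS optimum is reported without a nested outer validation loop, so
  its OA is an optimistically biased estimate of generalization — the
  standard caveat for accuracy-maximizing feature selection.
* F-scores assess features marginally; complementary feature pairs with
  weak marginal signal can be ranked late.
* The SVM decision threshold is libsvm's native sign; no calibration or
  cost-sensitive thresholding is provided.
* Only two-class problems are supported.
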