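---
title: "Two-stage gene selection: the K-S filter, CFS, and how this package makes them concrete"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage gene selection: the K-S filter, CFS, and how this package makes them concrete}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kscfs)
```

## The problem and the model

A binary-class expression matrix has far more genes than samples —
thousands of columns, tens of rows per class. Most genes carry no class
information; of those that do, many are mutually redundant (co-regulated
probes, duplicated sets). A useful gene panel is therefore small,
class-informative, and internally non-redundant. This package implements
a two-stage selection that addresses each property with the tool suited
to it.

**Stage 1.** Each gene is tested with the two-sample Kolmogorov–Smirnov
statistic, the maximum absolute difference between the class-conditional
empirical CDFs, and kept iff its p-value is at most a significance level
$\alpha$. The K-S test is nonparametric and sensitive to *any*
distributional difference. That breadth is the reason it is the default
stage-1 filter here: a gene whose classes share a mean but differ in
spread is invisible to the t test and essentially invisible to the
rank-sum test, yet may carry real class signal. The package's own
simulation (`scripts/acceptance.R`) quantifies this: at a 3× sd ratio
with 50 samples per class, the K-S filter rejects for roughly 85–90% of
such genes at $\alpha = 0.05$ while Wilcoxon and t stay near their 5%
false-positive level.

**Stage 2.** Correlation-based feature selection (CFS) scores a subset
$S$ of $k$ genes by the merit
$$\mathrm{merit}(S) = \frac{k\,\overline{r_{cf}}}{\sqrt{k + k(k-1)\,\overline{r_{ff}}}},$$
with $\overline{r_{cf}}$ the mean gene–class association and
$\overline{r_{ff}}$ the mean pairwise gene–gene association, and searches
for a high-merit subset among the stage-1 candidates. Running CFS second
is not only a matter of redundancy: subset search over thousands of genes
is combinatorially hopeless, and the filter brings the candidate count
down to the tens where best-first search is cheap.

The selected panel is evaluated by stratified $k$-fold cross-validation
of a linear support vector machine with fixed penalty $C = 1$ — a
deliberately un-tuned classifier, so that differences between gene
subsets, not hyperparameter luck, drive the comparison — averaged over
repeated random sample shuffles.

## Parameters that matter

| Parameter | Default | Role |
|---|---|---|
| `alpha` | 0.01 | Stage-1 significance level. 0.01 keeps the candidate set in the tens-to-hundreds at typical sample sizes; `alpha = 1` disables the filter (all-genes baseline). |
| `stall` | 5 | Best-first search stops after this many consecutive expansions that fail to improve the best merit. |
| `dedup_threshold` | 0.95 | Candidates whose association reaches this level are collapsed to one representative before the search (below). |
| `top_k` | 50 | Ranked-list cutoff for the mRMR/ReliefF baselines before forward selection. |
| `k_neighbors` | 10 | ReliefF hit/miss neighborhood size. |
| `folds`, `repeats` | 10, 10 | Evaluation protocol: stratified folds, shuffle repeats. |
| `C` (SVM) | 1 | Fixed by design; not searched. |

All associations and accuracies are unitless ([0, 1] scales and
percentages); expression values are Z-score standardized per gene over
all samples pooled before any selection. Standardization is pooled, not
per class, because per-class scaling would inject label information into
the features; it uses the sample (n−1) standard deviation, so the column
`(1, 2, 3)` maps exactly to `(-1, 0, 1)`. Genes that are constant across
all samples map to all zeros and are flagged rather than rejected —
every downstream test treats them as "no difference" (D = 0, p = 1), so
flat probes in real exports cannot crash a run.

## Design decisions in the statistical layer

**K-S p-values.** For $n_{pos} \cdot n_{neg} \le 10{,}000$ the p-value
comes from the exact conditional null distribution of D (all class
assignments, continuous-data assumption); beyond that, from the
asymptotic Kolmogorov distribution with Stephens' small-sample
correction $(\sqrt{m} + 0.12 + 0.11/\sqrt{m})\,D$,
$m = n_{pos}n_{neg}/(n_{pos}+n_{neg})$. The exact branch matters: the
two-sample D null is discrete, and mid-range D values sit on large
probability atoms where the continuous approximation can be off by
several hundredths — enough to misplace the decision boundary at small
$\alpha$. Monte-Carlo permutation checks in the test suite pin the exact
branch to within sampling error. Since the p-value is monotone in D, the
rule "p ≤ α" is identical to the classical "D ≥ D_crit(α)" formulation.

**ECDF ties.** The ECDF uses the right-continuous "≤" convention, and D
is evaluated at the pooled unique observation points, where the maximum
of a difference of two step functions is always attained.

**Wilcoxon and t.** The rank-sum test reports the rank sum of the
smaller group with midranks and takes its two-sided p-value from the
normal approximation with tie-corrected variance and 0.5 continuity
correction — the convention of standard statistical software at these
sample sizes (an exact enumeration oracle appears only in the tests).
The t test is Welch's unequal-variance form, the safer default when
per-class variances differ — which is exactly the situation the K-S
stage is there to exploit. Both are two-sided throughout: the screening
question is nondirectional.

**No multiple-testing correction.** Stage 1 filters at raw $\alpha$ by
design — the level is a knob for candidate-set size, not an inferential
claim about individual genes. Users wanting FDR control can apply
`p.adjust` to the `filter_genes()` report.

## Design decisions in the selection layer

**Association measure.** Gene–class association is the absolute
point-biserial (Pearson) correlation; gene–gene association is the
absolute Pearson correlation of *within-class centered* values. Two
points deserve spelling out.

First, why correlation rather than the information-theoretic
symmetrical uncertainty (SU) over discretized values that CFS
implementations descended from Weka use? Because independent
discretization erases near-ties. Discretizing each gene separately
(supervised MDL or quantile bins) puts two near-identical genes on
slightly different cut points, so a 0.05-sd near-copy of a gene scores
SU ≈ 0.9 against its source rather than ≈ 1 — and the merit denominator
only bites on redundancy when the pairwise association is essentially 1.
Working on the continuous values keeps a near-copy at |r| ≈ 0.999. SU
over MDL- or quantile-discretized codes remains available
(`association = "su"`), and is the better choice when class association
is strongly nonlinear; the default favors the redundancy contract.

Second, why center within classes for the gene–gene term? Any two genes
that are both class-associated are correlated *through the class*
(roughly $r_1 r_2$ on raw values). Counting that shared class signal as
"redundancy" penalizes precisely the genes the panel exists to collect.
Removing the class means leaves only the within-class co-variation —
co-regulation, duplication — which is what redundancy ought to mean.

**Duplicate pre-collapse.** The merit has a structural blind spot for
exact duplication: if within-copy association is 1 and cross-gene
association is purely class-driven, merit is *invariant* under
duplicating every subset member the same number of times
($\mathrm{merit}^2 = (\sum r_{cf})^2 / \sum c_i^2$ with copy counts
$c_i$, maximized at equal $c_i$ regardless of their value). With sample
associations a hair below 1, the fully-duplicated subset even gains a
hair of spurious merit, so a merit-guided search lands on either side of
the tie essentially at random. `cfs_select()` therefore collapses
clusters of candidates with pairwise association at or above
`dedup_threshold` (0.95) to their most class-associated member before
searching. 0.95 sits far above within-class correlations that arise by
sampling noise at these n (≲ 0.5) and below nothing one would want to
keep apart.

**Best-first search.** Forward best-first from the empty set: the open
node with the highest merit is expanded by every absent gene; the search
stops after `stall = 5` consecutive expansions that fail to improve the
best merit seen. Ties break toward the earlier-generated node, making
results deterministic and order-stable. On small candidate sets this
search recovers the exhaustive-subset maximum merit (verified on random
instances in the acceptance checks).

**Locally predictive sweep.** Because the merit averages associations,
it saturates: once a subset holds ~15–20 comparably informative genes,
one more such gene moves the mean too little to register, and the search
stops short of genuinely independent signals. Following CFS practice,
after the search any unselected gene whose class association strictly
exceeds its association with *every* selected gene is swept in,
strongest first, iteratively. A redundant copy can never qualify (its
association with its source exceeds any class association), so the sweep
recovers orphaned signals without undoing the redundancy removal. On the
benchmark preset this step is what lifts planted-signal recall from
roughly half to two-thirds.

**mRMR.** Difference (MID) form over mutual information in bits between
three-level discretized expression (cuts at mean ± sd) — the common
convention for continuous expression — with the quotient (MIQ) form
behind a flag. The reported score is the greedy criterion value at
selection time.

**ReliefF.** Manhattan distance on range-normalized standardized
values, `k_neighbors = 10`, all instances used in order (hence fully
deterministic); misses weighted by class priors. A constant gene
contributes no distance anywhere and gets weight exactly 0.

**Forward selection.** Genes are taken in rank order; one is kept iff it
*strictly* improves the evaluator's cross-validated accuracy. Strictness
is the stopping rule: under ties nothing is added, so a constant
evaluator yields exactly the top-ranked gene and subset growth is
bounded.

**Tie-breaking everywhere** is by score first, original gene order
second, so every selector is deterministic and invariant to candidate
input order.

## The evaluation protocol and its bias

`repeated_shuffle_evaluation()` reshuffles the sample order per repeat
(seed `base_seed + r`), re-runs the selector on the shuffled dataset,
and cross-validates the selected subset. Note what this means: by
default **selection sees the full dataset, including samples that later
serve as CV test folds**. This selection-outside-the-loop protocol is
the one the package's comparison tables mirror, and it is optimistically
biased — accuracies are best read as comparisons between methods under
one protocol, not as unbiased generalization estimates. The stricter
variant, `per_fold = TRUE`, re-runs selection inside each training fold;
an instrumented-selector test verifies that held-out samples are then
never visible to selection. Folds are stratified by class (plain random
folds can starve a fold of the minority class at these sizes), and
accuracy is reported in percent.

## What the synthetic generator emulates — and what it does not

`simulate_expression()` plants four gene roles: mean-shifted genes
(location signal, `shift_effect` in within-class sd units),
variance-shifted genes (`scale_ratio`, equal means — the K-S test's
home turf), redundant near-copies of informative genes
(`redundancy_noise` perturbation sd), and standard-normal noise genes.
The default preset — 2,000 genes: 20 shift at 2 sd, 10 scale at ratio
3, 15 copies at 0.05 sd, 1,955 noise, 40 samples per class — matches
the shape of the classic benchmark matrices (thousands of genes, tens of
samples per class, a small informative minority) at a size a laptop
re-verifies in seconds. Effect sizes were fixed once: 2 sd is a strong
but realistic differential-expression effect after standardization, and
ratio 3 a clearly heteroscedastic gene.

What the generator deliberately does not emulate: heavy-tailed and
skewed expression distributions, probe-level artifacts and missingness,
correlated noise blocks (batch effects), class imbalance, and
label noise. Consequently, passing tests show that the algorithms do
what they claim under clean Gaussian structure — they do not certify
performance on any real dataset. The honest claims are directional:
K-S catches distributional shifts the location tests miss; CFS removes
planted redundancy the filter keeps; the two-stage pipeline matches the
filter's accuracy with decisively fewer genes.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run, per invocation: the
2,000-gene null calibration at n = 50/50; 200 variance-only genes for
the power comparison; 100 random ≤ 10-gene datasets against exhaustive
subset enumeration; 50 seeded duplicate-removal runs; and the full
benchmark preset through selection plus two 10 × 10-fold evaluation
protocols. Together these complete in about a minute on one CPU.

## Known limitations

* Binary classes only; multiclass labels are rejected at load time.
* The K-S exact p-value assumes continuous data; with heavy ties it is
  conservative (the permutation distribution conditional on ties is
  tighter).
* CFS with the correlation association can miss purely nonlinear class
  signals (e.g. variance-only genes rarely survive stage 2 even when
  stage 1 catches them); `association = "su"` trades redundancy
  sharpness for that sensitivity.
* Best-first search with a stall limit is a heuristic; beyond a few
  dozen candidates global optimality is not guaranteed (nor needed — the
  stage-1 filter is what keeps the candidate set in that regime).
* Runtime of the full pipeline is dominated by the pairwise association
  matrix when stage 1 is run at large `alpha`; no optimization beyond
  caching is attempted.
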