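---
title: "Methods: information-based fingerprint reduction with aicmax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: information-based fingerprint reduction with aicmax}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical model, the algorithmic and numerical
choices, and the scope of the synthetic validation suite behind `aicmax`. It
is a methods document, not a tutorial; see the README for a worked example.
Code chunks are shown but not evaluated at build time.

## The score

Let $Y \in \{0, 1\}$ be a binary activity label and let $X$ be the joint
pattern of a subset of binary fingerprint bits (a string in $\{0,1\}^k$ for a
$k$-bit subset). The score of the subset is the normalized mutual information

$$\mathrm{AIC}_Y(X) \;=\; \frac{I(X; Y)}{H(Y)}
  \;=\; \frac{H(Y) - H(Y \mid X)}{H(Y)} \;\in\; [0, 1],$$

with all entropies in bits (base-2 logarithms) and the convention
$0 \cdot \log 0 = 0$. A score of 0 means the bit patterns carry no
information about the label; a score of 1 means the label is a deterministic
function of the pattern. Because the score is built on the *joint* pattern
distribution, it detects interactions that no per-bit statistic can see: two
bits whose XOR equals the label each have a singleton score of exactly 0 but
a pair score of 1 (`xor_showcase_dataset()` constructs this case exactly).

All probabilities are maximum-likelihood relative frequencies of the observed
rows — no pseudocounts, no smoothing. This is a deliberate choice: the score
is a descriptive statistic of the sample, and the selection procedure only
ever compares scores computed on the same sample, so a shared bias does not
change rankings. The cost is optimism on small samples (patterns observed
once look perfectly predictive); the evaluation harness exists precisely to
check selections on held-out data.

For multi-target selection, `aic_score_multi()` averages the per-task scores
with equal weights by default. Unequal task sizes could motivate weighting;
equal weights match the interpretation "each target's assay is one
experiment" and are the package default, with `weights` exposed.

## Greedy forward selection

`greedy_select()` grows the subset one bit at a time, at each step adding the
bit that maximizes the (multi-task average) score of the enlarged subset.
Exhaustive search over subsets is exponential and is implemented only as a
test oracle (`brute_force_aic()`, capped at 16 bits). The incremental
implementation maintains, per task, a dense index of observed patterns and
extends it by one bit in $O(n)$ time, so a full selection run is
$O(k \cdot B \cdot n)$ for $k$ steps over $B$ candidate bits.

Numerical policy:

* Scores within $10^{-12}$ of the step maximum are treated as tied; ties are
  broken by the higher mean singleton score, then by the lower bit id. This
  makes selections reproducible across platforms in the presence of
  floating-point noise.
* A score may undershoot 0 or overshoot 1 by floating-point underrun only;
  violations up to $10^{-12}$ are clipped and anything larger is treated as
  an internal error rather than silently truncated.
* `saturated_at` records the first step whose score reaches $1 - 10^{-9}$.
  Selection continues to the requested budget (further bits are ties at the
  ceiling and follow the tie-break rule), because downstream set summaries
  expect fixed-size selections.

The default budget is `k = 100` bits per task, a selection size small enough
for manual inspection while typically far above saturation on separable
tasks.

## Activity thresholds and pair tasks

`split_activity()` labels a compound active when its potency is at most
100 nM and inactive when above 1000 nM, with potencies in nM throughout;
compounds in the (100, 1000] gap are discarded, and replicate measurements
are collapsed by the median before thresholding. Both cutoffs are arguments,
not constants.

Ligand-selectivity analysis builds one binary task per unordered target pair:
actives of target A (label 1) versus actives of target B (label 0).
Compounds active at both targets are excluded by default and counted in
`excluded_overlap`, since they carry no selectivity signal; the alternative
`overlap = "by_potency"` assigns each dual active to its higher-potency
target. A pair left with fewer than two compounds in either class raises a
typed condition (`aicmax_degenerate_pair`); `select_all_pairs()` records such
pairs as skipped instead of failing the whole analysis. Per-target summaries
are the union (`union_bits()`) and intersection (`core_bits()`) of the
selected sets over all pairs involving that target.

## Evaluation harness

`cross_validated_mcc()` runs stratified $k$-fold cross-validation (default
10-fold; folds shrink with a warning when a class is smaller than the fold
count) and computes one Matthews correlation coefficient on the pooled
out-of-fold predictions. A confusion matrix with a zero marginal yields an
MCC of 0 with a warning — a stated convention, since the statistic is
undefined there.

`compare_representations()` computes, per task, the MCC of the raw (all-bit)
representation and of the reduced subset at the same folds and seed, labels
the difference `+`, `-`, or `nc` with an `nc` band of $|\Delta| \le 0.005$,
and runs a one-sided Wilcoxon signed-rank test ("reduced better") on the
non-`nc` differences. The signed-rank tail is exact for up to 25 differences
(computed by generating-function convolution over doubled ranks, which
handles ties and equals literal enumeration of all $2^n$ sign assignments)
and a continuity-corrected, tie-corrected normal approximation beyond that.
The default learner is a random forest (`ranger`, 500 trees,
$\lfloor\sqrt{p}\rfloor$ candidate features per split, one thread, seeded);
the learner is an adapter interface (`new_learner()`), and a deterministic
single-bit stump (`learner_stump()`) is provided for fast, exactly
reproducible harness tests.

One caveat discovered during validation and worth stating: the signed-rank
test assumes the paired differences are symmetric under the null. When the
two representations differ in size (a subset versus all bits) and the
learner performs feature selection internally, the difference distribution
can be noticeably skewed even when the labels are independent of every bit,
which makes the one-sided test anti-conservative in that regime. The
package's type-I simulations therefore pair two exchangeable, equal-size,
disjoint subsets on null tasks — the design under which the null hypothesis
actually holds. Users comparing representations of very different sizes
should read small p-values with this asymmetry in mind.

## Synthetic data and what passing means

All validation runs on generated data with planted ground truth, because the
score, the selection, and the harness can then be checked against known
answers:

* `generate()` plants bits with specified per-class occurrence rates
  (closed-form singleton scores are recorded in the manifest via
  `closed_form_aic()`), XOR pairs whose parity overrides the labels,
  duplicated columns, and independent noise bits. Column generation is
  seeded per (target, bit), so adding bits never perturbs existing columns.
* `generate_pairwise_suite()` builds multi-target active sets in which each
  target has characteristic bits (occurrence 0.7 on its own actives, 0.1
  elsewhere by default — an effect size of 0.6), plus shared noise bits,
  optional dual-active overlap, and an optional degenerate pair.
* `xor_showcase_dataset()` is fully deterministic and exactly balanced, so
  the XOR recovery property holds with equality rather than with high
  probability.

The acceptance-level problem sizes are the package's own choices, set to
make the checks sharp yet fast on one CPU: planted-bit recovery uses 20
seeded suites of 4 targets (6 pairs) with 300 actives per target and effect
0.6; the type-I simulation uses 500 suites of 8 null tasks (30 per class, 12
noise bits) with the stump learner; the dilution experiment uses 12 tasks of
200 compounds per class whose 5 informative bits are diluted by 1000 noise
columns, evaluated with a 150-tree forest and 5-fold cross-validation. These
quantities are recomputed from scratch by `scripts/acceptance.R` and by the
test suite; none of them are stored constants.

Passing these checks demonstrates correctness of the implementation and
recoverability under the generator's assumptions (independent compounds,
class-conditionally independent planted bits, stationary noise). It does
not certify performance on real fingerprint data, where bits are correlated
by substructure nesting and compound series; the evaluation harness is the
tool for that judgement on a per-dataset basis.

## Fingerprints for real molecules

`compute_krfp()` computes substructure-key fingerprints from SMILES via the
OpenBabel SMARTS matcher (ChemmineR/ChemmineOB, listed in Suggests). Two
limitations are explicit:

* The shipped 4860-key dictionary (`synthetic_krfp_keys()`) is a synthetic
  stand-in of the same size and format as the Klekota–Roth key set, whose
  original SMARTS list is distributed with external software and not
  redistributed here. Substitute a real key file through the `keys`
  argument for production use.
* Aromaticity and tautomer perception differ between toolkits, so key hits
  are not bit-for-bit portable across fingerprinting engines; the matcher
  is recorded in the output's `"matcher"` attribute.
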