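---
title: "Dynamic amino-acid characteristics and crystallization propensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic amino-acid characteristics and crystallization propensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crystprop)
```

## The modelling problem

Crystallization propensity is treated here as a binary label per protein
(crystallized under a screening criterion or not), to be predicted from a
20-dimensional encoding of the sequence. Constant characteristics — one
fixed number per residue type, as catalogued in AAIndex — are inflexible:
two proteins of equal composition receive identical encodings however
differently their residues are arranged. The package therefore implements
three *dynamic* characteristics whose values depend on the whole sequence,
and the benchmark machinery to compare them against constant
characteristics under identical models and validation.

## Distribution probability

### Model

The r residues of one amino-acid type are modelled as r distinguishable
balls dropped uniformly at random into n equal partitions of the
sequence, with n = r. If the observed occupancy vector is
$(r_1,\dots,r_n)$ and $q_j$ partitions hold exactly $j$ residues, the
probability of that occupancy pattern is

$$\frac{r!}{q_0!\,q_1!\cdots q_n!}\times
  \frac{r!}{r_1!\,r_2!\cdots r_n!}\times n^{-r}.$$

The second factor counts ball-to-hole assignments realizing a fixed
ordered occupancy; the first counts the orderings sharing the same
multiset of occupancies; $n^{-r}$ is the uniform probability of each
assignment. The 20 per-type probabilities form the `distribution`
encoding.

### Partitioning rule

When L is not divisible by r the sequence cannot be cut into exactly
equal partitions. The package cuts 1..L into n = r contiguous partitions
whose lengths differ by at most one residue, placing the longer
partitions first (the first `L mod r` partitions get the extra residue).
This rule is deterministic and documented at the interface
(`partition_occupancy`); placing the longer partitions last, or spreading
them, are coherent alternatives that were considered and not implemented —
for typical compositions they perturb individual occupancies by at most
one count. Positions are 1-based throughout.

Two conventions complete the definition: an absent residue type has
probability 0 (not undefined), and a singleton necessarily has
probability 1.

### Numerics

The formula is evaluated in log space with `lfactorial`, taking a single
`exp` at the end. Factorials of counts in the hundreds (r = 17 lysines is
routine; r > 100 occurs in long proteins) overflow double-precision
arithmetic long before the probability itself — which always lies in
(0, 1] — so the log-gamma route is the numerically stable choice; it
agrees with exhaustive enumeration of all $n^r$ ball assignments to
within $10^{-12}$ for every occupancy pattern with $r \le 6$, and the
probabilities over all patterns of fixed r sum to 1 at the same
tolerance (both are tested).

## Future composition

Each amino acid's codons (standard genetic code, via Biostrings) are
subjected to all nine single-nucleotide substitutions; tallying the
translated targets over a residue's codons gives the transition matrix
$P(a \to b)$. The future composition of type b is
$100\sum_a c_a P(a\to b)$ percent, with $c_a$ the current composition.

Three conventions are configurable because the reference matrix for this
construction is not fully specified anywhere the package can consult:

* **Codon weighting** — uniform over a residue's codons. Protein
  sequences carry no codon-usage information, so any organism-specific
  weighting would be an unverifiable assumption.
* **Stop-codon targets** — excluded and the row renormalized (default),
  so every row is stochastic and future compositions conserve total mass
  at 100 %; a `keep` option retains the lost mass for sensitivity
  analyses.
* **Synonymous transitions** — included by default (a substitution that
  preserves the amino acid is still a mutational outcome); excludable.

A caveat worth recording: published per-protein tables of this
characteristic show future-composition columns summing to far less than
100 %, which cannot be produced by any row-stochastic matrix applied to a
composition. The implementation follows the verbal definition literally
(conservation holds by construction); the normalization behind such
printed tables is unknown, and those printed values are not used as
reference points.

## Pair predictability

Under independence of residues, the expected count of the adjacent
ordered pair XY among the L − 1 overlapping pairs is
$r_X r_Y / L$ for $X \ne Y$ and $r_X (r_X - 1)/L$ for $X = Y$ —
equivalently $r_X/L \times r'_Y/(L-1) \times (L-1)$ with the
second-draw count $r'_Y$. Summed over all 400 ordered pair types this is
exactly $L - 1$, a conservation law the tests check on random
compositions.

The expected count is rounded half-up to the predicted integer (2.23
predicts two occurrences; 0.46 predicts none — half-up agrees with plain
rounding on every case that defines the characteristic, and half-up makes
the tie deterministic). Under the default **strict** rule, all actual
pairs of a type are predictable iff actual equals predicted; the **min**
rule instead credits min(actual, predicted) pairs of each type. The
strict rule is the default because the characteristic's verbal definition
classifies pair types wholesale; the min rule is kept behind a flag as
the natural partial-credit variant. Portions are percentages of L − 1 and
sum to 100 under both rules.

## Constant-characteristic benchmark

AAIndex1 flat files are parsed into per-residue value tables (native
A/R/N/D/C/Q/E/G/H/I + L/K/M/F/P/S/T/W/Y/V row order, re-ordered
alphabetically; `NA` values masked). The benchmark encoding weights each
value by the residue's count, $x_a = \mathrm{value}_a \times
\mathrm{count}_a$; the unweighted `raw` mode — constant across proteins —
is retained only to demonstrate the inflexibility argument. A
characteristic with a masked residue present in a protein errors unless
an imputation value is supplied; at screen time such characteristics are
flagged and skipped, which mirrors the practice of excluding a small
number of incomplete AAIndex entries from a benchmark set.

One property of the weighted encoding matters when interpreting screens:
for characteristics with all-nonzero values, the encoding is an
invertible diagonal rescaling of the count vector, so a logistic
regression attains *identical* accuracy on every such characteristic —
duplicated or near-duplicated characteristics tie exactly (the screening
table breaks those ties alphabetically). Discrimination between constant
characteristics comes from zero/masked entries and from nonlinear models;
discrimination between constant and dynamic characteristics comes from
the positional information only the latter carry. The planted-signal test
exploits exactly this: labels planted on the distribution encoding are
recovered best by the distribution encoding, ahead of 55 constant
decoys.

## Models

**Logistic regression.** $P(y)=1/(1+e^{-(b_0+\sum_i b_i x_i)})$, fitted
by maximum likelihood (`stats::glm`) on internally z-scored predictors
with coefficients mapped back to the original scale. A positive-exponent
variant of the equation ($1/(1+e^{+\eta})$) is supported as a sign
convention; refitting under either convention negates the coefficients
and leaves every predicted probability unchanged (tested to $10^{-9}$).
Constant columns get coefficient 0 with a warning. Complete separation —
non-convergence, diverging standardized coefficients, or a numerically
perfect fit — triggers an automatic refit with a small L2 penalty
($\lambda = 10^{-4}$, penalized IRLS, intercept unpenalized) and a
notice; any $\lambda > 0$ may also be requested directly, which is the
route for $n \le 21$ datasets.

**Neural network.** A 20→10→1 single-hidden-layer feed-forward network —
20 inputs (one per residue type), 10 hidden units, one sigmoid output —
trained on cross-entropy by `nnet::nnet` with an explicit
uniform(−0.5, 0.5) initial weight vector drawn from the caller's seed, so
identical (data, seed, config) give bit-identical weights. `nnet`'s
hidden activation is the logistic sigmoid; since no reference trainer is
available to match weight-for-weight, the contract is behavioral and the
tests pin capacity (≥99 % training accuracy on linearly separable data;
beats logistic regression on XOR-structured data), determinism, and the
fixed 241-weight architecture rather than any particular optimizer
trajectory.

Classification thresholds probabilities at 0.5 with ties to the positive
class (documented and tested).

## Evaluation

Accuracy, sensitivity and specificity follow the standard confusion
formulas in percent; a zero denominator yields `NA` rather than 0.
Delete-1 jackknife validation trains n models of n − 1 samples and
assembles the report from the n held-out predictions only; per-fold seeds
derive deterministically from (seed, fold index), and a fold whose
training labels are single-class falls back to the training prevalence
and is flagged. Held-out predictions are invariant to the ordering of the
other samples (tested).

ROC curves sweep thresholds over the distinct scores plus ±∞ sentinels;
the AUC is trapezoidal in the standard sensitivity vs (1 − specificity)
convention and equals the Mann–Whitney $U/(n_1 n_2)$ identity to
$10^{-9}$ (tested, and cross-checked against pROC). The point table also
carries the sensitivity-vs-specificity convention used when plotting
against the diagonal line of indiscrimination.

For the group comparison of predictable portions, each protein's
accuracy is defined as the percentage of repeated model fits (default 20
seeds; full-data models in fit mode, held-out predictions in jackknife
mode) in which it is classified correctly — with a deterministic fitter
this collapses to 0/100, with the neural network it grades. This
repeated-seeds definition is one reasonable reading of a per-protein
accuracy bar; it is configurable (`n_repeats`) precisely because it is an
interpretation. Proteins are split at a 90 % accuracy cutoff and their
predictable portions compared by a two-sided Mann–Whitney rank-sum test:
exact when the smaller group has ≤ 8 untied observations, otherwise the
normal approximation with tie correction; if every observation is tied
across both groups the statistic is the midpoint $n_1 n_2/2$ and p = 1.

## The synthetic-data generator

`synthetic_spec`/`generate_dataset` emulate the study conditions the
package is designed around: 301 proteins, lengths uniform in 50–1000
residues, label prevalence 85/301, and i.i.d. residues from a uniform
composition (0.05 per type — no composition statistics are available for
the reference set; a `table1` preset reuses the composition of the
122-residue worked-example protein). Labels are either independent noise
at the target prevalence or planted through a logistic model on a chosen
encoding, with the intercept tuned to the target prevalence by bisection
on the simulated mean probability. The default planted coefficients put
moderate effects (±3, ±2) on four residue types of the distribution
encoding — enough signal to be recoverable, not enough to separate; the
planted-screen fixtures use larger effects (±8, ±6) so the ranking check
is clear of sampling noise.

What the generator does **not** emulate: real crystallization biology
(labels are statistical fixtures), residue autocorrelation, domain
structure, homology between proteins, or length–label dependence.
Passing tests therefore demonstrate that the estimators and validation
machinery are correct and well-calibrated under a known
generating process — not that any characteristic predicts real
crystallization outcomes.

## Problem sizes and known limitations

The test suite exercises coefficient recovery at n = 5000 (where planted
coefficients are recovered within 3 standard errors on the generating
encoding), screening at the study scale n = 301 against 55 decoys,
jackknife contracts at n = 10–301, and exhaustive occupancy enumeration
at r ≤ 6; these sizes are the package's chosen trade-off between
statistical resolution and a suite that runs in about a minute.

Two limitations are worth flagging. First, delete-1 jackknife accuracy of
a weakly-regularized logistic model on *small* unbalanced null datasets
falls below the majority-class baseline — the held-out sample's absence
tilts the training prevalence against its own label — which is a known
pessimism of leave-one-out with near-chance models, not a defect of the
implementation; at n ≈ 300 the null jackknife sits within a couple of
points of baseline (tested). Second, the predictable-portion
reference value of 75.25 % quoted for a specific 122-residue protein
cannot be audited offline (the sequence, not just its composition, is
required, and 75.25 % of 121 pairs is not an integer count, so the
original denominator convention is itself uncertain); the pair classifier
is instead validated on constructed sequences where every count is
enumerable by hand.
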