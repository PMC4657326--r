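# crystprop

Predicting whether a purified protein will crystallize is a long-standing
bottleneck in structural biology: most sequence-based predictors encode a
protein with *constant* amino-acid characteristics (hydrophobicity scales,
chain-length indices, and the other per-residue values catalogued in
AAIndex), which assign the same number to a residue type in every protein
regardless of where its residues actually sit. `crystprop` implements an
alternative family of *dynamic* characteristics — per-protein quantities
that change with sequence context — together with the full screening,
fitting, jackknife-validation and ROC machinery needed to compare them
against the constant-characteristic benchmark on a binary
crystallized/not-crystallized label. It is aimed at structural
bioinformaticians studying sequence determinants of crystallization
propensity.

## The three dynamic characteristics

**Distribution probability.** The r residues of one amino-acid type are
treated as r distinguishable balls dropped into n = r equal contiguous
partitions of the sequence. The probability of the observed occupancy
pattern (r₁, …, rₙ), with qⱼ partitions holding exactly j residues, is

    r!/(q₀!·q₁!···qₙ!) × r!/(r₁!·r₂!···rₙ!) × n⁻ʳ

A residue type whose placement is "typical" scores high; clustered or
conspicuously even placements score low. Absent types score 0, singletons
score 1.

**Future composition.** Each amino acid's codons are mutated one
nucleotide at a time under the standard genetic code, giving a 20×20
transition matrix P(a→b). The future composition of type b is
100 × Σₐ cₐ·P(a→b) percent, where cₐ is the current composition — the
composition the protein drifts toward after one round of point mutation.

**Pair predictability.** Under residue independence, the adjacent pair XY
is expected rX·rY/L times (rX(rX−1)/L for X = X). In a 122-residue protein
with 17 lysines, KK is expected 17·16/122 = 2.23 times; if KK is observed
the rounded predicted number of times, those pairs are *predictable*,
otherwise *unpredictable*. The predictable portion (% of the L−1 adjacent
pairs) is a whole-protein characteristic.

Each encoding feeds a logistic regression
P(y) = 1/(1+e^−(b₀+b₁x₁+…+b₂₀x₂₀)) or a 20→10→1 feed-forward neural
network, evaluated by accuracy/sensitivity/specificity in fit mode and
under delete-1 jackknife validation, with ROC analysis and a Mann–Whitney
comparison of predictable portions between well- and poorly-predicted
proteins.

## Worked example

```r
library(crystprop)

# expected adjacent-pair counts from a composition (L = 122, 17 K, 7 G, 8 S)
cts <- setNames(integer(20), AMINO_ACIDS)
cts[c("K", "G", "S")] <- c(17L, 7L, 8L)
round(expected_pair_count(cts, 122, "K", "K"), 2)
#> [1] 2.23        # KK expected about twice
round(expected_pair_count(cts, 122, "G", "S"), 2)
#> [1] 0.46        # GS should not appear

# distribution probability of an occupancy pattern
distribution_probability(occupancy_pattern(c(2, 1, 0)))
#> [1] 0.6666667

# a synthetic study: 301 proteins, labels planted on the distribution encoding
ds <- generate_dataset(synthetic_spec(n_proteins = 301, seed = 1,
                                      label_model = "planted_logistic"))
ds
#> <labeled_dataset> n = 301, positives = 71 (prevalence 0.236)

enc   <- encode_dataset(ds, distribution_vector)
model <- fit_logistic(enc$X, enc$y)
evaluation_report(rownames(enc$X), predict_logistic(model, enc$X), enc$y)
#> <evaluation_report> mode = fit, n = 301 | acc 79.07%, sens 14.08%, spec 99.13%

jackknife_delete1(ds, distribution_vector, "logistic", seed = 1)
#> <evaluation_report> mode = jackknife, n = 301 | acc 74.42%, sens 4.23%, spec 96.09%

roc_curve(predict_logistic(model, enc$X), enc$y)
#> <roc_curve> 303 points, AUC = 0.6356
```

The fit/jackknife reports show the regime typical of unbalanced
crystallization data: accuracy near the majority-class baseline, very high
specificity and low sensitivity; jackknife metrics sit below fit metrics
because each held-out protein is predicted without itself.

A command-line front end wraps the same functions:

```sh
exec/crystprop synth --n 301 --seed 1 --out-dir demo
exec/crystprop featurize --fasta demo/proteins.fasta --out demo/features.tsv
exec/crystprop screen --fasta demo/proteins.fasta --labels demo/labels.csv \
    --aaindex demo/aaindex1.txt --model logistic --out demo/screen.tsv
exec/crystprop jackknife --fasta demo/proteins.fasta --labels demo/labels.csv \
    --encoding distribution --model nn --seed 1 --out demo/jk.tsv
```

Every subcommand is deterministic given `--seed` and writes a JSON
manifest beside its outputs.

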