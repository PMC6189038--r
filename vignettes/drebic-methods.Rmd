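---
title: "Methods: from knockout screen to drug-response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from knockout screen to drug-response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drebic)
```

This vignette is the package's account of its statistical methods: the
models, the tunable parameters and their defaults, the numerical decisions
taken where the underlying procedure is ambiguous, what the synthetic-data
generator does and does not emulate, and the known limitations.

## 1. Screen scoring

### Read handling

Amplicon reads carry a composite sample barcode (56 nt in the screens this
package was designed around) followed by the sgRNA spacer.
`assign_sample_barcode()` assigns a read to a sample when a contiguous
stretch of at least `min_match = 36` barcode nucleotides is present in the
read's start region. Matching is an exact substring match: the threshold is
the method's defined parameter, and exact matching keeps demultiplexing
deterministic and directly testable. Sequencing truncates barcodes from the
5' side, so all barcode suffixes of length ≥ `min_match` are tried. Reads
matching barcodes of two samples are left unassigned with a warning rather
than raising an error, since a pooled run should survive a handful of
pathological reads.

`count_guides()` gives each read at most one count: under the default
`scan` policy the read is searched for any library spacer and reads
containing spacers of two different guides are discarded (tallied in
`n_ambiguous`); under `fixed` the spacer is read at a configured offset.
Where the barcode sits and where the spacer starts are platform details,
not constants of the method, so both are parameters; the generator's FASTQ
layout (barcode, 10-nt stuffer, spacer, hence offset 66) documents one
concrete choice. Base qualities are ignored throughout — the pipeline's
unit of evidence is an exact 20-mer match, and a sequencing error anywhere
in the spacer already voids the match.

### Normalization

`normalize_counts()` uses median-of-ratios size factors: guides with
nonzero counts in every sample define per-sample medians of the ratio to
the guide's geometric mean. This is the standard count-normalization for
pooled screens and sequencing count data generally; it is insensitive to a
minority of strongly depleted or enriched guides, which is exactly the
signal the screen is meant to find. A sample with all-zero counts is a
failed library and raises an error naming the sample.

### Viability scores

For each treated replicate, guide log2 fold changes are taken against the
mean of the control replicates, with a pseudocount of 1 on normalized
counts (`pseudocount` is configurable; zeros are common in vivo, and an
additive constant is the simplest transparent guard). LFCs are z-scored
per comparison using the population SD over *all* scored guides. The
standardization population matters: standardizing against all guides (not
controls only) keeps gene z-scores and control z-scores on one scale, which
is what the downstream gene-vs-control comparison assumes.

The gene score is the median of guide z-scores within a comparison, then
the median across replicate comparisons. The aggregation order
(LFC → z → median over guides → median over replicates) is fixed; the
alternative reading — median of raw abundance ratios first, log
afterwards — is available as `gene_score_log_median_ratio()` for
comparison. Medians are used at both levels because a pooled screen's
guide-level values are heavy-tailed (cloning artifacts, off-target
killing); the tests verify empirically that one corrupted guide in five
moves a gene score only to a neighboring order statistic.

Significance per gene is a two-sample Kolmogorov–Smirnov test of the
gene's guide z-scores against the control guides' z-scores
(`gene_ks_test()`), exact for small tie-free samples and asymptotic
otherwise. The package's `alternative = "less"` tests stochastic depletion
and maps to `stats::ks.test(..., alternative = "greater")`, whose
convention is about CDF ordering; the mapping is pinned by tests against a
brute-force enumeration oracle.

Hit calling (`consistent_hit_genes()`) classifies each guide against the
25–75% band of control LFCs in every replicate (quartiles by linear
interpolation, R type 7 — stated explicitly because boundary
classifications depend on the estimator; values exactly on a quartile are
`unchanged` since the rule uses strict inequalities). A guide is a true
hit only if it falls on the same side in *all* replicates. A gene needs
`min_consistent_guides = 2` agreeing true guides — one guide is never
treated as gene-level evidence, since single-guide effects are the classic
off-target signature. Genes rank by (number of true guides, |median LFC of
those guides|), both descending, then name.

## 2. DREBIC scores

Expression is centered per gene in log2 space with `epsilon = 1`
(`center_log_expression()`), i.e. each value becomes the log2 ratio to the
gene's geometric mean. Microarray-style data that are already log-scale
take `already_log = TRUE` rather than a guessed heuristic. The centering
cohort is by default the cohort being scored — the score is deliberately
ordinal and cohort-relative — and a `reference` argument freezes the
per-gene means so new samples can be scored against an established cohort.

`build_drebic_model()` takes the `n_depleted` most negative and
`n_enriched` most positive viability scores (defaults 175/225, the
optimized sizes in the screen this package emulates), with alphabetical
tie-breaks so model construction is reproducible to the byte.

### The sign convention

The published form of the scoring equation subtracts the enriched-gene
sum while ordering genes by descending viability score. Taken literally,
that makes a sample *over*-expressing resistance genes score as *more*
sensitive — the opposite of the observed biology that cells expressing
less of the enriched genes are more resistant. The package therefore
defaults to the `signed_sum` convention:

$$\mathrm{raw}_S \;=\; \sum_{g\in\text{depleted}} C_g\,G_{S,g}
 \;+\; \sum_{g\in\text{enriched}} C_g\,G_{S,g},$$

where every score carries its own sign (depleted C < 0, enriched C > 0),
so both gene classes contribute in the direction their screen phenotype
implies. The literal form is retained as `convention = "printed_eq1"` for
side-by-side comparison. This is the package's most consequential design
decision and the reason both conventions are exposed and tested.

Raw scores are rescaled affinely so the cohort spans [−1, +1]
(`rescale_scores()`); a degenerate cohort (one sample, or all raw scores
equal) maps to 0. Rescaling preserves ranks, so it can never change an
AUC.

## 3. Evaluation

`stratify_responders()` labels the lowest log-IC50 quartile responders and
the highest non-responders (type-7 quartiles; boundary ties are included
in the labeled class, which matters on discrete IC50 grids). Ambiguous
middle-half samples are excluded from ROC analysis: the evaluation
question is whether the score separates clear responders from clear
non-responders.

`roc_auc()` computes the AUC by the Mann–Whitney identity with ties
counting ½, which the tests pin to an exhaustive pair-counting oracle and
to an independent implementation (pROC). `optimize_model_size()` searches
the depleted and enriched set sizes separately (two one-dimensional grid
searches, ties to the smaller model) — a deliberate simplification that
matches how the emulated analysis was optimized and keeps the search
interpretable.

`permutation_null()` draws the two random gene sets disjointly and without
replacement (the natural reading of "two random sets"), carries the genes'
*actual* viability scores, and is right-tailed by default: the question
posed is whether the real model predicts better than random models of the
same size. An absolute-deviation two-tailed option exists. The seed is a
required argument; there is no silent global-RNG mode. Note that the
permutation replicates share one cohort and label assignment, so their
mean converges to the cohort-conditional chance level, which itself varies
around 0.5 like 1/√n_samples — visible when comparing small cohorts.

`average_roc()` follows the upper-staircase convention: at each x on the
union of all curves' breakpoints (an exact grid, not a fixed lattice),
each curve contributes the maximal y it attains at that x, and the spread
is the population SD across curves.

Mutation analysis (`mutation_delta_stats()`) reports differences of
medians and raw KS p-values; no multiple-testing correction is applied to
the primary columns (matching the emulated analysis), but
Benjamini–Hochberg columns are appended because users will want them. The
recurrence filter (≥ 12 mutant lines) is applied after intersecting the
score, response and mutation cohorts, with dropped-sample counts messaged.

## 4. Synergy

`fit_median_effect()` fits the median-effect linearization
log(fa/(1−fa)) = m·log D − m·log Dm by least squares; points with fa at 0
or 1 are outside the model's support and excluded with a warning; a
non-positive fitted slope is an error, not a silent nonsense fit.
`combination_index()` uses the two-term (mutually exclusive) CI without a
cross-term — the default of the standard software for constant-ratio
designs — and enforces the constant-ratio precondition. Verdicts use an
additivity tolerance `tol = 0.05` around CI = 1, below the one-decimal
resolution at which CI values are customarily reported. The analytic
identity that a sham self-combination gives CI ≡ 1 at every effect level
is the module's golden test.

## 5. The synthetic-data generator

The generator exists so that every claim the package makes is testable
against planted ground truth.

`simulate_screen()` models guide counts as negative binomial
(`dispersion = 0.2`) around lognormal baselines (`depth = 400` mean
reads/guide, sdlog 0.5) — the standard generative caricature of pooled
screen counts. Defaults mirror the emulated screen's shape at desk scale:
500 genes × 10 guides + 100 non-targeting controls (the real library is
~3733 genes; 500 keeps the default suite fast while leaving guide-level
statistics realistic), 3 control + 3 treated replicates plus a day-0
sample, 5% planted depleted and 5% enriched genes at ±2 log2 units of
fitness effect. The in vivo arm passes counts through guide-level
Bernoulli dropout, independent per tumor, calibrated numerically so an
untreated tumor's expected detectable fraction (count ≥ 1) matches the
0.64 observed in the emulated screen's tumors; day-0 cells are
pre-injection and never pass the bottleneck.

`simulate_expression_response()` draws centered-log expression deviations
as standard normal, defines latent sensitivity as the viability-weighted
sum over a causal gene set (the 50 most depleted + 50 most enriched scored
genes by default), standardized to unit SD, plus Gaussian noise
(`noise_sd = 0.25` by default — noise at a quarter of the signal SD, a
regime where a correct model should dominate), and sets
log IC50 = −sensitivity. A planted mutation shifts carriers' sensitivity
by `mutation_shift` signal-SD units *through their causal-gene
expression* (a gradient step δ·C_g/ΣC²): a shift injected only into the
latent variable would be invisible to any expression-based score, so
modeling it as expression-mediated is what makes the genotype analysis
testable — and is also how a real expression-mediated driver mutation
would present.

What the generator does **not** emulate: correlated gene–gene expression
structure, batch effects, copy-number confounding of screen counts,
off-target guide activity, platform-specific expression distributions, or
any fitted resemblance to the deposited data of a particular screen.
Passing tests therefore demonstrate that the algorithms recover structure
they are designed for, at realistic noise — not that any particular
biological dataset will yield a given AUC.

## 6. Problem sizes and numerical conventions in the test suite

The default suite scores screens of 100–500 genes, cohorts of 120–400
samples, and permutation nulls of 100–1000 replicates; the benchmark
script uses a 4,000-gene × 400-sample cohort with 1,000 permutation
replicates. These sizes were chosen so each statistic operates in the
regime its approximations assume (e.g. ≥ 100 labeled samples per class
for AUC stability) while the whole suite stays interactive. Exact
expectations in tests come from closed forms or enumeration oracles;
stochastic expectations state explicit bands justified by the statistic's
sampling variance. All simulations take explicit seeds.

## 7. Known limitations

- DREBIC scores are ordinal within a cohort; they are not calibrated to
  absolute IC50 values, and cross-cohort comparison requires the frozen
  reference-cohort centering mode.
- Guide matching is exact; a mismatch-tolerant mode is out of scope, so
  heavily error-prone sequencing will undercount (visible in
  `match_fraction`).
- Normalization assumes a core of guides with nonzero counts in all
  samples; extreme in vivo bottlenecks can violate this, in which case the
  error message is the correct outcome rather than a silent fallback.
- The KS test's exact p-values require tie-free data; z-scored LFCs are
  effectively continuous, but heavily rounded input will silently shift to
  the asymptotic formula.
- The median-effect CI assumes mutually exclusive drug action and
  constant-ratio design; non-constant-ratio checkerboards need a different
  framework (Loewe/Bliss surfaces are out of scope).
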