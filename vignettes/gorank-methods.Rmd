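---
title: "Methods: scoring genes and ranking GO terms by classification power"
author: "gorank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring genes and ranking GO terms by classification power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gorank)
```

## The question the package answers

Given a normalised expression matrix (genes × samples), a factor that
partitions the samples into two or more predefined groups, and a flat
gene-to-GO-term annotation, `gorank` asks: *which functional classes of
genes best discriminate the groups?* It is a functional class scoring (FCS)
workflow, not an over-representation test: every measured gene gets a
continuous score for its classification power, and a term's statistic is an
aggregate over **all** of its annotated genes, measured or not. No gene list
or significance cut-off is chosen upstream.

The workflow is:

1. **Score** each measured gene (random-forest Gini importance, or the
   one-way ANOVA F ratio).
2. **Rank** all genes of the annotation universe by descending score.
3. **Summarise** each term by the mean rank (or mean score) of its genes.
4. **Permute** the ranking table to attach an empirical P-value per term.
5. **Filter, export, plot.**

## Input assumptions

The expression matrix is used exactly as supplied: the package never
transforms, normalises or imputes expression values. It therefore expects a
complete, finite matrix on whatever scale the upstream pipeline produced
(typically log2 intensities or log2 CPM); missing values are a load-time
error. Factor levels are compared as whitespace-trimmed strings, so numeric
time points act as categorical groups — their continuity only matters in
the plotting functions, where an all-numeric factor is drawn on a numeric
axis.

Annotations arrive as three tables: a `(gene_id, term_id)` mapping, gene
metadata, and term metadata (name, GO namespace). The mapping is expected to
include genes absent from the expression data, so that the full set of
annotated genes — not just the measured ones — forms the background.
Features are kept as supplied (probeset-level if the platform is
probeset-based); no collapsing of multiple features per gene is attempted,
because the scoring is feature-wise and collapsing is an upstream decision.

## Gene scores

**Random forest (default).** A classifier of the sample groups is trained
on all genes simultaneously (`randomForest`, `ntree = 1000` trees,
`mtry = floor(sqrt(P))` candidate genes per split, both recorded in the
result). The score of gene *g* is its mean decrease in Gini impurity: the
total impurity reduction achieved by splits on *g*, averaged over the
forest. The forest sees all groups at once, so the score captures
multi-group discrimination without specifying contrasts, and is insensitive
to monotone transforms of single genes. The forest seed is a required,
recorded parameter (default 0), making scores bitwise reproducible. Note
that Gini importances of uninformative genes are not exactly zero — they
fluctuate with the forest — so the *order* among near-zero genes is noisy
across seeds even though the informative genes stay firmly at the top;
1000 trees keeps that fluctuation small relative to real signal at the
sample sizes below.

**One-way ANOVA (alternative).** For k groups and n samples,
`F = (SSB / (k - 1)) / (SSW / (n - k))`, computed in closed form for all
genes at once. A gene with identical within-group values but distinct group
means has infinite F; to keep the ranking total such scores are capped at
ten times the largest finite F and the affected genes are flagged. A
constant gene has F = 0 by convention. The parametric F assumes roughly
equal-variance Gaussian noise; the random forest does not, which is why it
is the default.

Both scorers refuse single-level factors and levels with fewer than two
samples, and warn below five replicates per level — with fewer, both the
impurity estimates and the within-group variances are too unstable to rank
on.

## Ranking and the absent-gene penalty

Measured genes are ranked by descending score with *fractional (average)
ranks* for ties, so the N measured ranks always sum to N(N+1)/2 and no
arbitrary tie order leaks into the results. Every annotated gene absent
from the data is appended with score 0 and the single shared rank N + 1 —
the worst rank that preserves continuity. Measured genes without any
annotation stay in the table: they compete for ranks like any other gene.

The penalty is the deliberate heart of the term statistic: a term whose
annotation is largely unmeasured (filtered out upstream, or simply not on
the platform) is dragged towards the bottom, so the ranking implicitly
favours terms well covered by informative data. The best average rank a
term with m genes can reach is (m + 1) / 2 — 3 for a five-gene term — and
the worst is N + 1; both bounds are asserted on every table construction.
Because small terms can reach better averages and are more exposed to
single-gene flukes, term lists are normally filtered on a minimum annotated
count (15 is a common report threshold) before interpretation.

## Permutation P-values

The null asks: *how good an average rank would this term reach if the
ranking carried no information about its genes?* For each of B permutations
(default 1000) the (score, rank) label pairs are shuffled jointly across
the gene universe and every term's statistic is recomputed; the P-value is
the proportion of permutations with a statistic at least as good as
observed. P-values are reported unadjusted: the term statistics share one
competitive ranking and are strongly dependent, so familywise or FDR
control over them has no clean interpretation — the P-value is a
per-term probability statement, not a discovery-rate device.

Implementation notes, which matter for exactness and testability:

* Under the exchangeable null, a term's permuted statistic depends only on
  how many of its labels circulate. Each permutation therefore shuffles the
  label pool once and evaluates one statistic per term-size class from a
  prefix of the shuffled pool (a cumulative sum gives every prefix mean in
  one pass). Equal-size terms thus face the *identical* permuted stream, so
  a term with a better observed statistic can never receive a larger
  P-value than an equal-size term — a property that per-term independent
  draws only satisfy in expectation.
* By default the absent genes' 0 / N+1 labels circulate too
  (`scope = "universe"`). A direct consequence: for a term made entirely of
  measured genes, the permuted statistic is stochastically *worse* than its
  observed null distribution whenever the universe extends beyond the data,
  so its P-values run small. That asymmetry is the absent-gene penalty
  expressed in the null, not a bug; `scope = "present"`, which shuffles
  only measured labels, gives exactly calibrated P-values for
  fully-measured terms and is the right choice when the universe and the
  data coincide in interpretation.
* Comparisons use a small absolute tolerance (1e-9 on the rank scale) so a
  term annotated with the entire universe — whose statistic is permutation
  invariant up to floating-point summation order — gets P = 1 exactly.
* The plain proportion count/B can be zero; an optional
  (count + 1) / (B + 1) estimator is available when strictly positive
  P-values are needed. The permutation seed is separate from the scoring
  seed and both are recorded.

Custom aggregation functions (e.g. `median`, or a trimmed mean) can replace
the mean in both summarisation and permutation; the mean-specific bound
checks are then skipped, and the permutation falls back to evaluating the
function per size class rather than using prefix sums.

## Filtering, export, reproducibility

`subset_scores()` filters the term table on namespace, minimum annotated
genes, minimum measured genes and maximum P-value, conjunctively. The
threshold on *annotated* genes is the default interpretation of a
minimum-size filter (the measured-gene threshold is offered separately)
because term size in the annotation is what drives the small-term
artefacts described above. Filtering happens strictly after the permutation
stage and never recomputes P-values — recomputing on a filtered universe
would silently change the null. Original statistics are preserved; the
filtered table only adds 1..M positions, and the applied criteria join the
parameter record.

Every result directory carries `gene_table.tsv`, `term_table.tsv` and a
`parameters.yaml` with the factor, sample subset, method, hyperparameters,
aggregation, seeds, permutation settings and filters. Floating point is
serialised with 17 significant digits, so a written result re-reads
bit-for-bit and re-running any stage with the same recorded parameters
reproduces the files byte-identically. The `gorank` executable exposes the
same stages as subcommands (`simulate`, `analyse`, `pvalue`, `filter`,
`genes`, `plot`, `heatmap`).

## Visualisation choices

`expression_plot()` draws group means against an ordered factor with a
mean ± standard error band (the band is labelled in the plot; where a cell
has one sample the SE is undefined and the band is omitted).
`expression_profiles()` draws unaggregated per-series polylines.
`heatmap_go()` clusters the term's measured genes and the samples with
Euclidean distance and average linkage — both configurable — and returns
the dendrogram leaf orders, so downstream checks can assert on the
clustering rather than on rendered pixels; the plot-data TSV exports serve
the same purpose for the line plots. None of the plotting functions modify
the expression matrix.

## The synthetic-data generator

`sim_config()` defaults describe a designed multi-group experiment at desk
scale: 3 groups × 5 biological replicates (five replicates being the
working minimum for stable forest scores), 1000 measured genes with unit
Gaussian noise on the log scale, one planted 10-gene term whose genes step
their group means by 2 standard deviations per group, 200 ten-gene null
terms drawn from the background, and 100 annotated-but-unmeasured genes
grouped into their own background terms. A negative-binomial mode
(`model = "nb"`) produces log2-CPM-like fixtures for count data.

What it deliberately does not emulate: gene–gene correlation (real
co-expression makes term statistics more variable than independent noise),
probe-level artefacts, batch effects, library-size pathologies, or
annotation bias. Passing the recovery and calibration tests therefore shows
the machinery is correct under its stated model, not that any particular
biological dataset will yield stable term lists.

The test suite uses these sizes throughout: recovery and calibration runs
use the default 3 × 5 × 1000 configuration (20 independent replicates for
recovery; 200 null terms for calibration with B = 1000), oracle
equivalence uses 1000 genes against per-gene `anova(lm())` fits, and the
exhaustive permutation check uses a 7-gene universe where all C(7,3) = 35
null assignments can be enumerated. Calibration is checked with no
unmeasured annotated genes, where the permutation null and the sampling
distribution of a measured term's statistic coincide exactly (see the
scope discussion above).

## Known limitations

* Flat annotations only: terms are taken as given, with no propagation of
  genes to ancestor terms and no use of the ontology graph.
* Gini importance inherits the known biases of impurity-based measures
  (e.g. towards features with more split points); within one expression
  matrix on a common scale this is mild, but scores should not be compared
  across platforms.
* Term P-values are comparable within a run, not across runs with
  different universes — changing the annotation changes the null.
* The permutation null treats genes as exchangeable; correlated gene sets
  violate this, and their P-values should be read as descriptive rather
  than strictly frequentist.
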