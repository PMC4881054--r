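---
title: "Methods: rank-based gene scoring, process essentiality and drug prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based gene scoring, process essentiality and drug prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goprio)
```

## The problem

Tumors accumulate molecular alterations — point mutations, copy-number
changes, expression shifts — and many of those alterations hit proteins
that existing drugs already target. The question this package addresses
is: given (a) a heterogeneous body of prior evidence about which genes
matter in cancer, and (b) the molecular profile of a new cohort of tumor
samples, which drugs should be prioritized for that cohort, and which
samples are likely to respond?

The prior evidence is heterogeneous by nature: differential-expression
analyses, copy-number frequency screens, survival associations, curated
cancer-gene lists. These disagree in units, scale and coverage, so the
package stores each source as a **study**: a ranked gene list in which
rank 1 is the strongest evidence. Ranks are the only statistic carried
forward; this makes sources commensurable and avoids the bias toward
well-studied genes that citation-weighted or magnitude-weighted scores
suffer from.

## The scoring pipeline

### Step 1 — K-ranks

Studies are grouped into **study sets** sharing an interpretation (the
defaults are `activating`, `inactivating`, `survival`). Within a set
$S$, a gene $g$ ranked $r_{gs}$ of $N_s$ in study $s$ contributes the
normalized score

$$u_{gs} = \frac{N_s - r_{gs} + 1}{N_s} \in (0, 1],$$

and its **K-rank** is

$$K_g = \frac{1}{|S|} \sum_{s \in S_g} u_{gs},$$

where $S_g \subseteq S$ are the studies that rank $g$. Dividing by the
full set size $|S|$ rather than $|S_g|$ is deliberate: a gene that
recurs across studies outscores a gene seen once, which encodes the
reproducibility of evidence directly into the score. The alternative
(mean over supporting studies only) is available as
`krank_denominator = "support"` for users who consider absence from a
study uninformative. Genes absent from *every* study of the set get no
K-rank at all: failing a study's inclusion criteria is not the same as
ranking last.

Two properties follow immediately and are enforced by tests: $K_g \in
(0, 1]$ with 1 attained exactly by a gene ranked first everywhere, and
invariance of all downstream results under strictly monotone,
sign-preserving transforms of the statistics that produced the ranks.

### Step 2 — process essentiality

Genes are tied to Gene Ontology biological processes through regulation
triples (gene, process, direction). A process $P$ with regulator set
$R(P)$ (positive and negative regulators pooled) receives the score

$$T_P = \sum_{g \in R(P),\, g \text{ scored}} K_g.$$

Significance is assessed with a size-matched gene-sampling null: draw
$B$ random gene sets of size $n_P = |\{g \in R(P): g \text{ scored}\}|$
from the K-ranked gene universe, sum their K-ranks, and report

$$p_P = \frac{b + 1}{B + 1}, \qquad
  b = \#\{ \text{permuted sums} \ge T_P \}.$$

The add-one pseudocount keeps $p_P \ge 1/(B+1) > 0$, which the
harmonic mean in step 3 requires. The null is the standard construction
for sum-score gene-set statistics: it asks whether these particular
regulators score higher than a random gene set of the same size, so
process size itself is not rewarded. Pooling the two regulation
directions into one regulator set is the default because downstream
recalibration consumes a single p-value per process; direction-split
scoring would double the testing burden without a consumer for the
second value.

### Step 3 — recalibration

A gene's final relevance score is computed from the processes it
regulates, not from its K-rank directly: for the set $U_g$ of processes
the gene regulates in exactly one direction (processes annotated in
both directions for the same gene are ambiguous and excluded),

$$H_g = \frac{|U_g|}{\sum_{P \in U_g} 1/p_P}, \qquad
  \text{score}_g = -\log_{10} H_g.$$

The harmonic mean has the property this step exists for: it is
independent of $|U_g|$ when the p-values are equal, so a gene annotated
to 200 generic, high-level processes gains nothing over a gene
annotated to 2 equally significant ones. Highly connected GO terms
therefore cannot dominate the drug ranking. The bounds
$\min p \le H \le \max p$ and the count-independence identity are
asserted exactly in the test suite.

### The activity matrix

The query cohort enters as up to three gene-by-sample evidence layers:
expression status (`up`/`down`/`unchanged`), copy-number status
(`amplified`/`deleted`/`neutral`) and mutation calls
(`activating`/`inactivating`/`none`), any of which may be `missing`.
They are fused into one ternary status per cell by fixed precedence:

1. mutation calls win outright;
2. otherwise an altered copy-number state wins — including over
   conflicting expression;
3. otherwise expression decides;
4. otherwise `unchanged`.

Expression is thus the *preferred* evidence in the common case (layers
2 and 1 silent), while genomic alterations override it when present,
because they are more stable and reproducible across cohorts and hence
better biomarkers. Placing mutation above copy number is the one
genuinely open ordering decision: a point mutation is the most direct
evidence about the protein itself, and the whole table lives in one
place (`build_activity_matrix()`) so the 64-state truth table — which
the tests enumerate exhaustively — can be diffed or overridden. A
`missing` layer defers to the next rule rather than forcing
`unchanged`, so single-layer cohorts remain usable.

For continuous expression input, per-gene robust z-scores
($z = (x - \mathrm{median})/(1.4826 \cdot \mathrm{MAD})$, cut at
$|z| \ge 2$) are the default discretization; when MAD degenerates to
zero (a majority of identical values) a mean / population-sd z-score is
the fallback before a gene is declared flat. A quantile method
(`q = 0.1` tails) is the alternative. The thresholds are configurable
and deliberately conservative: a 2-robust-sd excursion, not a fold
change, since cohort-internal standardization is all that is available
for rank-heterogeneous sources.

### Step 4 — drug scores and stratification

For drug $d$ with known target set $G_d$, the eligible altered targets
$A_d$ are the targets that have a recalibrated score, appear altered in
the activity matrix, and hold the status the drug's mode of action
requires (`active` for inhibitors and for drugs of unknown action —
inhibitor semantics dominate drug-target databases — `inactive` for
activators) in at least one sample. With $f_g$ the fraction of samples
in the required status,

$$D_d = \frac{1}{|G_d|} \sum_{g \in A_d} \text{score}_g \cdot f_g .$$

This is the minimal form that balances the three stated criteria:
dividing by the *total* target count penalizes diffuse
polypharmacology; $\text{score}_g$ carries knowledge-base relevance;
$f_g$ carries measured activity in the cohort. The variant that divides
by $|A_d|$ instead is one switch away (`drug_score =
"per_altered_targets"`); neither is claimed to be uniquely right, which
is why the formula is isolated in one function and cross-checked
against a brute-force oracle in the tests. Drugs with $A_d = \emptyset$
are omitted rather than scored 0 — a drug whose targets are unmeasured
is not evidence against the drug. Ties break by more altered targets,
then lexicographic drug id, so rankings are fully deterministic.

A drug's **sensitive samples** are the union over $g \in A_d$ of the
samples holding the required status; `render_stratification()` lays
drugs, genes and clinical annotations out as a categorical
(oncoprint-style) matrix with a stable sample order.

## The synthetic fixture

Because the real inputs (tumor cohorts, drug-target databases, GO
snapshots) cannot be bundled, `fixture_spec()` generates a
self-contained stand-in that emulates their statistical structure: 3
study sets × 3 studies ranking 100 genes; 10 planted genes drawing
top-decile ranks in every study; 20 processes of which the planted one
is regulated exactly by the planted genes; 10 drugs of which the
planted one (an inhibitor) targets planted genes; and a 50-sample
cohort in which planted genes are made active-consistent (expression
up and/or amplification) in 40 % of samples — a fraction chosen to
match the sensitive-sample fractions reported for real breast-cancer
cohorts — over a 2 % per-cell noise floor of uniform status flips.
Background processes draw regulators from background genes so that
planted-signal recovery is cleanly separable at this scale.

What the fixture does *not* emulate: real marginal distributions of
expression or copy number, batch effects, correlated gene modules, the
GO hierarchy (triples are flat), or survival endpoints. Passing the
planted-recovery tests therefore demonstrates that the pipeline
propagates a known signal through all four stages and ranks it first
under realistic noise — not that it reproduces any particular biological
result on real cohorts.

`plant_signal = FALSE` produces the matched negative control: planted
genes get background ranks *and* background activation, so the planted
drug should rank uniformly among eligible drugs. Keeping the activation
while removing only the rank signal would not be a null — the
activation fraction alone would carry the drug to the top.

## Numerical and reproducibility choices

- Permutation p-values use the $(b+1)/(B+1)$ pseudocount; $B = 10000$
  by default, $B = 2000$ in the fixture-scale validation runs. A seed
  is mandatory wherever permutations are drawn; `score_all_processes()`
  visits processes in lexicographic id order on one seeded stream, so
  results are bit-reproducible.
- Permuted sums are compared with the observed sum using a relative
  tolerance of $10^{-9}$ so that ties survive summation-order rounding
  (the all-equal-K-ranks universe must give $p = 1$ exactly).
- Tied or gapped curated ranks are densified by stable sort (input
  rank, then gene id) to restore the permutation invariant; sources
  that count rank $N$ as strongest are flipped at load with a per-study
  flag.
- Benjamini–Yekutieli adjustment (study inclusion at $q \le 0.001$)
  is delegated to `stats::p.adjust(method = "BY")` and cross-checked
  against a hand-written step-up implementation to $10^{-12}$ in the
  tests. Survivors are ranked by descending $|$effect$|$, ties by
  ascending raw p then gene id.
- The test suite and validation scripts run the planted-recovery study
  at 100 seeds × (20 processes × 2000 permutations), which completes in
  roughly two minutes on one core; exhaustive enumeration oracles are
  kept to universes of ≤ 12 genes and regulator sets of ≤ 4 where
  $\binom{12}{4} = 495$ subsets are enumerable instantly.

## Known limitations

- The K-rank treats all studies in a set as exchangeable; there is no
  weighting by sample size or source quality.
- Regulation triples are used as given: no propagation up the GO
  hierarchy, and the OBO-based deriver only resolves terms named
  "positive/negative regulation of X" by exact name match.
- Classifying mutations as activating or inactivating is the caller's
  responsibility (e.g. from a cancer gene census class); the package
  performs no variant-effect prediction.
- Drug scoring ignores binding affinity, drug combinations and
  synthetic lethality; process p-values are nominal and used only for
  ranking, never corrected for multiple testing.

## A worked example

```{r example, fig.width = 7, fig.height = 4}
spec <- fixture_spec(seed = 42)
kb <- generate_knowledge_base(spec)
query <- generate_query_dataset(spec)
fit <- goprio(kb, query, study_set = "activating", B = 2000, seed = 42)
fit
summary(fit, n = 5)
plot(fit, drugs = fit$drugs$drug_id[1])
```
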