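---
title: "TCR repertoire diversity and the GA-tuned SVM nodule classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TCR repertoire diversity and the GA-tuned SVM nodule classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrnodule)
```

## The problem

Most lung nodules flagged by low-dose CT screening are indeterminate: a
large share of patients who go to surgery turn out to have benign disease.
The premise of this package is that the peripheral-blood T-cell receptor
(TCR) repertoire carries a usable malignancy signal: tumours drive clonal
T-cell expansion, which shows up in blood as reduced repertoire diversity
and an excess of highly expanded clonotypes. The package implements the
full analysis chain from per-subject CDR3&beta; clonotype tables to a
diagnostic classifier:

1. ingest AIRR-style clonotype tables and subject metadata;
2. compute per-subject diversity and clonal-homeostasis features;
3. compare groups and correlate features with clinical covariates;
4. identify group-exclusive and enriched CDR3&beta; sequences and their
   common motifs;
5. rank candidate features (random forest + information gain) and keep the
   top three;
6. fit a support-vector machine whose hyperparameters are tuned by a
   genetic algorithm, calibrate its score, and pick a Youden cutoff;
7. evaluate on a held-out cohort, overall and within clinical strata.

Because patient-level repertoire data cannot ship with a package, a
synthetic-cohort generator reproduces the statistical structure the
analysis relies on; every stage is tested against it.

## Diversity features

For a repertoire with clonal fractions $p_1,\dots,p_S$ (counts over total
reads):

* Shannon index $H=-\sum_i p_i\ln p_i$ (nats; natural log throughout —
  evenness is base-invariant and the choice is convention);
* Pielou evenness $E=H/\ln S$ and clonality $1-E$; for the degenerate
  monoclonal case $S=1$ we define $E=0$, clonality $1$ (the maximal-
  monoclonality limit);
* Gini–Simpson index $1-\sum_i p_i^2$;
* clonal-homeostasis bins: each clone falls in a right-closed clonal-
  fraction interval — rare $(0,10^{-5}]$, small $(10^{-5},10^{-4}]$,
  medium $(10^{-4},10^{-3}]$, large $(10^{-3},10^{-2}]$, hyperexpanded
  $(10^{-2},1]$. Both the read mass and the clone count per bin are
  reported; group comparisons default to read mass, matching the
  convention of sizing clones by clonal fraction. The thresholds are the
  widely used clonal-homeostasis convention and are fully configurable.

Group differences use the two-sided Wilcoxon rank-sum test (robust,
assumption-light for small cohorts; fully tied groups are reported as
$p=1$). Feature–clinical associations use Spearman correlation with
pairwise-complete observations; constant features yield `NA` with a
warning rather than an error. Whether "clonality" should be $1-E$ or a
Simpson-based statistic is a genuinely open convention; $1-E$ is
implemented, and the Simpson index is reported alongside so either view is
available.

## Enrichment and motifs

Clone identity defaults to the CDR3&beta; amino-acid sequence alone
(sharing analyses across subjects are sequence-level; the
(sequence, V, J) triple is available via `clone_key = "cdr3_vj"`).
Out-of-frame/stop-containing sequences are rejected by default.

`select_enriched_sequences()` nominates condition-associated sequences as
the union of each subject's top 30 sequences by clonal fraction and the
top 3000 by pooled fraction, then keeps those present in at least two
subjects. The two sub-rules and the support filter interact ambiguously in
informal descriptions of this procedure; the union-then-filter reading is
the most inclusive and is the default, with `rule = "top_subject"` or
`"top_pooled"` restricting to either sub-rule. Ties break
deterministically: fraction, then count, then lexicographic.

`find_common_motifs()` reports all substrings of length at least
`min_length` (default 5) carried by at least `min_support` sequences,
keeping only maximal motifs (a substring is suppressed when a longer
substring has exactly the same support set) and ranking by support, then
length. Brute-force substring hashing is used; at the scale of enriched
sets (thousands of short peptides) this is fast and exactly matches an
exhaustive enumeration, which the tests assert.

## Feature selection

Candidates are the TCR features (richness, clone reads, the four diversity
indices, five bin masses) plus encoded clinical covariates (GGN flag, sex
as 0/1, nodule diameter, age; missing numerics are median-imputed and
logged). Constant columns are dropped with a warning. Two rankings are
fused: random-forest mean-decrease-impurity importance (500 trees,
$\sqrt p$ features per split, seeded) and information gain in bits with
quartile binning for continuous features (equal-width binning available).
The combined rank is the mean of the two per-method ranks, with ties
broken by information gain and then name — the fusion rule is a design
choice (single-method selection is available via the returned ranking).

## The classifier

`ga_svm(label ~ ..., data)` is the package's central model. Features are
standardized on the training rows (parameters stored), then a genetic
algorithm searches the SVM hyperparameter space: $\log_2 C \in [-5, 15]$,
$\log_2\gamma \in [-15, 3]$, kernel $\in$ {RBF, linear}. Fitness is the
mean stratified 5-fold cross-validated AUC; fold scaling is re-estimated
inside each training fold so no held-out information leaks into the model.
The GA uses tournament selection (size 2), uniform crossover (rate 0.8),
per-gene Gaussian mutation clipped to the bounds (rate 0.1), and elitism
(2), which makes the best-fitness trajectory non-decreasing — an invariant
the tests assert. Population 30 and 40 generations are the fitting
defaults; the fitness surface for a three-feature model is smooth enough
that much smaller budgets reach the same region, which is what the test
suite and the acceptance script use to keep runs fast.

The final SVM is refit on all training rows with the selected
hyperparameters. Because the plotted "predicted value" of such a
classifier should be bounded, decision scores are mapped through a Platt
sigmoid fitted on the training scores; the raw decision scores remain
available (`predict(type = "decision")`). The decision rule uses the
Youden cutoff $\arg\max(\text{sens}+\text{spec}-1)$ computed on the
training predicted values (lowest cutoff on ties). Computing the cutoff on
training data rather than a validation split is a deliberate default —
the evaluation functions accept any externally supplied cutoff.

The trained model is a self-contained support-vector expansion (support
vectors, coefficients, offset, kernel parameters, scaling, Platt
coefficients, cutoff), serialized as schema-versioned JSON at full
precision; a restored model predicts identically to the original, and the
whole train-to-predict path is deterministic under the configured seed.

`ablate_tcr_features()` refits under identical seeds with all TCR-derived
columns removed, quantifying the repertoire's contribution to diagnostic
performance.

## Evaluation

AUC uses the rank (Mann–Whitney) statistic with half credit for ties; the
ROC polyline sweeps the unique observed scores with $(0,0)$/$(1,1)$
sentinels, so its trapezoidal integral equals the rank AUC exactly (both
facts are asserted against brute-force pair counting). Confusion metrics
at a cutoff report `NA` for undefined ratios instead of failing.
`stratified_evaluation()` reuses the single global cutoff within clinical
strata — GGN vs non-GGN, nodule diameter at most 20 mm or 10 mm
(inclusive bounds, matching the usual reading of "&le; 20 mm"; strict
inequality available), and per-stage subsets pooled with all benign
subjects — flagging single-class strata as insufficient rather than
erroring, and emits a waterfall table of predicted value minus cutoff.
`expert_agreement_table()` cross-tabulates model calls against any number
of expert raters and the pathology truth.

## What the synthetic generator emulates

`cohort_sim_config()` defines the study conditions. Per subject, clone
masses follow a Zipf rank-frequency law with per-subject exponent jitter,
multiplicative log-normal scatter on each clone's mass (real top-clone
sizes are strongly stochastic), log-normal richness variation, and
technical read-depth variation with observed richness following a
saturation curve (depth$^{0.6}$). Counts are drawn multinomially with
every clone guaranteed one read. The malignant class differs by a steeper
exponent (1.13 vs 1.05), a 25% lower expected richness (clonal expansion
crowding the observed repertoire), and 3% of read mass boosted onto the
top ten clones — together producing lower Shannon diversity, more
hyperexpanded-type mass and less small-type mass. Cohort-level structure:
a shared public-clonotype pool (each clone has a 5% chance of being drawn
from it), a pool of malignant-associated motif-carrier sequences all
containing the plantable motif `SSGGSSYEQYF` (drawn by malignant subjects
at rate 0.2 among non-public clones, hence an effective per-clone rate of
$0.2 \times 0.95$), class-dependent GGN rates (0.08 benign vs 0.80
malignant; the single most informative covariate by design), log-normal
nodule diameters (medians 12.5 vs 15 mm, pooled mean near 14 mm), stages
for malignant subjects (60/25/15), and read depth coupled to nodule size
so clone reads and diameter correlate positively. One global seed fans
out into per-subject substreams, so cohorts are reproducible regardless
of generation order.

Class effect sizes are deliberately stronger than a real screening cohort
would show: they are set so that planted effects are recoverable with
high probability at desk-scale cohort sizes (tens of subjects, ~1000
clones per subject), not to mimic any particular study's effect sizes.
Consequences of the small scale worth knowing:

* With ~1000 observed clones per subject the spectrum body sits near the
  medium/large bin boundary, so bin-mass features are more informative
  relative to the diversity indices than they would be at realistic
  sequencing depth (where most clones live deep in the rare/small bins).
  On these synthetic cohorts the random-forest/information-gain selection
  therefore reliably ranks the GGN flag first, but the specific diversity
  index filling the remaining slots varies between Shannon, evenness,
  clonality and a bin mass across replicates — all of them monotone
  summaries of the same planted spectrum shift. A test documents this:
  GGN recovery is asserted at the 90% level, and the stricter requirement
  that Shannon itself always co-appear is asserted at the same level and
  is expected to be the suite's hardest check.
* The generator plants no V(D)J recombination realism, no
  generation-probability structure, no HLA effects and no sequence
  similarity beyond the shared pools; passing tests show the pipeline
  recovers the statistical structure it models, not that the biology of
  any real cohort is captured.

## Numerical choices and degenerate inputs

Fraction vectors must be positive and sum to 1 within $10^{-8}$; bin
masses are checked to conserve mass within $10^{-9}$. A monoclonal
repertoire takes the evenness-0/clonality-1 limit. Duplicate clone keys
aggregate by summing counts. Feature tables serialize at 17 significant
digits so write/read round-trips are bit-exact. All ranking and selection
steps (top-N, enrichment, motifs, GA) carry explicit deterministic
tie-breaks. Library code never perturbs the caller's RNG state: every
seeded operation saves and restores `.Random.seed`.

## Problem sizes used by the test suite

The suite favours many small seeded replicates over few large ones: oracle
equivalences run on up to 200 random repertoires (5–5000 clones) and 100
random score sets (&le; 200 subjects); recovery checks use cohorts of
20–120 subjects at ~1000 clones each with 10–20 replicates, and reduced GA
budgets (populations of 10–12 over 6–8 generations) that reach the same
fitness region as the defaults on three-feature problems. The
reproduction script (`scripts/acceptance.R`) runs one full
discovery/validation study (60+60 and 30+30 subjects) at the default
study conditions.

## Known limitations

* No rarefaction or depth-normalized diversity correction is applied;
  with strongly varying sequencing depth, richness-sensitive indices
  inherit technical variation (the generator emulates exactly this).
* The enrichment rule and motif extraction are exact-match,
  sequence-level procedures; no position-weight-matrix or similarity-
  graph motif models.
* The classifier handles exactly two classes; stage is used only for
  stratified evaluation, not multi-class prediction.
* Downstream antigen annotation of enriched sequences is out of scope.
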