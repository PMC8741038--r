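---
title: "Statistical methods in comutkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in comutkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comutkit)
```

# Scope

comutkit implements the integrative statistics used to dissect the genetic
relationship between two recurrently mutated cancer genes — the motivating
case is a tumor suppressor (TP53) and a chromatin remodeler (ARID1A) in
endometrial carcinoma — across several layers of evidence:

1. **Mutual-exclusivity / co-occurrence screens** on binary alteration
   matrices (Fisher's exact test, stratified by tumor type, histology or
   molecular subtype).
2. **Keyword-pathway activation**: a permutation test asking whether a
   named family of pathways (e.g. all "p53" pathways of a pathway-activity
   compendium) is jointly more activated in mutant than wild-type tumors.
3. **Cross-comparison enrichment concordance** between two GSEA-style
   normalized-enrichment-score (NES) tables, e.g. a human tumor contrast
   versus a mouse model contrast.
4. **N-gram term over-representation** on gene-set names, summarizing what
   a list of enriched sets is "about".
5. **Gene-list overlap enrichment** and **peak-to-TSS promoter
   annotation** connecting differential expression to chromatin binding.

Upstream inference — differential-expression model fitting, GSEA itself,
pathway-activity inference, peak calling — is out of scope; their output
tables are inputs here. A synthetic-data module generates inputs with
planted truth for every stage, so the full pipeline is testable without any
external download.

# Alteration matrices and the exact test

A sample is *altered* for a gene if it carries at least one retained
mutation (the variant-class vocabulary is configurable; the default
non-silent set is `non_silent_classes()`) or a GISTIC copy-number call with
`|level| >= cna_threshold`. The default threshold of 2 counts only deep
deletions and high-level amplifications; shallow events are noisier calls
and inflate alteration rates if admitted. For two genes in a stratum of
$n$ samples the 2x2 table $(a, b, c, d)$ counts both-altered, A-only,
B-only, neither.

`fisher_exact()` reports:

* the exact p-value over the hypergeometric distribution with fixed
  margins; the two-tailed value follows the **probability-mass rule** (sum
  of the probabilities of all tables at most as probable as the observed
  one), the convention of the major statistical environments, rather than
  doubling the one-sided tail;
* the **conditional maximum-likelihood odds ratio**: the maximizer
  $\hat\psi$ of the noncentral hypergeometric likelihood of $a$ given the
  margins. The score equation $E_\psi[X] = a$ has a monotone left side and
  is solved on the log scale to tolerance $10^{-12}$ — substantially
  tighter than the estimate printed by common exact-test routines, which
  matters when validating against brute-force likelihood maximization.
  Boundary tables ($a$ at the support edge) return 0 or $\infty$ with no
  continuity correction;
* the sample (cross-product) odds ratio $ad/bc$, optionally with the
  Haldane–Anscombe $+0.5$ correction.

Mutual exclusivity corresponds to OR $< 1$; co-occurrence to OR $> 1$.
Stratified screens (`screen_strata()`) report raw per-stratum p-values
with conventional significance stars and apply no cross-strata
multiplicity correction: the strata are a small, fixed set of biological
subgroups reported side by side, not a discovery scan.

# The random-pathway-subset permutation test

Given a pathway-by-sample activity matrix and a mutant/wild-type labelling,
the per-pathway statistic is the group mean difference
$\Delta_j = \bar s_{j,\mathrm{mut}} - \bar s_{j,\mathrm{wt}}$. The test
statistic for a keyword family $S$ (selected by plain substring match on
display names, case-insensitive by default) is
$\bar\Delta_S = \frac{1}{|S|}\sum_{j \in S} \Delta_j$.

The null distribution is formed by drawing $B$ subsets of size $k = |S|$
uniformly **without replacement from the full pathway pool** and taking
each subset's mean $\Delta$. The keyword pathways remain in the pool (an
`exclude_keyword` flag provides the leave-out variant); with $k$ a tiny
fraction of the pool the two nulls are nearly identical, and including
them is the natural reading of "random pathways". Note the permutation is
over *pathway identity*, not sample labels: the question is whether the
keyword family is extreme among pathways, not whether the grouping matters
at all.

Two p-values are reported for an upper-tailed (activation) test:

* `p_uncorrected` $= \#\{b : \bar\Delta^{(b)} \ge \bar\Delta_S\}/B$ — the
  raw exceedance fraction, which can be exactly 0 and is the headline
  convention;
* `p_add_one` $= (\#+1)/(B+1)$ — the estimator that accounts for the
  observed statistic itself and is the statistically safer summary.

The default $B = 50{,}000$ and $k = 36$ match the scale of a genome-wide
pathway-activity compendium screen. A per-pathway Wilcoxon rank-sum screen
with Benjamini–Hochberg FDR (`pathway_wilcoxon_screen()`) complements the
set-level test. The rank-sum p-value is exact (full enumeration) for
combined $n \le 20$ without ties, and the tie/continuity-corrected normal
approximation otherwise; fully tied inputs carry no rank evidence and are
reported as $p = 1$.

# Enrichment concordance

Two NES tables are joined on set id (sets present in only one table are
dropped with a message, never imputed). A set is *enriched* when
$|\mathrm{NES}| > \tau$ with $\tau = 1$ by default and **strict**
inequality — a set at exactly the threshold is not enriched. Shared sets
fall into five exclusive quadrant classes (shared-up, shared-down,
discordant, one-sided, unenriched) whose counts always sum to the shared
count. Whether more sets are shared-up (or -down) than chance expects is
an upper-tail hypergeometric overlap of the two up (down) lists against
the shared-set universe; using all shared sets as the universe is the
default and the conservative choice. Pearson and Spearman correlations of
the NES vectors quantify global agreement.

`phi_coefficient()` gives the binary-variable Pearson correlation of a
2x2 classification with its $\chi^2_1$ p-value ($\chi^2 = n\phi^2$, no
continuity correction), and `compare_correlations_fisher_z()` compares two
correlation coefficients through $z = (\mathrm{atanh}\,r_1 -
\mathrm{atanh}\,r_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}$. That formula assumes
independent samples; the result carries the assumption explicitly because
the framework is sometimes applied to correlations computed on overlapping
data, where the p-value is only approximate.

# N-gram term over-representation

Set names are tokenized by stripping a collection prefix (`GO_`,
`HALLMARK_`, ...), splitting on underscores and lowercasing; terms are all
contiguous word runs of length 1–3 (words, doublets, triplets). For each
term, membership is counted per name (repeats within one name count
once), and the upper-tail hypergeometric p compares the term's frequency
among hit names to the universe. Defaults that matter:

* **No stop-word removal** — connective words remain because multi-word
  terms like "response to virus" depend on them.
* `min_term_count = 2` — a term present in a single universe name cannot
  be meaningfully enriched.
* **Joint BH across all n-gram orders.** Raw p-values are also emitted, so
  the uncorrected behaviour is reproducible.

Because every occurrence of a multi-word term is by construction also an
occurrence of each of its constituent sub-terms, the containment
invariant $K(\text{trigram}) \le K(\text{bigram}) \le K(\text{word})$
holds, and constituent terms *inherit* a planted term's signal. A
consequence worth knowing: a constituent that picks up even one accidental
extra hit occurrence can attain a smaller p than the full term. This is
the duplicate-term phenomenon (e.g. "to virus" alongside "response to
virus") that users of such frameworks curate manually; comutkit leaves
curation to the analyst. In validation, planted-*word* recovery is
therefore asserted as strict top rank, while planted-trigram recovery is
asserted as "outranked only by its own sub-terms".

# Overlap enrichment and promoter annotation

`hypergeom_overlap()` computes $P(X \ge k)$ for
$X \sim \mathrm{Hypergeom}(N, K, n)$ via the log-stable survival function.
There is **no default universe**: an overlap p-value is meaningless
without an explicit expressed-gene universe, so callers must pass one.
DE-overlap uses strict `fdr < 0.05` calls, and directional concordance is
the fraction of shared DE genes with same-sign log2 fold change (an exact
zero counts as discordant).

Peak-to-TSS annotation measures the absolute distance from each gene's
TSS (a point coordinate; 0-based, strand-irrelevant for the metric) to the
nearest peak **center** `floor((start + end)/2)`, the common annotation
convention; an edge-based metric would systematically shorten distances
for wide peaks. Conventional windows are $\pm 3$ kb (promoter-proximal)
and $< 50$ kb (relaxed). Nearest distances are found per chromosome by
sorted binary placement, validated in tests against a quadratic scan.

# The synthetic-data generators

Each generator plants its effect so downstream recovery is exact, with
deterministic (rounded) planted counts rather than binomial sampling —
sharper test surfaces at no loss of realism for validation purposes. All
generators are pure functions of (parameters, seed).

* `gen_alteration_matrix()` draws i.i.d. bivariate Bernoulli indicators
  whose cell probabilities are solved in closed form from the marginals
  and the target odds ratio $\theta$ (the admissible root of a quadratic),
  so the population OR is exactly $\theta$ — not a copula approximation.
  Default marginals of 30% reflect the alteration frequencies of major
  tumor-suppressor screens.
* `gen_pathway_scores()`: Normal(0, $\sigma$) noise everywhere; keyword
  pathways get mean shift $\delta$ in mutant samples. Gaussian noise is a
  modelling choice — real pathway-activity scores are heavier-tailed — so
  calibration results transfer qualitatively, not literally.
* `gen_paired_enrichment_tables()` plants exact quadrant counts with
  enriched magnitudes $1 + \mathrm{Exp}(\text{mean} = s)$ (strictly above
  the threshold) and unenriched NES $\sim U(-1, 1)$ (strictly below).
* `gen_paired_de_tables()` plants exact shared/unique DE lists and an
  exact count `round(concordant_fraction * n_shared)` of same-sign shared
  genes.
* `gen_setname_corpus()` needs a background occurrence rate for the
  planted term; the `background_rate` parameter (default 0.05) sets it,
  and the hit-name rate is `enrichment_factor` times it. The default
  vocabulary (`gene_set_vocab()`, ~400 distinct words) is deliberately
  large: real gene-set collections draw on thousands of distinct words,
  and a small vocabulary inflates accidental n-gram collisions enough to
  change the framework's ranking behaviour.
* `gen_peaks_tss()` lays TSSs on an even grid and places unbound peaks at
  inter-gene midpoints, which guarantees they are $\ge 2 d_\mathrm{prom}$
  from every TSS provided `genome_span >= 4 * d_prom * n_genes` (enforced).

# Numerical and validation choices

* Exact-test p-values are validated against exhaustive enumeration of the
  hypergeometric support for **every** table with total $\le 30$
  (tolerance $10^{-12}$); conditional-MLE ORs against dense grid search
  plus golden-section refinement of the conditional likelihood (log-OR
  agreement $10^{-4}$) on a seeded subsample of interior tables.
* Planted-OR recovery uses $n = 50{,}000$ samples,
  $\theta \in \{0.1, 0.155, 1, 4.6, 9\}$, five seeds each, asserting
  relative error below 10% on the OR scale (the log scale is degenerate at
  $\theta = 1$).
* Permutation calibration uses 500 null datasets (200 pathways, 30 + 30
  samples, $B = 2{,}000$), asserting a rejection rate at $\alpha = 0.05$
  within $[0.03, 0.07]$; power uses 100 datasets with $\delta = 5\sigma$
  on 36 of 2,000 pathways, asserting `p_add_one` $\le 0.001$ in $\ge$ 99%.
  Monte-Carlo p-values are checked against exhaustive subset enumeration
  for pools $\le 12$ and $k \le 3$ within three Monte-Carlo standard
  errors.
* Quadrant-count conservation is fuzzed over 1,000 random table pairs;
  planted quadrant, DE-overlap and bound-gene counts are asserted exactly.
* Upper-tail hypergeometric p-values of discrete tests are
  *super-uniform* under the null; uniformity checks therefore assert
  non-anti-conservativeness (empirical rejection $\le$ nominal plus
  sampling slack) rather than a two-sided uniformity fit, except for the
  permutation p at $B = 2{,}000$, which is dense enough for a KS check.

# Known limitations

* The generators model independence across pathways, gene sets and genes;
  real compendia are correlated, so planted-recovery results bound
  best-case, not typical-case, behaviour.
* The Fisher-Z comparison is exact only for independent samples.
* Barcode reconciliation between mutation, CNA and clinical tables is
  exact-string with an optional prefix-truncation helper; resolving
  aliquot-level ambiguities is the caller's responsibility.
* The term framework does not curate near-duplicate terms; see above.
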