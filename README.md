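# comutkit

Integrative statistics for dissecting the genetic relationship between two
recurrently altered cancer genes — the motivating case being a tumor
suppressor (TP53) and a chromatin remodeler (ARID1A) in endometrial
carcinoma. Somatic alterations in such pairs are often **mutually
exclusive**: co-altered tumors are rarer than independence predicts,
hinting that one lesion phenocopies, or is selected against in the
presence of, the other. comutkit packages the statistical layers used to
characterize that pattern and its downstream consequences:

* **Stratified mutual-exclusivity screens** — binary alteration matrices
  built from MAF mutation calls and GISTIC copy-number calls
  ("altered" = mutation or deep CNA), 2x2 Fisher exact tests per tumor
  type / histology / molecular subtype, with the conditional-MLE odds
  ratio (OR < 1: exclusivity; OR > 1: co-occurrence).
* **Keyword-pathway activation** — for a pathway-activity score matrix,
  tests whether a named pathway family (e.g. all "p53" pathways) has a
  higher mean mutant-vs-wild-type score difference than random pathway
  subsets of the same size (empirical null from *B* draws of *k*
  pathways; default *B* = 50,000, *k* = 36), plus per-pathway Wilcoxon
  rank-sum screens with Benjamini–Hochberg FDR.
* **Enrichment concordance** — comparison of two GSEA-style NES tables:
  shared-up / shared-down / discordant quadrant counts at a strict
  |NES| > 1 threshold, hypergeometric overlap of enriched lists, Pearson
  and Spearman correlations, phi coefficients and Fisher-Z comparison of
  correlations.
* **N-gram term over-representation** — which single words, doublets and
  triplets are enriched among the names of a hit list of gene sets,
  against the full collection as universe (hypergeometric, joint BH).
* **Overlap and promoter annotation** — DE-gene overlap with directional
  concordance, generic gene-list enrichment against an explicit expressed
  universe, and peak-center-to-TSS annotation at ±3 kb / <50 kb windows.
* **Synthetic data with planted truth** — generators that plant an exact
  odds ratio (closed-form bivariate Bernoulli cells), activation shift,
  quadrant counts, DE overlap/concordance, enriched name terms and
  promoter-bound fractions, so every stage is testable end to end without
  any external download.

The core quantities, in standard notation: for a 2x2 table $(a,b,c,d)$ the
exact test uses the noncentral hypergeometric model with fixed margins;
the reported OR is the conditional MLE $\hat\psi$ solving
$E_\psi[X] = a$, and the two-tailed p sums the probabilities of all tables
at most as probable as the observed one. Overlap tests report
$P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$. The permutation p for
keyword family $S$ is $\#\{b: \bar\Delta^{(b)} \ge \bar\Delta_S\}/B$ (with
the add-one variant $(\#+1)/(B+1)$ alongside).

## Worked example

```r
library(comutkit)

# a cohort of 2,000 tumors with 32% / 45% marginal alteration rates and a
# planted population odds ratio of 0.155 (strong mutual exclusivity)
am <- gen_alteration_matrix(2000, 0.32, 0.45, theta = 0.155,
                            genes = c("TP53", "ARID1A"),
                            metadata_spec = list(histology =
                              c(endometrioid = 0.65, serous = 0.25, mixed = 0.10)),
                            seed = 2024)
screen_strata(am, "TP53", "ARID1A", strata = "histology")
#> Stratified Fisher screen: TP53 x ARID1A (two-tailed)
#>       stratum    n  a   b   c   d or_cmle or_sample        p stars error
#>  endometrioid 1299 70 342 513 374   0.149     0.149 6.29e-46   ***  <NA>
#>         mixed  215 12  55  88  60   0.150     0.149 1.03e-08   ***  <NA>
#>        serous  486 23 147 169 147   0.137     0.136 4.21e-19   ***  <NA>
```

Every stratum recovers the planted OR of 0.155 (mutual exclusivity:
co-altered count `a` far below independence), each with its exact
two-tailed p-value — the screen is not an artifact of cohort composition.

```r
# pathway activation: 36 "p53"-tagged pathways of 2,000, planted mean
# shift of 1.5 noise SDs in 30 mutant vs 30 wild-type samples
ps <- gen_pathway_scores(n_pathways = 2000, n_mutant = 30, n_wildtype = 30,
                         keyword = "p53", keyword_fraction = 36/2000,
                         delta = 1.5, sigma = 1, seed = 7)
delta <- group_mean_difference(ps)
kw <- keyword_select(rownames(ps$scores), "p53")
permutation_keyword_test(delta, kw, B = 50000, seed = 8)
#> Random-pathway-subset permutation test (upper-tailed)
#> observed mean difference = 1.554 over k = 36 pathways
#> null: B = 50000 draws, mean = 0.01459, sd = 0.05448
#> p (count/B) = 0   p (add-one) = 2e-05
```

None of 50,000 random 36-pathway subsets reaches the keyword family's
mean difference: the raw exceedance p is 0, with the add-one estimate
2e-5 as the safer summary.

A thin command-line front end over the same functions lives at
`inst/cli/comutkit.R` (subcommands `comut`, `permtest`, `concord`,
`terms`, `overlap`, `annotate`, `simulate`).

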