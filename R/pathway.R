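#' Per-pathway mean score difference between groups
#'
#' For each pathway, the mean activity score in mutant samples minus the
#' mean in wild-type samples. Pathways with any missing score are dropped
#' (with a message) before computing.
#'
#' @param x A `pathway_scores` object ([gen_pathway_scores()]), or a numeric
#'   matrix (pathways x samples) with `group` supplied.
#' @param group Factor/character per column with levels `mutant`,
#'   `wildtype`; ignored when `x` is a `pathway_scores` object.
#' @return Named numeric vector of per-pathway differences.
#' @export
group_mean_difference <- function(x, group = NULL) {
  if (inherits(x, "pathway_scores")) {
    group <- x$group
    x <- x$scores
  }
  if (!is.matrix(x)) param_error("x must be a pathway x sample matrix")
  group <- as.character(group)
  if (length(group) != ncol(x)) param_error("group must label every sample column")
  bad <- setdiff(unique(group), c("mutant", "wildtype"))
  if (length(bad)) param_error("unknown group label(s): ", paste(bad, collapse = ", "))
  mut <- group == "mutant"
  if (!any(mut) || all(mut)) param_error("both groups must be non-empty")
  keep <- stats::complete.cases(x)
  if (!all(keep)) {
    message("dropping ", sum(!keep), " pathway(s) with missing scores")
    x <- x[keep, , drop = FALSE]
  }
  rowMeans(x[, mut, drop = FALSE]) - rowMeans(x[, !mut, drop = FALSE])
}

#' Select pathways whose display name contains a keyword
#'
#' Plain substring match (no regular expression) over pathway display names,
#' the rule used to pick the keyword-tagged family (e.g. the 36 "p53"
#' pathways) whose joint activation is tested.
#'
#' @param names Character vector of pathway display names.
#' @param keyword Non-empty substring to match.
#' @param case_sensitive Match case-sensitively? Default `FALSE`.
#' @return Integer indices of matching pathways.
#' @export
keyword_select <- function(names, keyword, case_sensitive = FALSE) {
  if (!nzchar(keyword)) param_error("keyword must be non-empty")
  hay <- if (case_sensitive) names else tolower(names)
  ndl <- if (case_sensitive) keyword else tolower(keyword)
  idx <- which(grepl(ndl, hay, fixed = TRUE))
  if (!length(idx)) param_error("keyword '", keyword, "' matches no pathway name")
  idx
}

#' Random-subset permutation test for keyword-pathway activation
#'
#' Tests whether the mean of per-pathway score differences over a keyword
#' set of size k exceeds what random pathway subsets of the same size
#' produce. Each of `B` null draws is the mean difference over k pathways
#' sampled uniformly without replacement from the full pathway pool (the
#' keyword pathways remain in the pool unless `exclude_keyword`). The
#' empirical p is reported both as the raw exceedance fraction `count / B`
#' and as the add-one estimate `(count + 1) / (B + 1)`, which cannot be
#' exactly zero.
#'
#' @param delta Named numeric vector of per-pathway differences
#'   ([group_mean_difference()]).
#' @param keyword_set Integer indices (or names) of the keyword pathways.
#' @param B Number of null draws (the reference analysis uses 50,000).
#' @param k_override Subset size for the null draws; default `length(keyword_set)`.
#' @param direction `"upper"` (activation; default), `"lower"`, or `"two"`
#'   (exceedance of |observed| by |null| after centering at the null mean).
#' @param exclude_keyword Drop the keyword pathways from the sampling pool?
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `perm_test_result`: list with `observed`, `null_draws`,
#'   `p_uncorrected`, `p_add_one`, `B`, `k`, `direction`, `seed`.
#' @export
permutation_keyword_test <- function(delta, keyword_set, B = 50000,
                                     k_override = NULL,
                                     direction = c("upper", "lower", "two"),
                                     exclude_keyword = FALSE, seed = NULL) {
  direction <- match.arg(direction)
  check_count(B, "B")
  if (is.character(keyword_set)) keyword_set <- match(keyword_set, names(delta))
  if (anyNA(keyword_set) || !length(keyword_set) ||
      any(keyword_set < 1L | keyword_set > length(delta))) {
    param_error("keyword_set must index pathways of delta")
  }
  k <- if (is.null(k_override)) length(keyword_set) else check_count(k_override, "k_override")
  pool <- if (exclude_keyword) setdiff(seq_along(delta), keyword_set) else seq_along(delta)
  if (k > length(pool)) param_error("k exceeds the number of pathways in the pool")
  observed <- mean(delta[keyword_set])
  if (!is.null(seed)) set.seed(seed)
  pool_delta <- delta[pool]
  m <- length(pool_delta)
  null_draws <- vapply(seq_len(B),
                       function(i) mean(pool_delta[sample.int(m, k)]),
                       numeric(1))
  count <- switch(direction,
    upper = sum(null_draws >= observed),
    lower = sum(null_draws <= observed),
    two = {
      ctr <- mean(null_draws)
      sum(abs(null_draws - ctr) >= abs(observed - ctr))
    })
  structure(list(observed = observed, null_draws = null_draws,
                 p_uncorrected = count / B, p_add_one = (count + 1) / (B + 1),
                 B = B, k = k, direction = direction, seed = seed),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat("Random-pathway-subset permutation test (", x$direction, "-tailed)\n", sep = "")
  cat(sprintf("observed mean difference = %.4g over k = %d pathways\n", x$observed, x$k))
  cat(sprintf("null: B = %d draws, mean = %.4g, sd = %.4g\n",
              x$B, mean(x$null_draws), stats::sd(x$null_draws)))
  cat(sprintf("p (count/B) = %.4g   p (add-one) = %.4g\n",
              x$p_uncorrected, x$p_add_one))
  invisible(x)
}

#' Wilcoxon rank-sum test between two groups
#'
#' Unpaired two-sample rank-sum test. The p-value is exact (full
#' enumeration) when the combined sample size is at most 20 and there are
#' no ties; otherwise the normal approximation with tie and continuity
#' correction is used. The method actually applied is recorded.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param tail `"two"`, `"greater"`, or `"less"` (alternative about `x`
#'   relative to `y`).
#' @return List with `p`, `statistic` (rank-sum W for `x`), `method`
#'   (`"exact"` or `"normal_approx"`), `tail`.
#' @export
wilcoxon_rank_sum <- function(x, y, tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  if (!length(x) || !length(y)) param_error("both groups must be non-empty")
  alt <- c(two = "two.sided", greater = "greater", less = "less")[[tail]]
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 20L && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alt, exact = exact,
                                            correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # fully tied data carry no rank evidence
  list(p = p, statistic = unname(wt$statistic),
       method = if (exact) "exact" else "normal_approx", tail = tail)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjusted p-values (q-values) with monotonicity enforced,
#' mapped back to the input order. Input p-values outside \[0, 1\] are an
#' error rather than silently clipped.
#'
#' @param p Numeric vector of p-values.
#' @return Numeric vector of q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) param_error("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-pathway rank-sum screen with FDR
#'
#' Runs [wilcoxon_rank_sum()] for every pathway (mutant vs wild-type scores)
#' and adjusts across pathways by [bh_fdr()]; the per-pathway companion to
#' the set-level [permutation_keyword_test()].
#'
#' @param x A `pathway_scores` object or matrix as in
#'   [group_mean_difference()].
#' @param group As in [group_mean_difference()].
#' @param tail Test tail; default two-sided.
#' @return data.frame with `pathway`, `delta`, `p`, `q`, `method`.
#' @export
pathway_wilcoxon_screen <- function(x, group = NULL, tail = "two") {
  if (inherits(x, "pathway_scores")) {
    group <- as.character(x$group)
    x <- x$scores
  }
  mut <- group == "mutant"
  delta <- rowMeans(x[, mut, drop = FALSE]) - rowMeans(x[, !mut, drop = FALSE])
  res <- apply(x, 1L, function(row) wilcoxon_rank_sum(row[mut], row[!mut], tail = tail),
               simplify = FALSE)
  p <- vapply(res, `[[`, numeric(1), "p")
  data.frame(pathway = rownames(x), delta = delta, p = p, q = bh_fdr(p),
             method = vapply(res, `[[`, character(1), "method"),
             row.names = NULL, stringsAsFactors = FALSE)
}
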