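#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing at least `k` shared items when a list of size
#' `n` is drawn from a universe of `N` items of which `K` belong to the
#' other list: `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Computed
#' via the survival function in log-stable form, so large universes are
#' safe.
#'
#' @param k Overlap count.
#' @param K Size of the first list.
#' @param n Size of the second list (the draw).
#' @param N Universe size.
#' @return An `overlap_result`: list with `k`, `K`, `n`, `N`, `p`,
#'   `expected` (the null mean `n*K/N`), and `fold` (`k / expected`).
#' @export
hypergeom_overlap <- function(k, K, n, N) {
  for (v in list(k = k, K = K, n = n, N = N)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != floor(v) || v < 0) {
      param_error("k, K, n, N must be single non-negative integers")
    }
  }
  if (K > N || n > N) param_error("list sizes K, n cannot exceed the universe N")
  if (k > min(K, n)) param_error("overlap k cannot exceed min(K, n)")
  p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  expected <- if (N > 0) n * K / N else NaN
  structure(list(k = as.integer(k), K = as.integer(K), n = as.integer(n),
                 N = as.integer(N), p = p, expected = expected,
                 fold = if (expected > 0) k / expected else NaN),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Hypergeometric overlap: k = %d of K = %d and n = %d in N = %d\n",
              x$k, x$K, x$n, x$N))
  cat(sprintf("expected = %.2f, fold = %.2f, upper-tail p = %.4g\n",
              x$expected, x$fold, x$p))
  invisible(x)
}

#' DE-gene overlap with directional concordance
#'
#' Calls genes differentially expressed at `fdr < fdr_threshold` in each
#' table, tests the overlap of the two DE lists against the shared
#' expressed-gene universe (upper-tail hypergeometric), and reports the
#' directional concordance: the fraction of shared DE genes whose log2
#' fold changes agree in sign (a zero fold change counts as discordant
#' with either sign).
#'
#' @param de_a,de_b data.frames with `gene`, `log2fc`, `fdr` columns
#'   ([read_de_table()]).
#' @param universe Character vector of expressed genes; must contain every
#'   DE-called gene. There is no default — the hypergeometric p is
#'   meaningless without an explicit universe.
#' @param fdr_threshold Significance cutoff; default 0.05 (strict `<`).
#' @return A `de_overlap_result`: list with `overlap`
#'   ([hypergeom_overlap()] over k shared DE genes, K = |DE A|, n = |DE B|,
#'   N = |universe|), `shared_genes`, `n_concordant`,
#'   `concordance` (fraction, `NA` when no genes are shared), and
#'   `fdr_threshold`.
#' @export
de_overlap_concordance <- function(de_a, de_b, universe, fdr_threshold = 0.05) {
  for (t in list(de_a, de_b)) {
    if (!all(c("gene", "log2fc", "fdr") %in% names(t))) {
      param_error("DE tables need gene, log2fc and fdr columns")
    }
  }
  sig_a <- de_a$gene[de_a$fdr < fdr_threshold]
  sig_b <- de_b$gene[de_b$fdr < fdr_threshold]
  outside <- setdiff(c(sig_a, sig_b), universe)
  if (length(outside)) {
    param_error("DE gene(s) absent from the universe: ",
                paste(utils::head(outside, 5L), collapse = ", "))
  }
  shared <- intersect(sig_a, sig_b)
  ov <- hypergeom_overlap(k = length(shared), K = length(sig_a),
                          n = length(sig_b), N = length(universe))
  if (length(shared)) {
    la <- de_a$log2fc[match(shared, de_a$gene)]
    lb <- de_b$log2fc[match(shared, de_b$gene)]
    n_conc <- sum(la * lb > 0)
    concordance <- n_conc / length(shared)
  } else {
    n_conc <- 0L
    concordance <- NA_real_
  }
  structure(list(overlap = ov, shared_genes = shared, n_concordant = n_conc,
                 concordance = concordance, fdr_threshold = fdr_threshold),
            class = "de_overlap_result")
}

#' @export
print.de_overlap_result <- function(x, ...) {
  cat("DE overlap at FDR <", x$fdr_threshold, "\n")
  print(x$overlap)
  if (is.na(x$concordance)) {
    cat("directional concordance: undefined (no shared DE genes)\n")
  } else {
    cat(sprintf("directional concordance: %d/%d = %.1f%% same-sign\n",
                x$n_concordant, x$overlap$k, 100 * x$concordance))
  }
  invisible(x)
}

#' Annotate peaks to TSS-proximal genes
#'
#' A gene is "bound" at distance `d` if some peak center lies within `d`
#' bases of its TSS on the same chromosome. Peak centers are
#' `floor((start + end) / 2)` of the 0-based half-open interval; distance is
#' absolute, so strand does not affect it. Conventional windows are
#' d = 3000 (+/- 3 kb promoter) and d = 50000 (relaxed).
#'
#' @param peaks data.frame with `chrom`, `start`, `end` ([read_bed()]).
#' @param tss data.frame with `gene`, `chrom`, `tss`, `strand`
#'   ([read_tss()]).
#' @param d Distance threshold in bases (>= 0).
#' @return data.frame with one row per gene: `gene`, `chrom`, `tss`,
#'   `nearest_peak_distance` (`NA` when the chromosome has no peaks) and
#'   `bound` (logical).
#' @export
annotate_peaks_to_tss <- function(peaks, tss, d = 3000) {
  if (!is.numeric(d) || length(d) != 1L || d < 0) param_error("d must be >= 0")
  centers <- (peaks$start + peaks$end) %/% 2L
  by_chrom <- split(centers, peaks$chrom)
  nearest <- rep(NA_real_, nrow(tss))
  for (chrom in names(by_chrom)) {
    cs <- sort(by_chrom[[chrom]])
    rows <- which(tss$chrom == chrom)
    if (!length(rows)) next
    pos <- tss$tss[rows]
    # nearest sorted center via binary placement: candidates flank the index
    i <- findInterval(pos, cs)
    left <- ifelse(i >= 1L, abs(pos - cs[pmax(i, 1L)]), Inf)
    right <- ifelse(i < length(cs), abs(cs[pmin(i + 1L, length(cs))] - pos), Inf)
    nearest[rows] <- pmin(left, right)
  }
  data.frame(gene = tss$gene, chrom = tss$chrom, tss = tss$tss,
             nearest_peak_distance = nearest,
             bound = !is.na(nearest) & nearest <= d,
             stringsAsFactors = FALSE)
}

#' Intersect a curated target list with an associated gene list
#'
#' Intersection of a curated target-gene list (e.g. high-confidence TP53 or
#' TP63 targets) with a data-derived associated gene list, plus the
#' upper-tail hypergeometric enrichment of that intersection against the
#' expressed-gene universe.
#'
#' @param target_list,assoc_gene_list Character vectors, both contained in
#'   `universe`.
#' @param universe Character vector of expressed genes.
#' @return List with `network_genes` (the intersection) and `overlap`
#'   ([hypergeom_overlap()]).
#' @export
target_network_intersect <- function(target_list, assoc_gene_list, universe) {
  outside <- setdiff(c(target_list, assoc_gene_list), universe)
  if (length(outside)) {
    param_error("gene(s) outside the universe: ",
                paste(utils::head(outside, 5L), collapse = ", "))
  }
  target_list <- unique(target_list)
  assoc_gene_list <- unique(assoc_gene_list)
  net <- intersect(target_list, assoc_gene_list)
  list(network_genes = net,
       overlap = hypergeom_overlap(k = length(net), K = length(target_list),
                                   n = length(assoc_gene_list),
                                   N = length(unique(universe))))
}
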