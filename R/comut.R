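#' Construct an alteration matrix
#'
#' Container for binary sample-by-gene alteration calls plus per-sample
#' metadata (cohort, histology, molecular subtype, sample type, ...).
#'
#' @param calls Integer/logical matrix (samples x genes) of 0/1 indicators,
#'   with sample ids as rownames and gene symbols as colnames.
#' @param meta data.frame with a `sample_id` column matching the rows of
#'   `calls`, plus arbitrary categorical columns.
#' @return An object of class `alteration_matrix`.
#' @export
alteration_matrix <- function(calls, meta = NULL) {
  if (!is.matrix(calls)) param_error("calls must be a matrix")
  storage.mode(calls) <- "integer"
  if (!all(calls %in% c(0L, 1L))) param_error("calls must contain only 0/1 indicators")
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    param_error("calls must carry sample rownames and gene colnames")
  }
  if (anyDuplicated(rownames(calls))) param_error("duplicate sample ids in calls")
  if (is.null(meta)) {
    meta <- data.frame(sample_id = rownames(calls), stringsAsFactors = FALSE)
  }
  if (!"sample_id" %in% names(meta)) param_error("meta must have a sample_id column")
  if (anyDuplicated(meta$sample_id)) param_error("duplicate sample ids in meta")
  if (!setequal(meta$sample_id, rownames(calls))) {
    param_error("meta sample ids do not match calls rownames")
  }
  meta <- meta[match(rownames(calls), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(calls = calls, meta = meta), class = "alteration_matrix")
}

#' @export
print.alteration_matrix <- function(x, ...) {
  cat("Alteration matrix:", nrow(x$calls), "samples x", ncol(x$calls), "genes\n")
  freq <- colMeans(x$calls)
  cat("Alteration frequencies:\n")
  print(round(freq, 4))
  extra <- setdiff(names(x$meta), "sample_id")
  if (length(extra)) cat("Metadata fields:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' Combine mutation and copy-number calls into an alteration matrix
#'
#' A sample is "altered" for a gene if it carries at least one retained
#' mutation in that gene or a GISTIC copy-number call of absolute level at
#' least `cna_threshold`. Mutation calls are assumed already filtered to the
#' desired variant classes (see [read_maf()]).
#'
#' @param mutations data.frame of mutation calls (`sample_id`, `gene`, ...);
#'   may have zero rows for a CNA-only or mutation-only matrix.
#' @param cnas data.frame of CNA calls (`sample_id`, `gene`, `gistic_level`
#'   in -2..2); may have zero rows.
#' @param samples data.frame of sample metadata with unique `sample_id`;
#'   defines the sample universe (samples with no calls count as unaltered).
#' @param genes Character vector of genes to score.
#' @param cna_threshold Minimum |GISTIC level| that counts as an alteration;
#'   default 2 (deep deletion / high-level amplification only).
#' @return An [alteration_matrix()].
#' @export
combine_alterations <- function(mutations, cnas, samples, genes, cna_threshold = 2) {
  if (!"sample_id" %in% names(samples)) param_error("samples must have a sample_id column")
  ids <- as.character(samples$sample_id)
  if (anyDuplicated(ids)) param_error("duplicate sample ids in samples")
  check_count(cna_threshold, "cna_threshold", positive = FALSE)
  calls <- matrix(0L, length(ids), length(genes), dimnames = list(ids, genes))
  apply_calls <- function(df, keep, what) {
    df <- df[keep & df$gene %in% genes, , drop = FALSE]
    if (!nrow(df)) return(invisible())
    unknown <- setdiff(unique(df$sample_id), ids)
    if (length(unknown)) {
      param_error(what, " call(s) reference unknown sample id(s): ",
                  paste(utils::head(unknown, 5L), collapse = ", "))
    }
    calls[cbind(match(df$sample_id, ids), match(df$gene, genes))] <<- 1L
  }
  if (!is.null(mutations) && nrow(mutations)) {
    apply_calls(mutations, rep(TRUE, nrow(mutations)), "mutation")
  }
  if (!is.null(cnas) && nrow(cnas)) {
    if (!"gistic_level" %in% names(cnas)) param_error("cnas must have a gistic_level column")
    if (!all(cnas$gistic_level %in% -2:2)) param_error("gistic_level must be in -2..2")
    apply_calls(cnas, abs(cnas$gistic_level) >= cna_threshold, "CNA")
  }
  alteration_matrix(calls, samples)
}

#' Build a 2x2 alteration contingency table
#'
#' Counts samples in a stratum by joint alteration status of two genes.
#' Orientation is fixed: rows are `gene_a` status (altered first), columns
#' `gene_b` status, so `a` counts both-altered, `b` A-only, `c` B-only,
#' `d` neither.
#'
#' @param x An [alteration_matrix()].
#' @param gene_a,gene_b Gene symbols present in `x`.
#' @param stratum Optional stratum: a logical vector over samples, or a
#'   predicate function applied to the metadata data.frame returning one.
#'   `NULL` uses all samples.
#' @return A `contingency_2x2` object (fields `a`, `b`, `c`, `d`).
#' @export
build_contingency <- function(x, gene_a, gene_b, stratum = NULL) {
  stopifnot(inherits(x, "alteration_matrix"))
  for (g in c(gene_a, gene_b)) {
    if (!g %in% colnames(x$calls)) param_error("gene not in matrix: ", g)
  }
  keep <- if (is.null(stratum)) rep(TRUE, nrow(x$calls))
          else if (is.function(stratum)) stratum(x$meta)
          else stratum
  if (!is.logical(keep) || length(keep) != nrow(x$calls)) {
    param_error("stratum must select samples as a logical vector over the matrix")
  }
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) param_error("stratum selects no samples")
  sa <- x$calls[keep, gene_a]
  sb <- x$calls[keep, gene_b]
  contingency_2x2(a = sum(sa == 1L & sb == 1L), b = sum(sa == 1L & sb == 0L),
                  c = sum(sa == 0L & sb == 1L), d = sum(sa == 0L & sb == 0L))
}

#' Construct a 2x2 contingency table
#'
#' @param a Both-altered count.
#' @param b First-gene-only count.
#' @param c Second-gene-only count.
#' @param d Neither count.
#' @return A `contingency_2x2` object.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    param_error("contingency cells must be non-negative integers")
  }
  cells <- as.integer(cells)
  structure(list(a = cells[1L], b = cells[2L], c = cells[3L], d = cells[4L]),
            class = "contingency_2x2")
}

## Conditional MLE of the odds ratio: the maximizer of the noncentral
## hypergeometric likelihood of cell a given fixed margins. The score
## equation is E_psi[X] = a with E monotone in psi, solved on the log scale
## to near machine precision (considerably tighter than the estimate
## fisher.test reports). Boundary counts return 0 / Inf.
cmle_odds_ratio <- function(a, b, c, d) {
  r1 <- a + b; n2 <- c + d; c1 <- a + c
  lo <- max(0L, c1 - n2); hi <- min(r1, c1)
  if (a == lo && a == hi) return(NaN)
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  x <- lo:hi
  lw <- lchoose(r1, x) + lchoose(n2, c1 - x)
  cond_mean <- function(lpsi) {
    lt <- lw + x * lpsi
    w <- exp(lt - max(lt))
    sum(x * w) / sum(w)
  }
  f <- function(lpsi) cond_mean(lpsi) - a
  bound <- 1
  while (f(-bound) > 0 || f(bound) < 0) {
    bound <- bound * 2
    if (bound > 2^12) break
  }
  root <- stats::uniroot(f, c(-bound, bound), tol = 1e-12)$root
  exp(root)
}

as_matrix_2x2 <- function(tbl) {
  matrix(c(tbl$a, tbl$b, tbl$c, tbl$d), 2L, 2L, byrow = TRUE,
         dimnames = list(c("A_alt", "A_wt"), c("B_alt", "B_wt")))
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  print(as_matrix_2x2(x))
  invisible(x)
}

#' Fisher's exact test on a 2x2 alteration table
#'
#' Exact test over the hypergeometric distribution with fixed margins. The
#' two-tailed p-value follows the probability-mass rule (sum of the
#' probabilities of all tables at most as probable as the observed one).
#' The headline odds-ratio estimate is the conditional MLE — the maximizer
#' of the noncentral hypergeometric conditional likelihood — which is 0 or
#' +Inf for boundary tables; the sample (cross-product) odds ratio
#' `a*d / (b*c)` is reported alongside, optionally with the
#' Haldane-Anscombe +0.5 correction.
#'
#' @param tbl A `contingency_2x2` (or an object coercible via
#'   [contingency_2x2()] fields `a`..`d`).
#' @param tail One of `"two"`, `"greater"`, `"less"`.
#' @param haldane If `TRUE`, the sample OR adds 0.5 to every cell.
#' @return A `fisher_result`: list with `p`, `tail`, `or_cmle`, `or_sample`,
#'   `or_method`, `conf_int`, `table`, `stars`.
#' @export
fisher_exact <- function(tbl, tail = c("two", "greater", "less"), haldane = FALSE) {
  tail <- match.arg(tail)
  stopifnot(inherits(tbl, "contingency_2x2"))
  m <- as_matrix_2x2(tbl)
  alt <- c(two = "two.sided", greater = "greater", less = "less")[[tail]]
  degenerate <- any(rowSums(m) == 0L) || any(colSums(m) == 0L)
  if (degenerate) {
    p <- 1
    or_cmle <- NaN
    ci <- c(NaN, NaN)
    or_method <- "undefined (degenerate margin)"
  } else {
    ft <- stats::fisher.test(m, alternative = alt)
    p <- ft$p.value
    or_cmle <- cmle_odds_ratio(tbl$a, tbl$b, tbl$c, tbl$d)
    ci <- if (!is.null(ft$conf.int)) as.numeric(ft$conf.int) else c(NA_real_, NA_real_)
    or_method <- "conditional_mle"
  }
  or_sample <- if (haldane) {
    (tbl$a + 0.5) * (tbl$d + 0.5) / ((tbl$b + 0.5) * (tbl$c + 0.5))
  } else if (tbl$b * tbl$c > 0) {
    tbl$a * tbl$d / (tbl$b * tbl$c)
  } else if (tbl$a * tbl$d > 0) Inf else NaN
  structure(list(p = p, tail = tail, or_cmle = or_cmle, or_sample = or_sample,
                 or_method = or_method, conf_int = ci, table = tbl,
                 stars = p_stars(p)),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("Fisher exact test (", x$tail, "-tailed)\n", sep = "")
  print(as_matrix_2x2(x$table))
  cat(sprintf("OR (conditional MLE) = %.4g   OR (sample) = %.4g\n",
              x$or_cmle, x$or_sample))
  cat(sprintf("p = %.4g %s\n", x$p, x$stars))
  invisible(x)
}

#' Stratified mutual-exclusivity / co-occurrence screen
#'
#' Runs [fisher_exact()] on the `gene_a` x `gene_b` contingency table within
#' each stratum (e.g. per tumor type, histology, or molecular subtype). No
#' multiplicity correction is applied across strata; raw per-stratum p-values
#' are reported with significance stars (* p<0.05, ** p<0.01, *** p<0.001).
#' A stratum that fails (e.g. selects no samples) is reported with an error
#' message and `NA` statistics; the other strata still run.
#'
#' @param x An [alteration_matrix()].
#' @param gene_a,gene_b Genes to screen.
#' @param strata Either the name of a metadata column (one stratum per
#'   level) or a named list of predicates/logical vectors as in
#'   [build_contingency()].
#' @param tail Test tail, as in [fisher_exact()].
#' @return A `comut_screen` data.frame: one row per stratum with columns
#'   `stratum`, `n`, `a`, `b`, `c`, `d`, `or_cmle`, `or_sample`, `p`,
#'   `stars`, `error`.
#' @export
screen_strata <- function(x, gene_a, gene_b, strata, tail = "two") {
  stopifnot(inherits(x, "alteration_matrix"))
  if (is.character(strata) && length(strata) == 1L) {
    col <- strata
    if (!col %in% names(x$meta)) param_error("no metadata column named ", col)
    levs <- sort(unique(as.character(x$meta[[col]])))
    strata <- lapply(levs, function(l) x$meta[[col]] == l)
    names(strata) <- levs
  }
  if (!length(strata)) param_error("at least one stratum required")
  if (is.null(names(strata))) names(strata) <- paste0("stratum", seq_along(strata))
  rows <- lapply(names(strata), function(nm) {
    res <- tryCatch({
      tbl <- build_contingency(x, gene_a, gene_b, strata[[nm]])
      fr <- fisher_exact(tbl, tail = tail)
      data.frame(stratum = nm, n = tbl$a + tbl$b + tbl$c + tbl$d,
                 a = tbl$a, b = tbl$b, c = tbl$c, d = tbl$d,
                 or_cmle = fr$or_cmle, or_sample = fr$or_sample,
                 p = fr$p, stars = fr$stars, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, comutkit_error = function(e) {
      data.frame(stratum = nm, n = NA_integer_, a = NA_integer_, b = NA_integer_,
                 c = NA_integer_, d = NA_integer_, or_cmle = NA_real_,
                 or_sample = NA_real_, p = NA_real_, stars = "",
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "genes") <- c(gene_a, gene_b)
  attr(out, "tail") <- tail
  class(out) <- c("comut_screen", "data.frame")
  out
}

#' @export
print.comut_screen <- function(x, ...) {
  g <- attr(x, "genes")
  cat("Stratified Fisher screen:", g[1L], "x", g[2L],
      paste0("(", attr(x, "tail"), "-tailed)\n"))
  df <- as.data.frame(x)
  df$or_cmle <- signif(df$or_cmle, 3)
  df$or_sample <- signif(df$or_sample, 3)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Hypergeometric enrichment of a category among co-altered samples
#'
#' Tests whether a sample category (e.g. mixed-morphology histology) is
#' over-represented among co-altered samples: upper-tail hypergeometric
#' probability of drawing at least the observed overlap when `n` co-altered
#' samples are drawn from a universe of `N` with `K` category members.
#'
#' @param co_altered Logical vector over the sample universe.
#' @param category Logical vector over the same universe.
#' @return An `overlap_result` (see [hypergeom_overlap()]).
#' @export
subtype_enrichment <- function(co_altered, category) {
  if (length(co_altered) != length(category)) {
    param_error("co_altered and category must cover the same sample universe")
  }
  if (anyNA(co_altered) || anyNA(category)) param_error("flags must not contain NA")
  hypergeom_overlap(k = sum(co_altered & category), K = sum(category),
                    n = sum(co_altered), N = length(co_altered))
}
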