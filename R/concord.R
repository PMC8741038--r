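#' Quadrant concordance between two enrichment comparisons
#'
#' Joins two per-gene-set NES tables on `set_id` (sets present in only one
#' table are dropped with a message) and classifies every shared set by the
#' strict |NES| > `tau` enrichment rule: shared-up (`nes > tau` in both),
#' shared-down (`nes < -tau` in both), discordant (enriched in both with
#' opposite signs), one-sided (enriched in exactly one), or unenriched.
#' Hypergeometric overlap enrichment is computed for the up lists and the
#' down lists against the shared-set universe, and Pearson/Spearman
#' correlations of the NES vectors are reported.
#'
#' @param table_a,table_b data.frames with columns `set_id`, `nes`
#'   (and optionally `fdr`), as from [read_nes_table()].
#' @param tau Enrichment threshold (> 0); strict inequality, so
#'   `|nes| == tau` is not enriched. Default 1.
#' @return A `concordance_result`: list with `tau`, `n_shared`, `counts`
#'   (named: shared_up, shared_down, discordant, one_sided, unenriched),
#'   `overlap_up`, `overlap_down` ([hypergeom_overlap()] results),
#'   `pearson_r`, `spearman_rho`, `n`, and the joined `sets` data.frame
#'   (set_id, nes_a, nes_b, quadrant).
#' @export
quadrant_concordance <- function(table_a, table_b, tau = 1) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) param_error("tau must be > 0")
  for (t in list(table_a, table_b)) {
    if (!all(c("set_id", "nes") %in% names(t))) {
      param_error("enrichment tables need set_id and nes columns")
    }
  }
  shared <- intersect(table_a$set_id, table_b$set_id)
  dropped <- length(setdiff(table_a$set_id, shared)) +
             length(setdiff(table_b$set_id, shared))
  if (!length(shared)) param_error("no shared set_ids between the two tables")
  if (dropped) message("dropping ", dropped, " set id(s) present in only one table")
  na <- table_a$nes[match(shared, table_a$set_id)]
  nb <- table_b$nes[match(shared, table_b$set_id)]
  enr_a <- abs(na) > tau
  enr_b <- abs(nb) > tau
  quadrant <- ifelse(na > tau & nb > tau, "shared_up",
              ifelse(na < -tau & nb < -tau, "shared_down",
              ifelse(enr_a & enr_b, "discordant",
              ifelse(xor(enr_a, enr_b), "one_sided", "unenriched"))))
  counts <- vapply(c("shared_up", "shared_down", "discordant", "one_sided",
                     "unenriched"),
                   function(q) sum(quadrant == q), integer(1))
  N <- length(shared)
  overlap_up <- hypergeom_overlap(k = counts[["shared_up"]], K = sum(na > tau),
                                  n = sum(nb > tau), N = N)
  overlap_down <- hypergeom_overlap(k = counts[["shared_down"]], K = sum(na < -tau),
                                    n = sum(nb < -tau), N = N)
  cors <- nes_correlation_vec(na, nb)
  structure(list(tau = tau, n_shared = N, counts = counts,
                 overlap_up = overlap_up, overlap_down = overlap_down,
                 pearson_r = cors$pearson_r, spearman_rho = cors$spearman_rho,
                 n = cors$n,
                 sets = data.frame(set_id = shared, nes_a = na, nes_b = nb,
                                   quadrant = quadrant, stringsAsFactors = FALSE)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("Enrichment concordance (|NES| > ", x$tau, ", strict) over ",
      x$n_shared, " shared sets\n", sep = "")
  print(x$counts)
  cat(sprintf("up-list overlap p = %.3g; down-list overlap p = %.3g\n",
              x$overlap_up$p, x$overlap_down$p))
  cat(sprintf("Pearson r = %.3f, Spearman rho = %.3f (n = %d)\n",
              x$pearson_r, x$spearman_rho, x$n))
  invisible(x)
}

nes_correlation_vec <- function(na, nb) {
  if (length(na) < 3L) param_error("need at least 3 shared sets for correlations")
  if (stats::sd(na) == 0 || stats::sd(nb) == 0) {
    warning("zero variance in an NES vector; correlations undefined")
    return(list(pearson_r = NA_real_, spearman_rho = NA_real_, n = length(na)))
  }
  list(pearson_r = stats::cor(na, nb, method = "pearson"),
       spearman_rho = stats::cor(na, nb, method = "spearman"),
       n = length(na))
}

#' Pearson and Spearman correlation of two NES tables
#'
#' Correlations over the sets shared between the two tables.
#'
#' @param table_a,table_b data.frames with `set_id` and `nes` columns.
#' @return List with `pearson_r`, `spearman_rho`, `n`.
#' @export
nes_correlation <- function(table_a, table_b) {
  shared <- intersect(table_a$set_id, table_b$set_id)
  if (length(shared) < 3L) param_error("need at least 3 shared sets for correlations")
  nes_correlation_vec(table_a$nes[match(shared, table_a$set_id)],
                      table_b$nes[match(shared, table_b$set_id)])
}

#' Phi coefficient of a 2x2 table
#'
#' `phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))` — the Pearson correlation
#' of the two binary classifications — with the chi-square-based p-value
#' (`chisq = n * phi^2`, 1 df, no continuity correction).
#'
#' @param tbl A `contingency_2x2` ([contingency_2x2()]).
#' @return List with `phi`, `chisq`, `p`, `n`; `phi` is `NaN` (with a
#'   warning) when any margin is zero.
#' @export
phi_coefficient <- function(tbl) {
  stopifnot(inherits(tbl, "contingency_2x2"))
  a <- tbl$a; b <- tbl$b; c <- tbl$c; d <- tbl$d
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    warning("zero margin: phi undefined")
    return(list(phi = NaN, chisq = NaN, p = NaN, n = n))
  }
  phi <- (a * d - b * c) / sqrt(prod(as.numeric(margins)))
  chisq <- n * phi^2
  list(phi = phi, chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE), n = n)
}

#' Compare two correlation coefficients by Fisher's Z-transformation
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p-value. The formula assumes the two correlations come
#' from independent samples; that assumption is recorded in the result so
#' downstream reports carry it.
#'
#' @param r1,r2 Correlation coefficients with |r| < 1.
#' @param n1,n2 Sample sizes (> 3).
#' @return List with `z`, `p`, `assumption`.
#' @export
compare_correlations_fisher_z <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) param_error("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) param_error("both sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
       assumption = "independent samples")
}
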