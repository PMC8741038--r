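## Independent oracles: brute-force / closed-form re-derivations used to
## check the package's statistics. These deliberately avoid the code paths
## (and, where possible, the base functions) used by the implementation.

## Exact two-tailed Fisher p by exhaustive enumeration over the
## hypergeometric support, probability-mass rule: sum the probabilities of
## all tables with point probability <= that of the observed table (up to a
## relative float tolerance).
oracle_fisher_two_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  lo <- max(0L, r1 + c1 - N); hi <- min(r1, c1)
  x <- lo:hi
  logp <- lchoose(c1, x) + lchoose(N - c1, r1 - x) - lchoose(N, r1)
  probs <- exp(logp)
  p_obs <- probs[x == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Exact one-tailed (greater) Fisher p by enumeration.
oracle_fisher_greater_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  lo <- max(0L, r1 + c1 - N); hi <- min(r1, c1)
  x <- lo:hi
  probs <- exp(lchoose(c1, x) + lchoose(N - c1, r1 - x) - lchoose(N, r1))
  sum(probs[x >= a])
}

## Conditional-MLE odds ratio by dense grid search over log-odds followed by
## golden-section refinement of the noncentral hypergeometric conditional
## log-likelihood. Returns 0 / Inf at the support boundary.
oracle_cmle_or <- function(a, b, c, d) {
  r1 <- a + b; n2 <- c + d; c1 <- a + c
  lo <- max(0L, c1 - n2); hi <- min(r1, c1)
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  x <- lo:hi
  lw <- lchoose(r1, x) + lchoose(n2, c1 - x)
  loglik <- function(lpsi) {
    a * lpsi - (max(lw + x * lpsi) + log(sum(exp(lw + x * lpsi - max(lw + x * lpsi)))))
  }
  grid <- seq(-20, 20, length.out = 2001)
  vals <- vapply(grid, loglik, numeric(1))
  i <- which.max(vals)
  lo_b <- grid[max(1L, i - 1L)]; hi_b <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(loglik, c(lo_b, hi_b), maximum = TRUE, tol = 1e-10)
  exp(opt$maximum)
}

## Upper-tail hypergeometric overlap p by direct summation of binomial
## coefficients.
oracle_hyper_upper <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  x <- k:hi
  sum(exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)))
}

## Exact two-sided Wilcoxon rank-sum p by enumerating every assignment of
## the pooled observations to the two groups (tie-free inputs only).
oracle_wilcoxon_two_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r_obs <- sum(rank(pooled)[seq_len(nx)])
  combos <- utils::combn(nx + ny, nx)
  ranks <- rank(pooled)
  w <- apply(combos, 2L, function(idx) sum(ranks[idx]))
  p_le <- mean(w <= r_obs)
  p_ge <- mean(w >= r_obs)
  min(1, 2 * min(p_le, p_ge))
}

## Exhaustive random-subset permutation p: upper-tail fraction of all
## C(m, k) subsets whose delta mean is >= the observed mean.
oracle_perm_exhaustive_p <- function(delta, keyword_idx, k = length(keyword_idx)) {
  obs <- mean(delta[keyword_idx])
  combos <- utils::combn(length(delta), k)
  means <- apply(combos, 2L, function(idx) mean(delta[idx]))
  mean(means >= obs)
}

## Step-up Benjamini-Hochberg by direct arithmetic.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

## Spearman rho by the rank-transform Pearson formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

## Brute-force nearest-peak distance: O(genes x peaks) scan.
oracle_nearest_distance <- function(peaks, tss) {
  vapply(seq_len(nrow(tss)), function(i) {
    same <- peaks$chrom == tss$chrom[i]
    if (!any(same)) return(NA_real_)
    centers <- (peaks$start[same] + peaks$end[same]) %/% 2L
    min(abs(centers - tss$tss[i]))
  }, numeric(1))
}

## Small fixture writers used by the io tests.
write_toy_maf <- function(path, rows) {
  header <- "Hugo_Symbol\tVariant_Classification\tTumor_Sample_Barcode"
  writeLines(c(header, rows), path)
  path
}
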