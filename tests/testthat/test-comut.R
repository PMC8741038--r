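toy_matrix <- function() {
  # statuses for (A, B): (1,1),(1,0),(0,1),(0,0),(0,0),(1,1)
  calls <- matrix(c(1,1, 1,0, 0,1, 0,0, 0,0, 1,1), ncol = 2, byrow = TRUE,
                  dimnames = list(paste0("S", 1:6), c("A", "B")))
  alteration_matrix(calls, data.frame(sample_id = paste0("S", 1:6),
                                      grp = rep(c("x", "y"), 3)))
}

test_that("combine_alterations applies the mutation-or-CNA rule", {
  samples <- data.frame(sample_id = c("S1", "S2", "S3"))
  genes <- c("TP53", "ARID1A")
  # S1 carries only a Silent TP53 call, which the non-silent filter removes
  muts <- data.frame(sample_id = "S1", gene = "TP53", variant_class = "Silent")
  muts <- muts[muts$variant_class %in% non_silent_classes(), ]
  cnas <- data.frame(sample_id = "S2", gene = "ARID1A", gistic_level = -2L)
  am <- combine_alterations(muts, cnas, samples, genes, cna_threshold = 2)
  expect_equal(unname(am$calls["S1", "TP53"]), 0L)
  expect_equal(unname(am$calls["S2", "ARID1A"]), 1L)
  # shallow deletion falls below the deep-event threshold
  am2 <- combine_alterations(muts, data.frame(sample_id = "S2", gene = "ARID1A",
                                              gistic_level = -1L),
                             samples, genes, cna_threshold = 2)
  expect_equal(sum(am2$calls), 0L)
  # mutation-only mode reproduces a pure mutation matrix
  m3 <- data.frame(sample_id = c("S1", "S3"), gene = c("TP53", "ARID1A"),
                   variant_class = c("Missense_Mutation", "Frame_Shift_Del"))
  am3 <- combine_alterations(m3, NULL, samples, genes)
  expect_equal(unname(am3$calls[cbind(c("S1", "S3"), c("TP53", "ARID1A"))]), c(1L, 1L))
  expect_error(combine_alterations(data.frame(sample_id = "NOPE", gene = "TP53",
                                              variant_class = "Missense_Mutation"),
                                   NULL, samples, genes),
               "NOPE", class = "comutkit_param_error")
})

test_that("contingency tables count joint alteration status per stratum", {
  am <- toy_matrix()
  tbl <- build_contingency(am, "A", "B")
  expect_equal(unlist(tbl[c("a", "b", "c", "d")]), c(a = 2L, b = 1L, c = 1L, d = 2L))
  one <- build_contingency(am, "A", "B", stratum = c(TRUE, rep(FALSE, 5)))
  expect_equal(one$a + one$b + one$c + one$d, 1L)
  expect_error(build_contingency(am, "A", "Z"), "Z", class = "comutkit_param_error")
  expect_error(build_contingency(am, "A", "B", stratum = rep(FALSE, 6)),
               class = "comutkit_param_error")
})

test_that("fisher_exact reproduces enumeration and conditional-MLE oracles", {
  bal <- fisher_exact(contingency_2x2(5, 5, 5, 5))
  expect_equal(bal$p, 1)
  expect_equal(bal$or_cmle, 1, tolerance = 1e-6)

  fr <- fisher_exact(contingency_2x2(3, 1, 1, 3), tail = "greater")
  expect_equal(fr$p, 17 / 70, tolerance = 1e-12)
  fr2 <- fisher_exact(contingency_2x2(3, 1, 1, 3))
  expect_equal(log(fr2$or_cmle), log(oracle_cmle_or(3, 1, 1, 3)), tolerance = 1e-4)
  expect_equal(fr2$or_cmle, 6.41, tolerance = 1e-3)
  expect_equal(fr2$or_sample, 9)
  expect_equal(fisher_exact(contingency_2x2(3, 1, 1, 3), haldane = TRUE)$or_sample,
               (3.5 * 3.5) / (1.5 * 1.5))

  deg <- fisher_exact(contingency_2x2(0, 0, 5, 5))
  expect_equal(deg$p, 1)
  expect_true(is.nan(deg$or_cmle))

  bound <- fisher_exact(contingency_2x2(5, 0, 0, 5))
  expect_identical(bound$or_cmle, Inf)
})

test_that("fisher_exact is transpose-invariant and OR reorients reciprocally", {
  set.seed(31)
  for (i in 1:25) {
    cells <- rmultinom(1, sample(8:40, 1), prob = runif(4, 0.05, 1))[, 1]
    t1 <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    t2 <- contingency_2x2(cells[1], cells[3], cells[2], cells[4])  # transpose
    f1 <- fisher_exact(t1); f2 <- fisher_exact(t2)
    expect_equal(f1$p, f2$p, tolerance = 1e-12)
    if (is.finite(f1$or_cmle) && f1$or_cmle > 0) {
      expect_equal(f1$or_cmle, f2$or_cmle, tolerance = 1e-6)
      # swapping the rows inverts the association
      f3 <- fisher_exact(contingency_2x2(cells[3], cells[4], cells[1], cells[2]))
      expect_equal(f3$or_cmle, 1 / f1$or_cmle, tolerance = 1e-6)
    }
  }
})

test_that("stratified screens conserve counts and survive failing strata", {
  am <- toy_matrix()
  scr <- screen_strata(am, "A", "B", strata = "grp")
  expect_equal(nrow(scr), 2L)
  glob <- build_contingency(am, "A", "B")
  expect_equal(sum(scr$a), glob$a)
  expect_equal(sum(scr$n), 6L)

  mixed <- screen_strata(am, "A", "B",
                         strata = list(all = rep(TRUE, 6), none = rep(FALSE, 6)))
  expect_true(is.na(mixed$p[mixed$stratum == "none"]))
  expect_match(mixed$error[mixed$stratum == "none"], "no samples")
  expect_false(is.na(mixed$p[mixed$stratum == "all"]))
})

test_that("screen recovers a planted odds ratio from synthetic matrices", {
  am <- gen_alteration_matrix(50000, 0.3, 0.3, 0.155, seed = 42)
  fr <- fisher_exact(build_contingency(am, "GENE_A", "GENE_B"))
  expect_equal(fr$or_cmle, 0.155, tolerance = 0.1)
  # log-OR error shrinks with sample size (median over seeds)
  err_at <- function(n) {
    median(vapply(1:5, function(s) {
      a <- gen_alteration_matrix(n, 0.3, 0.3, 4, seed = 100 + s)
      abs(log(fisher_exact(build_contingency(a, "GENE_A", "GENE_B"))$or_cmle) - log(4))
    }, numeric(1)))
  }
  expect_lt(err_at(20000), err_at(500))
})

test_that("subtype enrichment matches exact combinatorics", {
  co <- c(rep(TRUE, 5), rep(FALSE, 15))
  cat_flags <- c(rep(TRUE, 4), FALSE, TRUE, TRUE, rep(FALSE, 13))
  res <- subtype_enrichment(co, cat_flags)  # N=20, K=6, n=5, k=4
  expect_equal(res$p, 216 / 15504, tolerance = 1e-12)
  # zero overlap is never enriched
  expect_equal(subtype_enrichment(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE))$p, 1)
  expect_error(subtype_enrichment(c(TRUE, FALSE), c(TRUE, FALSE, TRUE)),
               class = "comutkit_param_error")
})
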