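test_that("joint-cell solver hits the closed-form cases and the OR identity", {
  cells <- solve_comut_cells(0.5, 0.5, 9)
  expect_equal(unname(cells), c(0.375, 0.125, 0.125, 0.375), tolerance = 1e-12)

  expect_equal(solve_comut_cells(0.3, 0.3, 1)[["p11"]], 0.09, tolerance = 1e-12)
  # theta -> 0 limit with p_a + p_b < 1: joint probability vanishes
  expect_lt(solve_comut_cells(0.3, 0.3, 1e-10)[["p11"]], 1e-9)

  set.seed(21)
  for (i in 1:50) {
    p_a <- runif(1, 0.05, 0.9); p_b <- runif(1, 0.05, 0.9)
    theta <- exp(runif(1, -3, 3))
    cl <- solve_comut_cells(p_a, p_b, theta)
    expect_equal(sum(cl), 1, tolerance = 1e-12)
    expect_equal(cl[["p11"]] + cl[["p10"]], p_a, tolerance = 1e-12)
    if (all(cl > 0)) {
      expect_equal(cl[["p11"]] * cl[["p00"]] / (cl[["p10"]] * cl[["p01"]]),
                   theta, tolerance = 1e-9)
    }
  }
})

test_that("alteration generator is seed-deterministic with planted marginals", {
  a1 <- gen_alteration_matrix(5000, 0.3, 0.4, 2, seed = 7,
                              metadata_spec = list(histology = c(endometrioid = 3, serous = 1)))
  a2 <- gen_alteration_matrix(5000, 0.3, 0.4, 2, seed = 7,
                              metadata_spec = list(histology = c(endometrioid = 3, serous = 1)))
  expect_identical(a1$calls, a2$calls)
  expect_identical(a1$meta, a2$meta)
  expect_equal(mean(a1$calls[, 1]), 0.3, tolerance = 0.03)
  expect_equal(mean(a1$calls[, 2]), 0.4, tolerance = 0.03)
  expect_setequal(unique(a1$meta$histology), c("endometrioid", "serous"))
})

test_that("pathway score generator plants the keyword shift in the mutant group", {
  ps <- gen_pathway_scores(n_pathways = 300, n_mutant = 40, n_wildtype = 40,
                           delta = 2, sigma = 1, seed = 5)
  expect_identical(gen_pathway_scores(n_pathways = 300, n_mutant = 40,
                                      n_wildtype = 40, delta = 2, sigma = 1,
                                      seed = 5)$scores, ps$scores)
  tagged <- grepl("p53", rownames(ps$scores))
  expect_equal(which(tagged), ps$keyword_idx)
  d <- group_mean_difference(ps)
  expect_equal(mean(d[ps$keyword_idx]), 2, tolerance = 0.3)
  expect_equal(mean(d[-ps$keyword_idx]), 0, tolerance = 0.1)
})

test_that("paired enrichment generator plants exact quadrant counts", {
  pe <- gen_paired_enrichment_tables(1000, 0.2, 0, 0, seed = 3)
  expect_equal(pe$n_shared_up, floor(0.2 * 1000))
  up <- pe$table_a$nes > 1 & pe$table_b$nes > 1
  expect_equal(sum(up), 200L)

  none <- gen_paired_enrichment_tables(500, 0, 0, 0, seed = 4)
  expect_equal(sum(abs(none$table_a$nes) > 1), 0L)
  expect_equal(sum(abs(none$table_b$nes) > 1), 0L)

  expect_error(gen_paired_enrichment_tables(100, 0.6, 0.5, 0),
               class = "comutkit_param_error")
})

test_that("paired DE generator plants overlap and concordance exactly", {
  de <- gen_paired_de_tables(2000, 100, 50, 80, concordant_fraction = 0.9, seed = 6)
  sig_a <- de$table_a$gene[de$table_a$fdr < 0.05]
  sig_b <- de$table_b$gene[de$table_b$fdr < 0.05]
  expect_length(sig_a, 150L)
  expect_length(sig_b, 180L)
  expect_setequal(intersect(sig_a, sig_b), de$shared_genes)
  expect_equal(de$n_concordant, 90L)

  empty <- gen_paired_de_tables(100, 0, 10, 10, seed = 8)
  res <- de_overlap_concordance(empty$table_a, empty$table_b, empty$universe)
  expect_equal(res$overlap$p, 1)
  expect_true(is.na(res$concordance))

  expect_error(gen_paired_de_tables(100, 60, 30, 30, 1),
               class = "comutkit_param_error")
})

test_that("set-name corpus generator validates its rates and vocabulary", {
  vocab <- c("cell", "cycle", "dna", "repair", "virus")
  expect_error(gen_setname_corpus(vocab, 100, 4, "not invocab", seed = 1),
               class = "comutkit_param_error")
  expect_error(gen_setname_corpus(vocab, 100, 4, "cell cycle",
                                  enrichment_factor = 30, background_rate = 0.05),
               class = "comutkit_param_error")
  corp <- gen_setname_corpus(vocab, 60, 4, "cell cycle", hit_fraction = 0.2,
                             enrichment_factor = 4, background_rate = 0.05, seed = 2)
  expect_length(corp$names, 60L)
  expect_false(anyDuplicated(corp$names) > 0)
  expect_true(all(corp$hits %in% corp$names))
  corp2 <- gen_setname_corpus(vocab, 60, 4, "cell cycle", hit_fraction = 0.2,
                              enrichment_factor = 4, background_rate = 0.05, seed = 2)
  expect_identical(corp2$names, corp$names)
})

test_that("peak/TSS generator plants the bound fraction and respects separation", {
  pk <- gen_peaks_tss(100, 0.5, d_prom = 3000, seed = 9)
  ann <- annotate_peaks_to_tss(pk$peaks, pk$tss, 3000)
  expect_equal(sum(ann$bound), 50L)
  expect_setequal(ann$gene[ann$bound], pk$bound_genes)
  # unbound genes really are >= 2 * d_prom from every peak center
  expect_true(all(ann$nearest_peak_distance[!ann$bound] >= 6000))

  none <- gen_peaks_tss(50, 0, seed = 10)
  expect_equal(sum(annotate_peaks_to_tss(none$peaks, none$tss, 3000)$bound), 0L)

  # querying below the generating window can only lose genes
  tight <- annotate_peaks_to_tss(pk$peaks, pk$tss, 500)
  expect_lte(sum(tight$bound), 50L)
  expect_true(all(tight$gene[tight$bound] %in% pk$bound_genes))

  expect_error(gen_peaks_tss(100, 0.5, d_prom = 3000, genome_span = 1e5),
               class = "comutkit_param_error")
})
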