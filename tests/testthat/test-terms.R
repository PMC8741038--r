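test_that("tokenization yields contiguous lowercased n-grams after prefix strip", {
  terms <- tokenize_ngrams("GO_RESPONSE_TO_VIRUS")
  expect_setequal(terms, c("response", "to", "virus",
                           "response to", "to virus", "response to virus"))
  expect_equal(tokenize_ngrams("HALLMARK_APOPTOSIS"), "apoptosis")
  # repeated word contributes each term once
  expect_equal(sum(tokenize_ngrams("GO_CELL_TO_CELL") == "cell"), 1L)
  expect_error(tokenize_ngrams("GO_"), class = "comutkit_param_error")
  # order cap
  expect_setequal(tokenize_ngrams("GO_A_B_C", max_order = 1), c("a", "b", "c"))
})

test_that("n-gram membership is nested: bigram K never exceeds its unigrams", {
  vocab <- c("cell", "cycle", "dna", "repair", "virus", "response", "to",
             "stress", "growth", "signal")
  corp <- gen_setname_corpus(vocab, 150, 5, "response to", hit_fraction = 0.2,
                             enrichment_factor = 3, seed = 17)
  tu <- build_term_universe(corp$names)
  Kof <- function(term) {
    m <- tu$membership[[term]]
    if (is.null(m)) 0L else length(m)
  }
  for (term in names(tu$membership)) {
    words <- strsplit(term, " ", fixed = TRUE)[[1]]
    if (length(words) == 2) {
      expect_lte(Kof(term), min(Kof(words[1]), Kof(words[2])))
    } else if (length(words) == 3) {
      b1 <- paste(words[1:2], collapse = " ")
      b2 <- paste(words[2:3], collapse = " ")
      expect_lte(Kof(term), min(Kof(b1), Kof(b2)))
    }
  }
})

test_that("term over-representation reproduces the exact worked example", {
  names6 <- c("GO_CELL_CYCLE_ARREST", "GO_CELL_CYCLE_CHECKPOINT",
              "GO_MITOTIC_CELL_CYCLE", "GO_DNA_REPAIR",
              "GO_RESPONSE_TO_VIRUS", "GO_LIPID_TRANSPORT")
  tu <- build_term_universe(names6)
  res <- term_overrepresentation(names6[1:2], tu)
  cc <- res[res$term == "cell cycle", ]
  expect_equal(cc$k, 2L); expect_equal(cc$K, 3L)
  expect_equal(cc$n, 2L); expect_equal(cc$N, 6L)
  expect_equal(cc$p, 0.2, tolerance = 1e-12)
  expect_equal(cc$p, oracle_hyper_upper(2, 3, 2, 6), tolerance = 1e-12)
  # a term absent from every hit scores p = 1 (singletons need min_term_count = 1)
  res_all <- term_overrepresentation(names6[1:2], tu, min_term_count = 1)
  expect_equal(res_all$p[res_all$term == "transport"], 1)
  # q-values are joint BH over all orders
  expect_equal(sort(res$q), sort(bh_fdr(res$p)))
  expect_error(term_overrepresentation("GO_NOT_THERE", tu),
               class = "comutkit_param_error")
})

test_that("singleton terms are skipped under min_term_count", {
  tu <- build_term_universe(c("GO_ALPHA_BETA", "GO_ALPHA_GAMMA"))
  res2 <- term_overrepresentation("GO_ALPHA_BETA", tu, min_term_count = 2)
  expect_equal(res2$term, "alpha")
  res1 <- term_overrepresentation("GO_ALPHA_BETA", tu, min_term_count = 1)
  expect_true(all(c("beta", "gamma", "alpha beta") %in% res1$term))
})

test_that("a strongly planted term is recovered; null corpora stay calibrated", {
  vocab <- gene_set_vocab()
  # a planted single word has no constituent terms that inherit its signal:
  # it must attain the smallest q outright
  top <- vapply(1:20, function(i) {
    corp <- gen_setname_corpus(vocab, 250, 5, "interferon",
                               hit_fraction = 0.1, enrichment_factor = 8,
                               background_rate = 0.05, seed = 300 + i)
    res <- term_overrepresentation(corp$hits, build_term_universe(corp$names))
    res$q[res$term == "interferon"] <= min(res$q) + 1e-12
  }, logical(1))
  expect_gte(mean(top), 0.95)

  # a planted trigram propagates every occurrence to its sub-n-grams, so
  # recovery means: nothing outranks it except its own constituents
  sub_terms <- c("response", "to", "virus", "response to", "to virus",
                 "response to virus")
  rec <- vapply(1:20, function(i) {
    corp <- gen_setname_corpus(vocab, 250, 5, "response to virus",
                               hit_fraction = 0.1, enrichment_factor = 8,
                               background_rate = 0.05, seed = 400 + i)
    res <- term_overrepresentation(corp$hits, build_term_universe(corp$names))
    q_pl <- res$q[res$term == "response to virus"]
    all(res$term[res$q < q_pl - 1e-12] %in% sub_terms)
  }, logical(1))
  expect_gte(mean(rec), 0.95)

  # with no planted enrichment the term's p-value is not anti-conservative
  pnull <- vapply(1:60, function(i) {
    corp <- gen_setname_corpus(vocab, 200, 5, "interferon",
                               hit_fraction = 0.1, enrichment_factor = 1,
                               background_rate = 0.08, seed = 700 + i)
    res <- term_overrepresentation(corp$hits, build_term_universe(corp$names))
    res$p[res$term == "interferon"]
  }, numeric(1))
  expect_lte(mean(pnull <= 0.05), 0.12)
  expect_gt(mean(pnull), 0.3)  # discrete upper-tail p is super-uniform
})
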