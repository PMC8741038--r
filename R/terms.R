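#' Tokenize a gene-set name into n-gram terms
#'
#' Strips a leading collection prefix (`GO_`, `HALLMARK_`, ... by default),
#' splits on underscores, lowercases, and forms all contiguous word runs of
#' length 1 to `max_order` (single words, doublets, triplets). Each term is
#' returned once even if it repeats within the name, so membership counting
#' is per-name.
#'
#' @param name Gene-set name, e.g. `"GO_RESPONSE_TO_VIRUS"`.
#' @param max_order Maximum n-gram length (default 3).
#' @param prefixes Collection prefixes stripped before tokenizing.
#' @return Character vector of unique terms (words joined by single spaces).
#' @export
tokenize_ngrams <- function(name, max_order = 3,
                            prefixes = c("GO_", "HALLMARK_", "KEGG_", "REACTOME_")) {
  check_count(max_order, "max_order")
  if (length(name) != 1L || is.na(name)) param_error("name must be a single string")
  stripped <- name
  for (p in prefixes) {
    if (startsWith(toupper(stripped), p)) {
      stripped <- substr(stripped, nchar(p) + 1L, nchar(stripped))
      break
    }
  }
  words <- tolower(strsplit(stripped, "_", fixed = TRUE)[[1L]])
  words <- words[nzchar(words)]
  if (!length(words)) param_error("name empty after prefix strip: ", name)
  terms <- character(0)
  for (ord in seq_len(min(max_order, length(words)))) {
    starts <- seq_len(length(words) - ord + 1L)
    terms <- c(terms, vapply(starts, function(s) {
      paste(words[s:(s + ord - 1L)], collapse = " ")
    }, character(1)))
  }
  unique(terms)
}

#' Build an n-gram term universe over gene-set names
#'
#' Tokenizes every name with [tokenize_ngrams()] and records, per term, which
#' names contain it. A name counts at most once per term.
#'
#' @param names Character vector of gene-set names (must be unique).
#' @param max_order Maximum n-gram length.
#' @param prefixes Passed to [tokenize_ngrams()].
#' @return A `term_universe`: list with `names`, `N` (universe size),
#'   `membership` (named list: term -> indices of names containing it), and
#'   `max_order`.
#' @export
build_term_universe <- function(names, max_order = 3,
                                prefixes = c("GO_", "HALLMARK_", "KEGG_", "REACTOME_")) {
  if (anyDuplicated(names)) param_error("gene-set names must be unique")
  tok <- lapply(names, tokenize_ngrams, max_order = max_order, prefixes = prefixes)
  idx <- rep(seq_along(names), lengths(tok))
  membership <- split(idx, unlist(tok))
  structure(list(names = names, N = length(names), membership = membership,
                 max_order = max_order),
            class = "term_universe")
}

#' @export
print.term_universe <- function(x, ...) {
  cat("Term universe:", length(x$membership), "n-gram terms (order <=",
      x$max_order, ") over", x$N, "set names\n")
  invisible(x)
}

#' N-gram term over-representation among hit gene-set names
#'
#' For every term of the universe (unigrams, bigrams and trigrams tested
#' jointly), computes the upper-tail hypergeometric probability that at
#' least `k` of the `n` hit names contain the term, given that `K` of the
#' `N` universe names do. Benjamini-Hochberg q-values are computed jointly
#' across all tested terms of all orders; raw p-values are also reported.
#' Terms contained in fewer than `min_term_count` universe names are
#' skipped.
#'
#' @param hit_names Character vector of hit set names, a subset of the
#'   universe names.
#' @param universe A `term_universe` from [build_term_universe()].
#' @param min_term_count Minimum universe membership for a term to be
#'   tested; default 2 (singleton terms are uninformative).
#' @return data.frame sorted by q then p: `term`, `order`, `k`, `K`, `n`,
#'   `N`, `p`, `q`.
#' @export
term_overrepresentation <- function(hit_names, universe, min_term_count = 2) {
  stopifnot(inherits(universe, "term_universe"))
  check_count(min_term_count, "min_term_count")
  hit_idx <- match(hit_names, universe$names)
  if (anyNA(hit_idx)) {
    param_error("hit name(s) absent from the universe: ",
                paste(utils::head(hit_names[is.na(hit_idx)], 5L), collapse = ", "))
  }
  memb <- universe$membership
  Kv <- lengths(memb)
  keep <- Kv >= min_term_count
  memb <- memb[keep]
  Kv <- Kv[keep]
  n <- length(hit_idx)
  N <- universe$N
  kv <- vapply(memb, function(m) sum(m %in% hit_idx), integer(1))
  p <- ifelse(kv == 0, 1, stats::phyper(kv - 1L, Kv, N - Kv, n, lower.tail = FALSE))
  out <- data.frame(term = names(memb),
                    order = lengths(strsplit(names(memb), " ", fixed = TRUE)),
                    k = kv, K = as.integer(Kv), n = n, N = N, p = p,
                    q = bh_fdr(p), row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$q, out$p, -out$k), , drop = FALSE]
}
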