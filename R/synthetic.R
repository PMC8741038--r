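## Synthetic-data generators. Each one plants a known effect (odds ratio,
## activation shift, overlap count, binding fraction) so the downstream
## statistic can be checked for exact recovery. Planted counts are
## deterministic (rounded), not binomially sampled. All generators are pure
## functions of (parameters, seed).

#' Solve the joint-alteration cell probability for a target odds ratio
#'
#' For a bivariate Bernoulli with marginals `p_a`, `p_b` and odds ratio
#' `theta`, the both-altered probability p11 is the admissible root of
#' `theta * (p_a - p11) * (p_b - p11) = p11 * (1 - p_a - p_b + p11)`,
#' i.e. of the quadratic
#' `(theta-1) p11^2 - [theta (p_a + p_b) + 1 - p_a - p_b] p11 + theta p_a p_b = 0`,
#' constrained to `[max(0, p_a + p_b - 1), min(p_a, p_b)]`.
#'
#' @param p_a,p_b Marginal alteration probabilities in (0, 1).
#' @param theta Target odds ratio, > 0.
#' @return Named numeric vector of cell probabilities `p11`, `p10`, `p01`, `p00`.
#' @export
solve_comut_cells <- function(p_a, p_b, theta) {
  check_prob(p_a, "p_a"); check_prob(p_b, "p_b")
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0) {
    param_error("theta must be a single finite number > 0")
  }
  lo <- max(0, p_a + p_b - 1)
  hi <- min(p_a, p_b)
  if (abs(theta - 1) < 1e-12) {
    p11 <- p_a * p_b
  } else {
    A <- theta - 1
    B <- -(theta * (p_a + p_b) + 1 - p_a - p_b)
    C <- theta * p_a * p_b
    disc <- B^2 - 4 * A * C
    if (disc < 0) param_error("no admissible joint probability for these parameters")
    roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
    ok <- roots >= lo - 1e-12 & roots <= hi + 1e-12
    if (!any(ok)) param_error("no admissible joint probability for these parameters")
    p11 <- min(max(roots[ok][1L], lo), hi)
  }
  cells <- c(p11 = p11, p10 = p_a - p11, p01 = p_b - p11, p00 = 1 - p_a - p_b + p11)
  if (any(cells < -1e-12)) param_error("no admissible joint probability for these parameters")
  pmax(cells, 0)
}

#' Simulate a binary alteration matrix with a planted odds ratio
#'
#' Draws `n_samples` i.i.d. bivariate alteration indicators for two genes
#' whose marginal alteration rates are `p_a` and `p_b` and whose population
#' odds ratio is exactly `theta` (cells solved in closed form by
#' [solve_comut_cells()]). Optional per-sample metadata fields are drawn from
#' categorical weight vectors, emulating cohort/histology/subtype labels.
#'
#' @param n_samples Number of samples to draw.
#' @param p_a,p_b Marginal alteration probabilities.
#' @param theta Target odds ratio.
#' @param genes Length-2 character vector naming the two genes.
#' @param metadata_spec Optional named list; each element is a named numeric
#'   vector of category weights, e.g.
#'   `list(histology = c(endometrioid = 0.75, serous = 0.2, mixed = 0.05))`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An `alteration_matrix` object (see [alteration_matrix()]).
#' @export
gen_alteration_matrix <- function(n_samples, p_a, p_b, theta,
                                  genes = c("GENE_A", "GENE_B"),
                                  metadata_spec = NULL, seed = NULL) {
  check_count(n_samples, "n_samples")
  if (length(genes) != 2L) param_error("genes must name exactly two genes")
  cells <- solve_comut_cells(p_a, p_b, theta)
  if (!is.null(seed)) set.seed(seed)
  draw <- sample.int(4L, n_samples, replace = TRUE, prob = cells)
  # categories: 1 = both, 2 = A only, 3 = B only, 4 = neither
  calls <- cbind(as.integer(draw %in% c(1L, 2L)), as.integer(draw %in% c(1L, 3L)))
  sample_ids <- sprintf("S%06d", seq_len(n_samples))
  dimnames(calls) <- list(sample_ids, genes)
  meta <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  if (!is.null(metadata_spec)) {
    for (field in names(metadata_spec)) {
      w <- metadata_spec[[field]]
      if (is.null(names(w)) || any(w < 0) || sum(w) <= 0) {
        param_error("metadata_spec$", field, " must be a named non-negative weight vector")
      }
      meta[[field]] <- sample(names(w), n_samples, replace = TRUE, prob = w / sum(w))
    }
  }
  alteration_matrix(calls, meta)
}

#' Simulate pathway activity scores with a planted activation shift
#'
#' Generates a pathway-by-sample score matrix for two sample groups (mutant
#' vs wild-type). All scores are i.i.d. Normal(0, `sigma`); for a
#' keyword-tagged subset of pathways the mutant-group mean is shifted by
#' `delta`, emulating coordinated activation of a named pathway family
#' (e.g. "p53" pathways) in mutant tumors. Tagged pathways embed the keyword
#' in their display name.
#'
#' @param n_pathways Total number of pathways.
#' @param n_mutant,n_wildtype Samples per group.
#' @param keyword Keyword embedded in tagged pathway names.
#' @param keyword_fraction Fraction of pathways tagged (count = `round`ed,
#'   at least 1).
#' @param delta Planted mean shift on tagged pathways in the mutant group.
#' @param sigma Score noise standard deviation, > 0.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `pathway_scores` object: list with `scores` (matrix), `group`
#'   (factor `mutant`/`wildtype` per column), `keyword`, and
#'   `keyword_idx` (planted tagged rows).
#' @export
gen_pathway_scores <- function(n_pathways = 2000, n_mutant = 30, n_wildtype = 30,
                               keyword = "p53", keyword_fraction = 36 / 2000,
                               delta = 0, sigma = 1, seed = NULL) {
  check_count(n_pathways, "n_pathways")
  check_count(n_mutant, "n_mutant"); check_count(n_wildtype, "n_wildtype")
  check_prob(keyword_fraction, "keyword_fraction")
  if (!is.numeric(sigma) || sigma <= 0) param_error("sigma must be > 0")
  if (!nzchar(keyword)) param_error("keyword must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  n_tag <- max(1L, as.integer(round(keyword_fraction * n_pathways)))
  tag_idx <- sort(sample.int(n_pathways, n_tag))
  nm <- sprintf("PW%05d_pathway", seq_len(n_pathways))
  nm[tag_idx] <- sprintf("PW%05d_%s_signaling", tag_idx, keyword)
  n_tot <- n_mutant + n_wildtype
  scores <- matrix(stats::rnorm(n_pathways * n_tot, sd = sigma), n_pathways, n_tot)
  scores[tag_idx, seq_len(n_mutant)] <- scores[tag_idx, seq_len(n_mutant)] + delta
  dimnames(scores) <- list(nm, c(sprintf("MUT%04d", seq_len(n_mutant)),
                                 sprintf("WT%04d", seq_len(n_wildtype))))
  group <- factor(rep(c("mutant", "wildtype"), c(n_mutant, n_wildtype)),
                  levels = c("mutant", "wildtype"))
  structure(list(scores = scores, group = group, keyword = keyword,
                 keyword_idx = tag_idx),
            class = "pathway_scores")
}

#' Simulate a pair of enrichment (NES) tables with planted quadrant structure
#'
#' Builds two per-gene-set NES tables over the same set ids, planting exact
#' counts of shared-upregulated, shared-downregulated and discordant sets
#' (counts are `floor(frac * m_sets)`). Enriched magnitudes are drawn as
#' `1 + Exponential(mean = nes_scale)` so they strictly exceed the |NES| > 1
#' enrichment threshold; all remaining sets draw NES from Uniform(-1, 1) and
#' are unenriched in both tables.
#'
#' @param m_sets Number of gene sets.
#' @param frac_shared_up,frac_shared_down,frac_discordant Planted fractions;
#'   non-negative, summing to at most 1.
#' @param nes_scale Mean of the exponential excess over 1.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return List with data.frames `table_a`, `table_b` (columns `set_id`,
#'   `nes`, `fdr`) and the planted counts `n_shared_up`, `n_shared_down`,
#'   `n_discordant`.
#' @export
gen_paired_enrichment_tables <- function(m_sets, frac_shared_up = 0,
                                         frac_shared_down = 0,
                                         frac_discordant = 0,
                                         nes_scale = 0.5, seed = NULL) {
  check_count(m_sets, "m_sets")
  fr <- c(frac_shared_up, frac_shared_down, frac_discordant)
  if (any(fr < 0)) param_error("planted fractions must be non-negative")
  if (sum(fr) > 1 + 1e-12) param_error("planted fractions sum to more than 1")
  if (!is.null(seed)) set.seed(seed)
  n_up <- as.integer(floor(frac_shared_up * m_sets))
  n_dn <- as.integer(floor(frac_shared_down * m_sets))
  n_dis <- as.integer(floor(frac_discordant * m_sets))
  ids <- sprintf("SET_%05d", seq_len(m_sets))
  ord <- sample.int(m_sets)
  up <- ord[seq_len(n_up)]
  dn <- ord[n_up + seq_len(n_dn)]
  dis <- ord[n_up + n_dn + seq_len(n_dis)]
  mag <- function(n) 1 + stats::rexp(n, rate = 1 / nes_scale)
  nes_a <- stats::runif(m_sets, -1, 1)
  nes_b <- stats::runif(m_sets, -1, 1)
  nes_a[up] <- mag(n_up);  nes_b[up] <- mag(n_up)
  nes_a[dn] <- -mag(n_dn); nes_b[dn] <- -mag(n_dn)
  dis_sign <- sample(c(-1, 1), n_dis, replace = TRUE)
  nes_a[dis] <- dis_sign * mag(n_dis)
  nes_b[dis] <- -dis_sign * mag(n_dis)
  enriched <- seq_len(m_sets) %in% c(up, dn, dis)
  fdr_of <- function(enr) ifelse(enr, stats::runif(m_sets, 0, 0.25),
                                 stats::runif(m_sets, 0.25, 1))
  list(table_a = data.frame(set_id = ids, nes = nes_a, fdr = fdr_of(enriched),
                            stringsAsFactors = FALSE),
       table_b = data.frame(set_id = ids, nes = nes_b, fdr = fdr_of(enriched),
                            stringsAsFactors = FALSE),
       n_shared_up = n_up, n_shared_down = n_dn, n_discordant = n_dis)
}

#' Simulate paired differential-expression tables with planted overlap
#'
#' Builds two DE tables over one expressed-gene universe, planting exactly
#' `n_shared` genes significant (FDR < 0.05) in both comparisons,
#' `n_unique_a`/`n_unique_b` significant in only one, and, among the shared
#' DE genes, exactly `round(concordant_fraction * n_shared)` with same-sign
#' log2 fold change. The three planted gene groups are disjoint.
#'
#' @param n_genes Universe size.
#' @param n_shared,n_unique_a,n_unique_b Planted DE-list structure.
#' @param concordant_fraction Fraction of shared DE genes with concordant
#'   fold-change direction, in \[0, 1\].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return List with data.frames `table_a`, `table_b`, character `universe`,
#'   and the planted `shared_genes` and `n_concordant`.
#' @export
gen_paired_de_tables <- function(n_genes, n_shared, n_unique_a, n_unique_b,
                                 concordant_fraction = 1, seed = NULL) {
  check_count(n_genes, "n_genes")
  check_count(n_shared, "n_shared", positive = FALSE)
  check_count(n_unique_a, "n_unique_a", positive = FALSE)
  check_count(n_unique_b, "n_unique_b", positive = FALSE)
  check_prob(concordant_fraction, "concordant_fraction", open = FALSE)
  if (n_shared + n_unique_a + n_unique_b > n_genes) {
    param_error("n_shared + n_unique_a + n_unique_b exceeds n_genes")
  }
  if (!is.null(seed)) set.seed(seed)
  universe <- sprintf("G%05d", seq_len(n_genes))
  ord <- sample(universe)
  shared <- ord[seq_len(n_shared)]
  only_a <- ord[n_shared + seq_len(n_unique_a)]
  only_b <- ord[n_shared + n_unique_a + seq_len(n_unique_b)]
  de_a <- c(shared, only_a)
  de_b <- c(shared, only_b)
  mk <- function(de_genes) {
    is_de <- universe %in% de_genes
    data.frame(gene = universe,
               log2fc = sample(c(-1, 1), n_genes, TRUE) *
                 ifelse(is_de, stats::runif(n_genes, 0.5, 4), stats::runif(n_genes, 0, 0.4)),
               fdr = ifelse(is_de, stats::runif(n_genes, 1e-8, 0.049),
                            stats::runif(n_genes, 0.051, 1)),
               stringsAsFactors = FALSE)
  }
  ta <- mk(de_a); tb <- mk(de_b)
  ## impose the planted direction structure on shared DE genes
  n_conc <- as.integer(round(concordant_fraction * n_shared))
  if (n_shared > 0L) {
    ia <- match(shared, ta$gene); ib <- match(shared, tb$gene)
    sgn <- sample(c(-1, 1), n_shared, replace = TRUE)
    ta$log2fc[ia] <- sgn * abs(ta$log2fc[ia])
    bsgn <- c(rep(1, n_conc), rep(-1, n_shared - n_conc)) * sgn
    tb$log2fc[ib] <- bsgn * abs(tb$log2fc[ib])
  }
  list(table_a = ta, table_b = tb, universe = universe,
       shared_genes = shared, n_concordant = n_conc)
}

#' Simulate a gene-set-name corpus with a planted enriched term
#'
#' Generates `n_sets` unique MSigDB-style set names (uppercased vocabulary
#' words joined by underscores, "GO_" prefix) and labels a fixed fraction as
#' "hits". The planted term (one or more contiguous vocabulary words) is
#' written into `round(enrichment_factor * background_rate * n_hits)` hit
#' names and `round(background_rate * n_background)` background names, i.e.
#' it occurs in hits at `enrichment_factor` times its background rate;
#' planted counts are deterministic. Names that would contain the full term
#' by chance are re-drawn, so term occurrences are exactly the planted ones.
#'
#' @param vocab Character vector of lowercase vocabulary words.
#' @param n_sets Number of set names.
#' @param words_per_name Words per generated name.
#' @param planted_term The term, e.g. `"response to virus"`; its words must
#'   be in `vocab` and fit within `words_per_name`.
#' @param hit_fraction Fraction of names labelled as hits.
#' @param enrichment_factor Fold over-representation of the term in hits
#'   (>= 1).
#' @param background_rate Background occurrence rate of the term among
#'   non-hit names.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return List with `names` (all set names), `hits` (hit-labelled names),
#'   and `planted_term`.
#' @export
gen_setname_corpus <- function(vocab, n_sets, words_per_name = 4,
                               planted_term, hit_fraction = 0.1,
                               enrichment_factor = 1, background_rate = 0.05,
                               seed = NULL) {
  check_count(n_sets, "n_sets"); check_count(words_per_name, "words_per_name")
  check_prob(hit_fraction, "hit_fraction")
  check_prob(background_rate, "background_rate")
  if (enrichment_factor < 1) param_error("enrichment_factor must be >= 1")
  term_words <- strsplit(planted_term, " ", fixed = TRUE)[[1L]]
  if (!all(term_words %in% vocab)) param_error("planted_term words must come from vocab")
  if (length(term_words) > words_per_name) param_error("planted_term longer than words_per_name")
  hit_rate <- enrichment_factor * background_rate
  if (hit_rate > 1) param_error("enrichment_factor * background_rate exceeds 1")
  if (!is.null(seed)) set.seed(seed)
  n_hits <- as.integer(round(hit_fraction * n_sets))
  if (n_hits < 1L || n_hits >= n_sets) param_error("hit_fraction leaves no hits or no background")
  k <- length(term_words)
  term_uc <- toupper(paste(term_words, collapse = "_"))
  contains_term <- function(nm) grepl(term_uc, nm, fixed = TRUE)
  draw_name <- function(with_term) {
    repeat {
      w <- sample(vocab, words_per_name, replace = TRUE)
      if (with_term) {
        pos <- sample.int(words_per_name - k + 1L, 1L)
        w[pos:(pos + k - 1L)] <- term_words
      }
      nm <- paste0("GO_", paste(toupper(w), collapse = "_"))
      if (contains_term(nm) == with_term) return(nm)
    }
  }
  n_bg <- n_sets - n_hits
  with_term <- c(seq_len(n_hits) <= round(hit_rate * n_hits),
                 seq_len(n_bg) <= round(background_rate * n_bg))
  names_out <- character(n_sets)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n_sets)) {
    attempts <- 0L
    repeat {
      nm <- draw_name(with_term[i])
      if (!exists(nm, envir = seen, inherits = FALSE)) {
        assign(nm, TRUE, envir = seen)
        break
      }
      attempts <- attempts + 1L
      if (attempts > 5000L) {
        param_error("cannot generate enough unique set names; ",
                    "increase vocab size or words_per_name")
      }
    }
    names_out[i] <- nm
  }
  ## shuffle within strata so hit labels are not positional
  hit_names <- sample(names_out[seq_len(n_hits)])
  list(names = sample(names_out), hits = hit_names, planted_term = planted_term)
}

#' Synthetic gene-set-name vocabulary
#'
#' A diverse word pool for [gen_setname_corpus()], built by crossing
#' biological prefixes with suffixes (400 distinct words) plus a few real
#' anchor words usable as planted terms. Real gene-set collections draw on
#' vocabularies of thousands of distinct words; a corpus generated from a
#' small vocabulary behaves very differently (accidental word collisions
#' inflate constituent n-grams), so the default pool is deliberately large.
#'
#' @param anchors Extra words prepended to the pool (deduplicated).
#' @return Character vector of lowercase words.
#' @export
gene_set_vocab <- function(anchors = c("response", "to", "virus", "interferon",
                                       "cell", "cycle")) {
  prefixes <- c("proto", "meta", "endo", "exo", "peri", "para", "epi", "hypo",
                "hyper", "inter", "intra", "trans", "sub", "super", "anti",
                "pro", "pre", "post", "iso", "neo")
  suffixes <- c("cyte", "some", "plast", "blast", "mere", "gen", "genic",
                "lysis", "lytic", "tropic", "phage", "philic", "phobic",
                "kinesis", "stasis", "plasia", "trophy", "genesis", "pathy",
                "osis")
  unique(c(anchors, paste0(rep(prefixes, each = length(suffixes)),
                           rep(suffixes, times = length(prefixes)))))
}

#' Simulate binding peaks and a TSS table with a planted bound fraction
#'
#' Lays `n_genes` transcription start sites on an evenly spaced grid across
#' `genome_span` bases of one chromosome and emits one peak per gene:
#' exactly `round(bound_fraction * n_genes)` genes get a peak whose center
#' falls within `d_prom` of their TSS; every other peak is placed at the
#' midpoint between neighbouring TSSs, at least `2 * d_prom` from every TSS.
#' Requires `genome_span >= 4 * d_prom * n_genes` so the separation holds.
#'
#' @param n_genes Number of genes/peaks.
#' @param bound_fraction Fraction of genes with promoter-proximal binding.
#' @param d_prom Promoter window half-width in bases (default 3000, the
#'   conventional +/- 3 kb promoter definition).
#' @param genome_span Chromosome length to spread the grid over.
#' @param peak_width Width of each emitted peak interval.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return List with `peaks` (BED-like data.frame), `tss` (gene/chrom/tss/
#'   strand data.frame), `bound_genes` (character), and `d_prom`.
#' @export
gen_peaks_tss <- function(n_genes, bound_fraction, d_prom = 3000,
                          genome_span = 6 * d_prom * n_genes,
                          peak_width = 200, seed = NULL) {
  check_count(n_genes, "n_genes")
  check_prob(bound_fraction, "bound_fraction", open = FALSE)
  if (genome_span < 4 * d_prom * n_genes) {
    param_error("genome_span too small: need >= 4 * d_prom * n_genes = ",
                4 * d_prom * n_genes)
  }
  if (!is.null(seed)) set.seed(seed)
  spacing <- floor(genome_span / n_genes)
  tss_pos <- as.integer((seq_len(n_genes) - 0.5) * spacing)
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  n_bound <- as.integer(round(bound_fraction * n_genes))
  bound_idx <- sort(sample.int(n_genes, n_bound))
  centers <- tss_pos + spacing %/% 2L            # midpoints: >= 2*d_prom from all TSSs
  centers[bound_idx] <- tss_pos[bound_idx] +
    as.integer(round(stats::runif(n_bound, -d_prom, d_prom)))
  half <- peak_width %/% 2L
  peaks <- data.frame(chrom = "chr1", start = centers - half,
                      end = centers + half, stringsAsFactors = FALSE)
  tss <- data.frame(gene = genes, chrom = "chr1", tss = tss_pos,
                    strand = sample(c("+", "-"), n_genes, replace = TRUE),
                    stringsAsFactors = FALSE)
  list(peaks = peaks, tss = tss, bound_genes = genes[bound_idx], d_prom = d_prom)
}
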