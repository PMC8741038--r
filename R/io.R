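#' Variant classes treated as non-silent
#'
#' The default functional-mutation vocabulary used when filtering MAF rows:
#' protein-altering SNVs and indels plus splice and translation-start events.
#' Silent/synonymous classes (`Silent`, `3'UTR`, ...) are excluded.
#'
#' @return Character vector of MAF `Variant_Classification` values.
#' @export
non_silent_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site")
}

#' Truncating variant classes
#'
#' Frameshift, nonsense and splice-site calls; the stricter filter used for
#' loss-of-function screens of chromatin remodelers such as ARID1A.
#'
#' @return Character vector of MAF `Variant_Classification` values.
#' @export
truncating_classes <- function() {
  c("Frame_Shift_Del", "Frame_Shift_Ins", "Nonsense_Mutation", "Splice_Site")
}

read_delim_checked <- function(path, required, what) {
  if (!file.exists(path)) format_error(what, " file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) format_error(what, " file unreadable: ", conditionMessage(e)))
  if (nrow(df) == 0L && ncol(df) == 0L) format_error(what, " file is empty: ", path)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    format_error(what, " file ", path, " is missing required column(s): ",
                 paste(missing, collapse = ", "))
  }
  df
}

#' Read a (subset) MAF mutation table
#'
#' Reads a tab-delimited somatic mutation table carrying at least the
#' `Hugo_Symbol`, `Variant_Classification` and `Tumor_Sample_Barcode` columns
#' (the subset of the MAF standard this pipeline consumes; extra columns are
#' ignored). Rows whose variant class is not in `included_classes` are
#' dropped. Sample barcodes are passed through unmodified; any truncation to
#' patient level is left to [truncate_barcodes()].
#'
#' @param path Path to a tab-delimited MAF file with a header row.
#' @param included_classes Variant classes to retain; defaults to the
#'   non-silent vocabulary of [non_silent_classes()]. Use `NULL` to keep all.
#' @return A data.frame of mutation calls with columns `sample_id`, `gene`,
#'   `variant_class`.
#' @export
read_maf <- function(path, included_classes = non_silent_classes()) {
  req <- c("Hugo_Symbol", "Variant_Classification", "Tumor_Sample_Barcode")
  df <- read_delim_checked(path, req, "MAF")
  if (nrow(df) == 0L) format_error("MAF file has a header but no rows: ", path)
  calls <- data.frame(sample_id = as.character(df$Tumor_Sample_Barcode),
                      gene = as.character(df$Hugo_Symbol),
                      variant_class = as.character(df$Variant_Classification),
                      stringsAsFactors = FALSE)
  if (any(!nzchar(calls$sample_id)) || any(!nzchar(calls$gene))) {
    format_error("MAF rows with empty Tumor_Sample_Barcode or Hugo_Symbol")
  }
  if (!is.null(included_classes)) {
    calls <- calls[calls$variant_class %in% included_classes, , drop = FALSE]
    rownames(calls) <- NULL
  }
  calls
}

#' Truncate TCGA-style barcodes to a fixed prefix length
#'
#' Barcode suffix depth differs between consortium files (sample vs aliquot
#' level); reconciling tables therefore often requires truncating to a common
#' prefix, e.g. 12 characters for TCGA patient codes.
#'
#' @param x Character vector of barcodes.
#' @param n Prefix length to keep; `NULL` returns `x` unchanged.
#' @return Character vector.
#' @export
truncate_barcodes <- function(x, n = NULL) {
  if (is.null(n)) return(x)
  check_count(n, "n")
  substr(x, 1L, n)
}

#' Read a GMT gene-set collection
#'
#' Each line is a set name, a description, and one or more gene symbols,
#' tab-delimited. Duplicate genes within a set are removed; set names are
#' preserved verbatim and genes compared case-sensitively.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (one per set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) format_error("GMT file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) format_error("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    format_error("GMT line ", bad[1L], " has fewer than 3 tab-delimited fields")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) {
    format_error("GMT contains duplicate set name(s): ",
                 paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  sets
}

#' Read BED3+ peak intervals
#'
#' First three columns (chrom, start, end) are required; coordinates are
#' 0-based half-open. Intervals with `start >= end` are rejected.
#'
#' @param path Path to a BED file (no header).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) format_error("BED file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                      comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) format_error("BED file unreadable: ", conditionMessage(e)))
  if (ncol(df) < 3L) format_error("BED file needs >= 3 columns, found ", ncol(df))
  out <- data.frame(chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end)) format_error("BED has non-integer coordinates")
  bad <- which(out$start >= out$end)
  if (length(bad)) {
    format_error("BED interval(s) with start >= end at row(s): ",
                 paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (any(out$start < 0L)) format_error("BED has negative start coordinate(s)")
  out
}

#' Read a TSS annotation table
#'
#' Tab-delimited with a header and columns `gene`, `chrom`, `tss` (0-based
#' point coordinate of the primary transcription start site) and `strand`.
#'
#' @param path Path to the TSS table.
#' @return data.frame with columns `gene`, `chrom`, `tss`, `strand`.
#' @export
read_tss <- function(path) {
  df <- read_delim_checked(path, c("gene", "chrom", "tss", "strand"), "TSS")
  out <- data.frame(gene = as.character(df$gene), chrom = as.character(df$chrom),
                    tss = as.integer(df$tss), strand = as.character(df$strand),
                    stringsAsFactors = FALSE)
  if (anyNA(out$tss) || any(out$tss < 0L)) format_error("TSS coordinates must be non-negative integers")
  bad <- setdiff(unique(out$strand), c("+", "-"))
  if (length(bad)) format_error("TSS table has unknown strand symbol(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(out$gene)) {
    format_error("TSS table has duplicate gene(s): ",
                 paste(unique(out$gene[duplicated(out$gene)]), collapse = ", "))
  }
  out
}

#' Read a differential-expression table
#'
#' Tab-delimited with header columns `gene`, `log2fc`, `fdr`.
#'
#' @param path Path to the table.
#' @return data.frame with those three columns.
#' @export
read_de_table <- function(path) {
  df <- read_delim_checked(path, c("gene", "log2fc", "fdr"), "DE")
  out <- data.frame(gene = as.character(df$gene),
                    log2fc = as.numeric(df$log2fc),
                    fdr = as.numeric(df$fdr), stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene)) {
    format_error("DE table has duplicate gene(s): ",
                 paste(unique(out$gene[duplicated(out$gene)]), collapse = ", "))
  }
  out
}

#' Read a per-comparison enrichment (NES) table
#'
#' Tab-delimited with header columns `set_id`, `nes`, `fdr`; one row per gene
#' set of one GSEA-style comparison. Set ids must be unique.
#'
#' @param path Path to the table.
#' @return data.frame with columns `set_id`, `nes`, `fdr`.
#' @export
read_nes_table <- function(path) {
  df <- read_delim_checked(path, c("set_id", "nes", "fdr"), "NES")
  out <- data.frame(set_id = as.character(df$set_id),
                    nes = as.numeric(df$nes),
                    fdr = as.numeric(df$fdr), stringsAsFactors = FALSE)
  dup <- unique(out$set_id[duplicated(out$set_id)])
  if (length(dup)) format_error("NES table has duplicate set_id(s): ", paste(dup, collapse = ", "))
  if (any(!is.finite(out$nes))) format_error("NES values must be finite")
  out
}

#' Read a pathway-by-sample score matrix
#'
#' Tab-delimited: first column pathway names, remaining columns one per
#' sample, header row of sample ids.
#'
#' @param path Path to the matrix file.
#' @return Numeric matrix with pathway rownames and sample colnames.
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) format_error("score matrix file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) format_error("score matrix needs a pathway column plus >= 1 sample column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write a table as TSV
#'
#' UTF-8, tab-separated, `.` decimal mark, no quoting, no row names; the
#' common exchange format of every writer in the pipeline. Numeric columns
#' round-trip through [read_de_table()] etc. at full double precision.
#'
#' @param x data.frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a score matrix as TSV
#'
#' @param m Numeric matrix with rownames (pathways) and colnames (samples).
#' @param path Output path.
#' @param id_col Name for the leading identifier column.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(m, path, id_col = "pathway") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  write_tsv(df, path)
}
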