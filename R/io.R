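#' Read an expression matrix from TSV or GCT
#'
#' TSV dialect: tab-delimited UTF-8, first column `gene_id`, remaining column
#' headers are sample IDs, one row per gene/probe. GCT 1.2 dialect: a `#1.2`
#' line, a `rows<TAB>cols` line, then a header of NAME, Description and the
#' sample IDs.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`.
#' @return a validated expression matrix (see [validate_expression_matrix]).
#' @export
read_expression <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  assert_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  if (format == "gct") {
    assert_that(length(lines) >= 3 && grepl("^#1\\.2", lines[[1]]),
                "not a GCT 1.2 file: missing '#1.2' header")
    dims <- as.integer(strsplit(lines[[2]], "\t", fixed = TRUE)[[1]][1:2])
    header <- strsplit(lines[[3]], "\t", fixed = TRUE)[[1]]
    samples <- header[-(1:2)]
    body <- lines[-(1:3)]
    id_col <- 1L; skip_cols <- 2L
    assert_that(length(body) == dims[[1]],
                sprintf("GCT declares %d rows but body has %d", dims[[1]], length(body)))
    assert_that(length(samples) == dims[[2]],
                sprintf("GCT declares %d columns but header has %d", dims[[2]], length(samples)))
  } else {
    assert_that(length(lines) >= 2, "expression TSV must have a header and at least one row")
    header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    samples <- header[-1]
    body <- lines[-1]
    id_col <- 1L; skip_cols <- 1L
  }
  assert_that(length(samples) >= 1, "no sample columns")
  dup <- samples[duplicated(samples)]
  assert_that(length(dup) == 0,
              paste0("duplicate sample IDs: ", paste(unique(dup), collapse = ", ")))
  cells <- strsplit(body, "\t", fixed = TRUE)
  genes <- vapply(cells, `[[`, character(1), id_col)
  assert_that(!anyDuplicated(genes),
              paste0("duplicate gene IDs: ",
                     paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (i in seq_along(cells)) {
    row <- cells[[i]]
    assert_that(length(row) == skip_cols + length(samples),
                sprintf("row '%s' has %d fields, expected %d", genes[[i]],
                        length(row), skip_cols + length(samples)))
    v <- suppressWarnings(as.numeric(row[-seq_len(skip_cols)]))
    if (anyNA(v)) {
      j <- which(is.na(v))[[1]]
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   row[skip_cols + j], genes[[i]], samples[[j]]), call. = FALSE)
    }
    vals[i, ] <- v
  }
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix to TSV or GCT
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip preserves them exactly.
#'
#' @param x expression matrix.
#' @param path output path.
#' @param format `"tsv"` or `"gct"`.
#' @export
write_expression <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  validate_expression_matrix(x)
  fmt_row <- function(i) paste(vapply(x[i, ], function(v)
    formatC(v, digits = 17, format = "g"), character(1)), collapse = "\t")
  rows <- vapply(seq_len(nrow(x)), fmt_row, character(1))
  if (format == "gct") {
    lines <- c("#1.2",
               paste(nrow(x), ncol(x), sep = "\t"),
               paste(c("NAME", "Description", colnames(x)), collapse = "\t"),
               paste(rownames(x), "na", rows, sep = "\t"))
  } else {
    lines <- c(paste(c("gene_id", colnames(x)), collapse = "\t"),
               paste(rownames(x), rows, sep = "\t"))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Columns: `sample_id`, `days_to_tumor_recurrence` (empty string or the
#' literal `null` encode a null entry, i.e. a patient who never improved
#' after therapy), optional `subtype`.
#'
#' @param path file path.
#' @return a clinical table (see [clinical_table]).
#' @export
read_clinical <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = TRUE)
  assert_that(all(c("sample_id", "days_to_tumor_recurrence") %in% names(df)),
              "clinical TSV needs columns sample_id, days_to_tumor_recurrence")
  days_raw <- trimws(df$days_to_tumor_recurrence)
  is_null <- !nzchar(days_raw) | tolower(days_raw) == "null" | is.na(days_raw)
  days <- rep(NA_integer_, nrow(df))
  if (any(!is_null)) {
    v <- suppressWarnings(as.numeric(days_raw[!is_null]))
    if (anyNA(v)) {
      bad <- days_raw[!is_null][is.na(v)][[1]]
      stop(sprintf("non-numeric days_to_tumor_recurrence entry '%s'", bad),
           call. = FALSE)
    }
    days[!is_null] <- as.integer(round(v))
  }
  subtype <- if ("subtype" %in% names(df)) df$subtype else
    rep("UNKNOWN", nrow(df))
  clinical_table(df$sample_id, days, subtype)
}

#' Write a clinical table to TSV
#'
#' Null days-to-recurrence entries are written as the literal `null`.
#' @param clinical a clinical table.
#' @param path output path.
#' @export
write_clinical <- function(clinical, path) {
  days <- ifelse(is.na(clinical$days_to_recurrence), "null",
                 as.character(clinical$days_to_recurrence))
  lines <- c("sample_id\tdays_to_tumor_recurrence\tsubtype",
             paste(clinical$sample_id, days, clinical$subtype, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a gene signature from a plain-text gene list
#'
#' One gene symbol per line; blank lines and lines starting with `#` are
#' ignored; symbols are whitespace-trimmed.
#'
#' @param path file path.
#' @param name signature name (default: file base name).
#' @param provenance free-text provenance note.
#' @return a [gene_signature].
#' @export
read_signature <- function(path, name = NULL, provenance = "") {
  assert_that(file.exists(path), paste0("file not found: ", path))
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  genes <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_signature(name %||% tools::file_path_sans_ext(basename(path)),
                 genes, provenance)
}

#' Read subtype centroids from TSV
#'
#' First column `gene_id`, then exactly four subtype columns of centroid
#' values.
#'
#' @param path file path.
#' @return a [subtype_centroids] matrix.
#' @export
read_centroids <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  assert_that(ncol(df) == 5, "centroid TSV needs gene_id plus 4 subtype columns")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  subtype_centroids(m)
}

#' Collapse probe-level rows to gene-level rows
#'
#' Multiple probes mapping to the same gene symbol are collapsed by the
#' per-sample arithmetic mean of their log2 values. Probes absent from the
#' mapping are dropped; the number dropped is reported via `message()`.
#'
#' @param x expression matrix with probe IDs in rows.
#' @param probe_to_gene named character vector: names are probe IDs, values
#'   gene symbols (matching is case-insensitive after trimming).
#' @return gene-level expression matrix.
#' @export
collapse_probes <- function(x, probe_to_gene) {
  validate_expression_matrix(x)
  assert_that(length(probe_to_gene) > 0, "empty probe-to-gene mapping")
  assert_that(!is.null(names(probe_to_gene)), "probe_to_gene must be named by probe ID")
  idx <- match_ids(rownames(x), names(probe_to_gene))
  dropped <- sum(is.na(idx))
  if (dropped > 0)
    message(sprintf("collapse_probes: dropped %d probe(s) absent from mapping", dropped))
  keep <- !is.na(idx)
  assert_that(any(keep), "no probes matched the mapping")
  x <- x[keep, , drop = FALSE]
  gene <- as.character(probe_to_gene)[idx[keep]]
  key <- norm_id(gene)
  first <- !duplicated(key)
  sums <- rowsum(x, group = key, reorder = FALSE)
  counts <- as.vector(table(factor(key, levels = rownames(sums))))
  out <- sums / counts
  rownames(out) <- gene[first][match(rownames(sums), key[first])]
  validate_expression_matrix(out)
  out
}

#' Restrict an expression matrix and clinical table to their shared samples
#'
#' Both are restricted to the intersection of their sample IDs, in the
#' matrix's column order; dropped-sample counts are reported via `message()`.
#'
#' @param x expression matrix.
#' @param clinical clinical table.
#' @return list with elements `expression` and `clinical`.
#' @export
align_samples <- function(x, clinical) {
  validate_expression_matrix(x)
  shared <- intersect(colnames(x), clinical$sample_id)
  assert_that(length(shared) > 0,
              "no shared samples between expression matrix and clinical table")
  d_expr <- ncol(x) - length(shared)
  d_clin <- nrow(clinical) - length(shared)
  if (d_expr > 0 || d_clin > 0)
    message(sprintf(
      "align_samples: dropped %d expression and %d clinical sample(s)",
      d_expr, d_clin))
  keep <- colnames(x)[colnames(x) %in% shared]
  list(expression = x[, keep, drop = FALSE],
       clinical = clinical[match(keep, clinical$sample_id), , drop = FALSE])
}
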