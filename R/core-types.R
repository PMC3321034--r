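#' Validate an expression matrix
#'
#' An expression matrix is a numeric genes x samples matrix of log2
#' normalized expression (RMA-style), with unique gene identifiers as row
#' names and unique sample identifiers as column names, and every value
#' finite.
#'
#' @param x object to validate.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(x) {
  assert_that(is.matrix(x) && is.numeric(x),
              "expression matrix must be a numeric matrix")
  assert_that(!is.null(rownames(x)) && !is.null(colnames(x)),
              "expression matrix must have gene row names and sample column names")
  assert_that(!anyDuplicated(rownames(x)),
              "duplicate gene identifiers in expression matrix")
  assert_that(!anyDuplicated(colnames(x)),
              "duplicate sample identifiers in expression matrix")
  assert_that(all(is.finite(x)),
              "expression matrix contains non-finite values")
  invisible(x)
}

#' Construct a clinical table
#'
#' Per-sample clinical annotation: days to tumor recurrence (the interval
#' from initial treatment to diagnosed recurrence after a period of
#' improvement), which is `NA` ("null") for patients who never improved
#' after therapy; a derived responder flag (`TRUE` iff days is non-null);
#' and an optional tumor subtype label.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param days_to_recurrence non-negative integer days, `NA` for null entries.
#' @param subtype one of Mesenchymal, Classical, Neural, Proneural, or
#'   `"UNKNOWN"`; defaults to all-unknown.
#' @return a `data.frame` with columns `sample_id`, `days_to_recurrence`,
#'   `responder`, `subtype`.
#' @export
clinical_table <- function(sample_id, days_to_recurrence,
                           subtype = rep("UNKNOWN", length(sample_id))) {
  sample_id <- as.character(sample_id)
  assert_that(!anyDuplicated(sample_id), "duplicate sample identifiers in clinical table")
  days <- suppressWarnings(as.integer(round(as.numeric(days_to_recurrence))))
  assert_that(length(days) == length(sample_id),
              "days_to_recurrence length mismatch")
  assert_that(all(is.na(days) | days >= 0), "negative days_to_recurrence")
  subtype <- as.character(subtype)
  subtype[is.na(subtype) | !nzchar(trimws(subtype))] <- "UNKNOWN"
  ok <- match_ids(subtype, c(GBM_SUBTYPES, "UNKNOWN"))
  assert_that(!anyNA(ok), paste0("unrecognized subtype label(s): ",
              paste(unique(subtype[is.na(ok)]), collapse = ", ")))
  subtype <- c(GBM_SUBTYPES, "UNKNOWN")[ok]
  data.frame(sample_id = sample_id,
             days_to_recurrence = days,
             responder = !is.na(days),
             subtype = subtype,
             stringsAsFactors = FALSE)
}

#' Construct a gene signature
#'
#' An ordered list of gene symbols defining a metagene.
#'
#' @param name signature name.
#' @param genes character vector of gene symbols, non-empty, no duplicates
#'   (compared case-insensitively after trimming).
#' @param provenance free-text provenance note.
#' @return an object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, provenance = "") {
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  assert_that(length(genes) > 0, "gene signature must be non-empty")
  assert_that(!anyDuplicated(norm_id(genes)),
              "duplicate genes in signature")
  structure(list(name = as.character(name), genes = genes,
                 provenance = as.character(provenance)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d genes\n", x$name, length(x$genes)))
  cat(" ", paste(utils::head(x$genes, 8), collapse = ", "),
      if (length(x$genes) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)

#' The 64-gene mesenchymal-transition (EMT) signature
#'
#' The Slug-based multi-cancer mesenchymal-transition signature: 64 gene
#' symbols (collapsed from the top 100 probe sets), shipped with the package
#' in signature rank order.
#'
#' @return a [gene_signature].
#' @export
emt_signature <- function() {
  path <- system.file("extdata", "emt_signature_64.txt", package = "mesrec",
                      mustWork = TRUE)
  read_signature(path, name = "mesenchymal_transition_64",
                 provenance = "Slug-based multi-cancer EMT signature (64 genes)")
}

#' Construct subtype centroids
#'
#' Classifier centroids: a genes x 4 matrix of mean expression per subtype.
#'
#' @param values numeric matrix, genes in rows, exactly four subtype columns.
#' @return the validated matrix, class `subtype_centroids`.
#' @export
subtype_centroids <- function(values) {
  assert_that(is.matrix(values) && is.numeric(values), "centroids must be a numeric matrix")
  assert_that(ncol(values) == 4, "centroids must have exactly 4 subtype columns")
  assert_that(!is.null(rownames(values)) && !anyDuplicated(rownames(values)),
              "centroids must have unique gene row names")
  assert_that(!is.null(colnames(values)) && !anyDuplicated(colnames(values)),
              "centroids must have unique subtype column names")
  assert_that(all(is.finite(values)), "centroids contain non-finite values")
  structure(values, class = c("subtype_centroids", class(values)))
}
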