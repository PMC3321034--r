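#' k-nearest-neighbour imputation of tumor subtype labels
#'
#' Expression is restricted to the subtype signature genes and each gene is
#' z-scored across all samples, so high-variance genes do not dominate the
#' Euclidean distance. Each unlabeled sample takes the majority label among
#' its `k` nearest labeled samples; vote ties are broken by the label of the
#' nearest neighbour carrying one of the tied labels. Distance ties are
#' broken by labeled sample ID, so assignments are deterministic and do not
#' depend on sample order. Given labels pass through unchanged.
#'
#' @param x expression matrix over all samples.
#' @param labeled named character vector mapping labeled sample IDs to
#'   subtype labels.
#' @param subtype_genes a [gene_signature] of subtype classifier genes
#'   (all four subtypes' gene lists jointly).
#' @param k number of neighbours (default 10).
#' @return `data.frame` with columns `sample_id`, `label`, `source`
#'   (`given`/`imputed`) and one `votes_<label>` column per label (vote
#'   counts sum to `k` for imputed samples, `NA` for given ones).
#' @export
knn_impute_subtypes <- function(x, labeled, subtype_genes, k = 10) {
  validate_expression_matrix(x)
  stopifnot(inherits(subtype_genes, "gene_signature"))
  assert_that(!is.null(names(labeled)) && length(labeled) > 0,
              "labeled must be a named sample -> label vector")
  lab_idx <- match(names(labeled), colnames(x))
  assert_that(!anyNA(lab_idx), "labeled sample(s) not in matrix")
  assert_that(length(labeled) >= k,
              sprintf("only %d labeled samples; reduce k (= %d)",
                      length(labeled), k))
  gidx <- match_ids(subtype_genes$genes, rownames(x))
  gidx <- gidx[!is.na(gidx)]
  assert_that(length(gidx) > 0, "no subtype genes found in matrix")

  z <- x[gidx, , drop = FALSE]
  mu <- rowMeans(z)
  sdev <- apply(z, 1, stats::sd)
  keep <- sdev > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d constant subtype gene(s)", sum(!keep)))
    assert_that(any(keep), "all subtype genes are constant")
  }
  z <- (z[keep, , drop = FALSE] - mu[keep]) / sdev[keep]

  labels <- as.character(labeled)
  label_set <- sort(unique(labels))
  samples <- colnames(x)
  is_lab <- samples %in% names(labeled)
  zl <- z[, lab_idx, drop = FALSE]
  lab_ids <- names(labeled)

  out_label <- character(length(samples))
  out_source <- ifelse(is_lab, "given", "imputed")
  votes <- matrix(NA_integer_, length(samples), length(label_set),
                  dimnames = list(samples, label_set))
  out_label[is_lab] <- labels[match(samples[is_lab], names(labeled))]

  for (i in which(!is_lab)) {
    d2 <- colSums((zl - z[, i])^2)
    ord <- order(d2, lab_ids)
    nn <- ord[seq_len(k)]
    v <- table(factor(labels[nn], levels = label_set))
    votes[i, ] <- as.integer(v)
    top <- label_set[v == max(v)]
    if (length(top) > 1) {
      ## nearest neighbour among those carrying a tied label decides
      first_tied <- nn[match(TRUE, labels[nn] %in% top)]
      top <- labels[first_tied]
    }
    out_label[i] <- top
  }
  out <- data.frame(sample_id = samples, label = out_label,
                    source = out_source, stringsAsFactors = FALSE)
  vd <- as.data.frame(votes)
  names(vd) <- paste0("votes_", label_set)
  rownames(out) <- NULL
  cbind(out, vd, row.names = NULL)
}
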