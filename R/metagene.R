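#' Compute metagene scores
#'
#' The metagene score of a sample is the unweighted mean of the log2
#' normalized expression of the signature genes found in the matrix (no
#' per-gene scaling), so the score lives on the same log2 scale as the
#' data. Signature genes absent from the matrix are counted and reported
#' via `message()`.
#'
#' @param x expression matrix.
#' @param signature a [gene_signature].
#' @return a named numeric vector of per-sample scores, class
#'   `metagene_scores`, with attributes `signature_name`, `n_genes_used`
#'   and `n_genes_missing`.
#' @export
compute_metagene <- function(x, signature) {
  validate_expression_matrix(x)
  stopifnot(inherits(signature, "gene_signature"))
  idx <- match_ids(signature$genes, rownames(x))
  n_missing <- sum(is.na(idx))
  assert_that(n_missing < length(signature$genes),
              sprintf("no genes of signature '%s' found in matrix", signature$name))
  if (n_missing > 0)
    message(sprintf("compute_metagene: %d of %d signature gene(s) not in matrix",
                    n_missing, length(signature$genes)))
  scores <- colMeans(x[idx[!is.na(idx)], , drop = FALSE])
  structure(scores,
            signature_name = signature$name,
            n_genes_used = length(signature$genes) - n_missing,
            n_genes_missing = n_missing,
            class = "metagene_scores")
}

#' @export
print.metagene_scores <- function(x, ...) {
  cat(sprintf("<metagene_scores> signature '%s': %d samples, %d gene(s) used, %d missing\n",
              attr(x, "signature_name"), length(x),
              attr(x, "n_genes_used"), attr(x, "n_genes_missing")))
  print(utils::head(unclass(x)), ...)
  invisible(x)
}

#' Build a signature by centroid-difference ranking
#'
#' Candidate genes are ranked by the difference between their centroid
#' component in the target subtype and the centroid component of the
#' remaining subtypes, descending; the top `top_k` are returned. The
#' "remaining" component is the mean of the other three centroids by
#' default; `rest = "overall_mean"` instead contrasts against the mean of
#' all four centroids (equivalent to the log-fold change between the
#' gene's target-subtype mean and its overall mean, up to a constant
#' factor). Ties are broken by lexicographically smaller gene symbol.
#'
#' @param centroids a [subtype_centroids] matrix.
#' @param target_subtype one of the centroid column names.
#' @param candidate_genes genes to rank (default: all centroid genes); must
#'   be a subset of the centroid genes.
#' @param top_k number of genes to keep.
#' @param rest how to summarize the non-target centroids.
#' @return a [gene_signature] of the `top_k` genes, in rank order.
#' @export
build_centroid_ranked_signature <- function(centroids, target_subtype,
                                            candidate_genes = NULL, top_k,
                                            rest = c("mean_others", "overall_mean")) {
  stopifnot(inherits(centroids, "subtype_centroids"))
  rest <- match.arg(rest)
  j <- match_ids(target_subtype, colnames(centroids))
  assert_that(!is.na(j), paste0("unknown subtype: ", target_subtype))
  candidate_genes <- candidate_genes %||% rownames(centroids)
  idx <- match_ids(candidate_genes, rownames(centroids))
  assert_that(!anyNA(idx), paste0("candidate gene(s) not in centroids: ",
              paste(candidate_genes[is.na(idx)], collapse = ", ")))
  assert_that(top_k >= 1 && top_k <= length(idx),
              "top_k must be between 1 and the number of candidates")
  target <- centroids[idx, j]
  other <- if (rest == "mean_others")
    rowMeans(centroids[idx, -j, drop = FALSE])
  else
    rowMeans(centroids[idx, , drop = FALSE])
  diff <- target - other
  genes <- rownames(centroids)[idx]
  ord <- order(-diff, genes)
  gene_signature(paste0(colnames(centroids)[j], "_centroid_top", top_k),
                 genes[ord][seq_len(top_k)],
                 provenance = sprintf("top %d by centroid difference (%s)", top_k, rest))
}
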