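# Fixtures are built in code; no binary data ships with the tests.

make_expr <- function(values, genes = NULL, samples = NULL) {
  m <- matrix(values, nrow = length(genes) %||% nrow(values))
  rownames(m) <- genes %||% sprintf("G%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("S%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Small signature of the first k EMT genes (keeps simulations light).
small_signature <- function(k = 5) {
  sig <- emt_signature()
  gene_signature("emt_head", sig$genes[seq_len(k)])
}

# Four well-separated subtype centroids over n_genes marker genes: each
# subtype overexpresses its own quarter of the genes by `sep`.
make_centroids <- function(n_genes = 40, sep = 2, baseline = 6) {
  stopifnot(n_genes %% 4 == 0)
  m <- matrix(baseline, n_genes, 4,
              dimnames = list(sprintf("ST%03d", seq_len(n_genes)),
                              c("Mesenchymal", "Classical", "Neural", "Proneural")))
  blk <- n_genes / 4
  for (j in 1:4) m[(j - 1) * blk + seq_len(blk), j] <- baseline + sep
  subtype_centroids(m)
}

# Brute-force oracle: number of k-subsets of {1..n} with sum <= s,
# by complete enumeration. Independent of the package's DP.
brute_subset_count <- function(n, k, s) {
  sum(colSums(utils::combn(n, k)) <= s)
}

# Scores that place a chosen set of samples at chosen ranks: sample i of
# `ids` gets score equal to its desired rank.
scores_with_ranks <- function(n, prefix = "P") {
  stats::setNames(seq_len(n), sprintf("%s%03d", prefix, seq_len(n)))
}
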