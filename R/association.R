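#' Pearson correlation with t-distribution p-value
#'
#' Sample Pearson correlation and the two-sided p-value from fitting
#' `t = r * sqrt((n - 2) / (1 - r^2))` to a t-distribution with `n - 2`
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (`n >= 3`), each with
#'   nonzero variance.
#' @return list with `r`, `p`, `t`, `df`, `n`.
#' @export
pearson_pvalue <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  n <- length(x)
  assert_that(n >= 3, "need n >= 3")
  assert_that(all(is.finite(x)) && all(is.finite(y)), "non-finite values")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "zero variance in x or y")
  r <- stats::cor(x, y)
  df <- n - 2
  if (abs(r) >= 1) {
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  list(r = r, p = p, t = t_stat, df = df, n = n)
}

#' Mutual information between two continuous variables (bits)
#'
#' Each variable is discretized into `bins` equal-frequency (quantile) bins
#' via ranks, making the estimate invariant under strictly monotone
#' transforms; the plug-in mutual information of the resulting contingency
#' table is computed in log base 2 and the Miller-Madow bias correction is
#' applied.
#'
#' @param x,y numeric vectors of equal length, `n >= 4 * bins`.
#' @param bins number of bins per variable (default 8).
#' @return mutual information in bits (non-negative up to the bias
#'   correction); a constant input yields 0 with a warning.
#' @export
mutual_information <- function(x, y, bins = 8) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  n <- length(x)
  assert_that(n >= 4 * bins, sprintf("need n >= 4 * bins = %d", 4 * bins))
  assert_that(all(is.finite(x)) && all(is.finite(y)), "non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; mutual information is 0")
    return(0)
  }
  bin_of <- function(v) ceiling(rank(v, ties.method = "first") * bins / n)
  tab <- table(bin_of(x), bin_of(y))
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log2(pxy[nz] / outer(px, py)[nz]))
  ## Miller-Madow: H_mm = H + (m - 1) / (2n) nats, applied to Hx + Hy - Hxy
  mm <- ((sum(px > 0) - 1) + (sum(py > 0) - 1) - (sum(nz) - 1)) /
    (2 * n * log(2))
  mi + mm
}

#' Rank all genes by mutual information with a target gene
#'
#' Mutual information (see [mutual_information]) of every other gene's
#' expression with the target gene's expression, sorted descending (ties
#' broken by gene ID). The target is excluded from its own ranking.
#'
#' @param x expression matrix.
#' @param target_gene gene ID present in the matrix.
#' @param bins bins for the MI estimator.
#' @return `data.frame` (`gene_id`, `score`) of class `gene_ranking` with
#'   attribute `score_kind = "mutual_information_bits"`.
#' @export
mi_rank_genes <- function(x, target_gene, bins = 8) {
  validate_expression_matrix(x)
  ti <- match_ids(target_gene, rownames(x))
  assert_that(!is.na(ti), paste0("target gene not in matrix: ", target_gene))
  others <- setdiff(seq_len(nrow(x)), ti)
  assert_that(length(others) > 0, "matrix has no genes besides the target")
  tgt <- x[ti, ]
  score <- vapply(others, function(g)
    suppressWarnings(mutual_information(x[g, ], tgt, bins)), numeric(1))
  ranking(rownames(x)[others], score, "mutual_information_bits")
}

#' Rank genes by linear fold change between two sample groups
#'
#' Per gene, the linear fold change `2 ^ (mean log2 in A - mean log2 in B)`,
#' sorted descending (ties broken by gene ID).
#'
#' @param x expression matrix (log2 values).
#' @param group_a,group_b disjoint non-empty sample ID sets.
#' @return `data.frame` (`gene_id`, `score`) of class `gene_ranking` with
#'   attribute `score_kind = "linear_fold_change"`.
#' @export
log2_fold_change_ranking <- function(x, group_a, group_b) {
  validate_expression_matrix(x)
  group_a <- unique(as.character(group_a))
  group_b <- unique(as.character(group_b))
  assert_that(length(group_a) > 0 && length(group_b) > 0,
              "both groups must be non-empty")
  assert_that(length(intersect(group_a, group_b)) == 0,
              "groups overlap")
  ia <- match(group_a, colnames(x)); ib <- match(group_b, colnames(x))
  assert_that(!anyNA(ia) && !anyNA(ib), "group sample(s) not in matrix")
  fc <- 2^(rowMeans(x[, ia, drop = FALSE]) - rowMeans(x[, ib, drop = FALSE]))
  ranking(rownames(x), unname(fc), "linear_fold_change")
}

ranking <- function(gene_id, score, kind) {
  out <- data.frame(gene_id = gene_id, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, score_kind = kind,
            class = c("gene_ranking", "data.frame"))
}

#' Hypergeometric gene-set enrichment (upper tail)
#'
#' The probability of observing at least `k` signature genes among a top
#' list of `n` genes drawn from a universe of `N` genes of which `K` belong
#' to the signature: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, by
#' exact summation of log-space binomial coefficients.
#'
#' @param N universe size.
#' @param K signature genes in the universe.
#' @param n list size.
#' @param k signature genes observed in the list.
#' @return object of class `enrichment_result`: `N`, `K`, `n`, `k`,
#'   `tail_p`.
#' @export
hypergeometric_enrichment <- function(N, K, n, k) {
  assert_that(all(c(N, K, n, k) == round(c(N, K, n, k))) &&
              all(c(N, K, n, k) >= 0), "counts must be non-negative integers")
  assert_that(K <= N && n <= N, "need K <= N and n <= N")
  assert_that(k <= min(K, n), "need k <= min(K, n)")
  assert_that(k >= max(0, n - (N - K)), "inconsistent counts: k below minimum overlap")
  i <- seq(k, min(K, n))
  tail_p <- if (k == 0) 1 else
    min(1, sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))))
  structure(list(N = N, K = K, n = n, k = k, tail_p = tail_p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> %d/%d list hits from %d/%d universe: P(X >= %d) = %.4g\n",
    x$k, x$n, x$K, x$N, x$k, x$tail_p))
  invisible(x)
}
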