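#' Rank samples by score
#'
#' Rank 1 is assigned to the smallest score (lowest expression), ascending.
#' Ties are broken by lexicographically smaller sample ID, so ranks are
#' always a permutation of `1..n`.
#'
#' @param scores named numeric vector (e.g. [compute_metagene] output).
#' @return named integer vector mapping sample ID to rank.
#' @export
rank_samples <- function(scores) {
  ids <- names(scores)
  assert_that(!is.null(ids) && !anyDuplicated(ids),
              "scores must be named by unique sample IDs")
  assert_that(length(scores) >= 2, "need at least 2 samples to rank")
  assert_that(all(is.finite(scores)), "non-finite score")
  ord <- order(unclass(scores), ids)
  ranks <- integer(length(scores))
  ranks[ord] <- seq_along(scores)
  names(ranks) <- ids
  ranks
}

#' Rank-sum statistic of a phenotype-defined sample subset
#'
#' After ranking all samples by a score, the statistic is the sum of the
#' ranks occupied by the phenotype subset. Low values mean the subset
#' concentrates at the low-expression end of the ranking.
#'
#' @param ranks named integer ranks from [rank_samples].
#' @param phenotype_set sample IDs forming the subset.
#' @return object of class `rank_sum_result` with fields `n`, `k`,
#'   `member_ranks` (ascending) and `rank_sum`.
#' @export
rank_sum_statistic <- function(ranks, phenotype_set) {
  phenotype_set <- unique(as.character(phenotype_set))
  assert_that(length(phenotype_set) > 0, "phenotype set is empty")
  idx <- match(phenotype_set, names(ranks))
  assert_that(!anyNA(idx), paste0("phenotype sample(s) not ranked: ",
              paste(phenotype_set[is.na(idx)], collapse = ", ")))
  member <- sort(unname(ranks[idx]))
  structure(list(n = length(ranks), k = length(member),
                 member_ranks = member, rank_sum = sum(member),
                 p_exact = NULL, p_mc = NULL, mc_se = NULL,
                 n_perm = NULL, seed = NULL),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("<rank_sum_result> n = %d, k = %d\n", x$n, x$k))
  cat("  member ranks:", paste(x$member_ranks, collapse = " + "),
      "=", x$rank_sum, "\n")
  if (!is.null(x$p_exact))
    cat(sprintf("  exact P(R <= %d) = %.6g\n", x$rank_sum, x$p_exact))
  if (!is.null(x$p_mc))
    cat(sprintf("  Monte-Carlo P = %.6g (SE %.2g, %g draws, seed %d)\n",
                x$p_mc, x$mc_se, x$n_perm, x$seed))
  invisible(x)
}

#' Select samples with long time to recurrence
#'
#' Responders (non-null days to recurrence) whose recurrence occurred more
#' than `threshold_days` after initial treatment. The default threshold is
#' three years (3 x 365 = 1095 days).
#'
#' @param clinical clinical table.
#' @param threshold_days strict lower bound in days.
#' @return character vector of sample IDs (possibly empty).
#' @export
select_long_recurrence <- function(clinical, threshold_days = 1095) {
  assert_that(nrow(clinical) > 0, "clinical table is empty")
  sel <- clinical$responder & !is.na(clinical$days_to_recurrence) &
    clinical$days_to_recurrence > threshold_days
  out <- clinical$sample_id[sel]
  if (length(out) == 0)
    message(sprintf("select_long_recurrence: no responder beyond %d days",
                    threshold_days))
  out
}

#' Count k-subsets of 1..n with bounded sum (exact null)
#'
#' Exact count of k-element subsets of `{1, ..., n}` whose element sum is
#' at most `s`, by integer dynamic programming. All intermediate counts are
#' integers held exactly in doubles; an error is raised if `choose(n, k)`
#' exceeds 2^53, beyond which exactness cannot be guaranteed.
#'
#' @param n universe size.
#' @param k subset size.
#' @param s sum bound (inclusive).
#' @return the exact count, as a double holding an integer.
#' @export
exact_null_count <- function(n, k, s) {
  assert_that(length(n) == 1 && length(k) == 1 && length(s) == 1 &&
              n == round(n) && k == round(k) && s == round(s),
              "n, k, s must be scalar integers")
  assert_that(k >= 1 && k <= n, "need 1 <= k <= n")
  assert_that(s >= 0, "need s >= 0")
  assert_that(choose(n, k) < 2^53,
              "choose(n, k) exceeds 2^53; exact integer counting not possible in doubles")
  s_min <- k * (k + 1) / 2
  s_max <- k * n - k * (k - 1) / 2
  if (s < s_min) return(0)
  s <- min(s, s_max)
  ## f[j+1, t+1] = number of subsets of {1..i} with j elements summing to t
  f <- matrix(0, nrow = k + 1, ncol = s + 1)
  f[1, 1] <- 1
  for (i in seq_len(min(n, s))) {
    for (j in seq(k, 1)) {
      tmax <- s - i
      if (tmax >= (j - 1) * j / 2) # room for the j-1 smaller distinct elements
        f[j + 1, (i:(tmax + i)) + 1] <- f[j + 1, (i:(tmax + i)) + 1] +
          f[j, (0:tmax) + 1]
    }
  }
  sum(f[k + 1, ])
}

#' Exact tail probability of the rank-sum null
#'
#' The probability that `k` distinct ranks drawn uniformly from `{1..n}`
#' sum to at most `s`: [exact_null_count]`(n, k, s) / choose(n, k)`,
#' computed with exact integer arithmetic and converted to a probability
#' once.
#'
#' @inheritParams exact_null_count
#' @return probability in `[0, 1]`.
#' @export
exact_null_pvalue <- function(n, k, s) {
  exact_null_count(n, k, s) / choose(n, k)
}

#' Monte-Carlo permutation tail probability of the rank-sum null
#'
#' Each replicate draws `k` distinct ranks uniformly from `{1..n}` (a
#' random permutation of the phenotype labels) and the estimate is the
#' fraction of replicates whose sum is at most `observed_R`.
#'
#' @param n number of ranked samples.
#' @param k phenotype subset size.
#' @param observed_R observed rank sum.
#' @param n_perm number of replicates (default ten million).
#' @param seed RNG seed (required, for reproducibility).
#' @return list with `estimate`, `mc_se` (binomial standard error),
#'   `n_perm`, `seed`.
#' @export
permutation_pvalue <- function(n, k, observed_R, n_perm = 1e7, seed) {
  assert_that(k >= 1 && k <= n, "need 1 <= k <= n")
  assert_that(n_perm >= 1, "need n_perm >= 1")
  assert_that(!missing(seed), "seed is required")
  hits <- with_seed(seed, perm_tail_hits(as.integer(n), as.integer(k),
                                         as.numeric(observed_R),
                                         as.numeric(n_perm)))
  est <- hits / n_perm
  list(estimate = est,
       mc_se = sqrt(est * (1 - est) / n_perm),
       n_perm = n_perm, seed = seed)
}

#' Full rank-sum association test
#'
#' Convenience wrapper: ranks the samples, computes the phenotype subset's
#' rank sum, and attaches the exact tail probability and (optionally) a
#' seeded Monte-Carlo permutation estimate. The tail is one-sided toward
#' low rank sums, matching the hypothesis that absence of expression
#' accompanies long time to recurrence.
#'
#' @param scores named numeric scores (metagene or single gene).
#' @param phenotype_set sample IDs of the phenotype subset.
#' @param n_perm Monte-Carlo replicates; `NULL` (default) skips the
#'   permutation estimate.
#' @param seed RNG seed for the permutation estimate.
#' @return a `rank_sum_result` with `p_exact` (and `p_mc`, `mc_se` if
#'   requested) filled in.
#' @export
rank_sum_test <- function(scores, phenotype_set, n_perm = NULL, seed = 1L) {
  ranks <- rank_samples(scores)
  res <- rank_sum_statistic(ranks, phenotype_set)
  if (choose(res$n, res$k) < 2^53) {
    res$p_exact <- exact_null_pvalue(res$n, res$k, res$rank_sum)
  } else {
    message(sprintf(paste0(
      "rank_sum_test: choose(%d, %d) exceeds 2^53, skipping the exact ",
      "integer null; use the Monte-Carlo estimate"), res$n, res$k))
    res$p_exact <- NA_real_
  }
  if (!is.null(n_perm)) {
    mc <- permutation_pvalue(res$n, res$k, res$rank_sum, n_perm, seed)
    res$p_mc <- mc$estimate
    res$mc_se <- mc$mc_se
    res$n_perm <- n_perm
    res$seed <- seed
  }
  res
}

#' Genome-wide single-gene rank-sum scan
#'
#' For every gene in the matrix, samples are ranked by that gene's
#' expression (same ascending order and sample-ID tie rule as
#' [rank_samples]) and the phenotype subset's rank sum is recorded. The
#' result is sorted ascending by rank sum, then by gene ID, so the most
#' phenotype-associated genes come first.
#'
#' @param x expression matrix (restrict its columns to the phenotyped
#'   samples before scanning, e.g. with [align_samples]).
#' @param phenotype_set sample IDs of the phenotype subset.
#' @return `data.frame` with columns `gene_id`, `rank_sum`, class
#'   `scan_result`.
#' @export
genome_wide_scan <- function(x, phenotype_set) {
  validate_expression_matrix(x)
  phenotype_set <- unique(as.character(phenotype_set))
  idx <- match(phenotype_set, colnames(x))
  assert_that(length(idx) > 0 && !anyNA(idx),
              "phenotype set must be non-empty and within matrix samples")
  n <- ncol(x)
  id_ord <- rank(colnames(x), ties.method = "first") # lexicographic tie-break
  rs <- numeric(nrow(x))
  ranks <- integer(n)
  for (g in seq_len(nrow(x))) {
    ord <- order(x[g, ], id_ord)
    ranks[ord] <- seq_len(n)
    rs[g] <- sum(ranks[idx])
  }
  out <- data.frame(gene_id = rownames(x), rank_sum = rs,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank_sum, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scan_result", "data.frame")
  out
}
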