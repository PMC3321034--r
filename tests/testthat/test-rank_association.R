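test_that("rank_samples assigns ascending ranks with sample-ID tie-break", {
  expect_identical(rank_samples(c(A = 0.1, B = 0.5, C = 0.3)),
                   c(A = 1L, B = 3L, C = 2L))
  expect_identical(rank_samples(c(B = 1, A = 1)), c(B = 2L, A = 1L))
  expect_error(rank_samples(c(A = 1, B = NaN)), "non-finite")
  # ranks are always a permutation of 1..n
  for (seed in 1:5) {
    set.seed(seed)
    s <- stats::setNames(rnorm(20), sample(sprintf("x%02d", 1:20)))
    expect_identical(sort(unname(rank_samples(s))), 1:20)
  }
})

test_that("rank_sum_statistic sums the subset's ranks", {
  # the worked example: members at ranks 1,2,6,7,9,11,16,18 of 99
  scores <- scores_with_ranks(99)
  members <- names(scores)[c(1, 2, 6, 7, 9, 11, 16, 18)]
  res <- rank_sum_statistic(rank_samples(scores), members)
  expect_identical(res$rank_sum, 70L)
  expect_identical(res$member_ranks, c(1L, 2L, 6L, 7L, 9L, 11L, 16L, 18L))
  expect_identical(res$n, 99L)
  expect_identical(res$k, 8L)

  # subset occupying the k lowest ranks attains the minimum k(k+1)/2
  res_min <- rank_sum_statistic(rank_samples(scores), names(scores)[1:5])
  expect_identical(res_min$rank_sum, 15L)

  s5 <- scores_with_ranks(5)
  res5 <- rank_sum_statistic(rank_samples(s5), names(s5)[c(2, 5)])
  expect_identical(res5$rank_sum, 7L)

  expect_error(rank_sum_statistic(rank_samples(s5), "nope"), "not ranked")
})

test_that("select_long_recurrence keeps responders beyond the threshold", {
  cl <- clinical_table(c("a", "b", "c", "d"), c(100, 1100, NA, 2000))
  expect_identical(select_long_recurrence(cl), c("b", "d"))
  expect_identical(select_long_recurrence(cl, threshold_days = 0),
                   c("a", "b", "d"))
  cl_null <- clinical_table(c("a", "b"), c(NA, NA))
  expect_message(out <- select_long_recurrence(cl_null), "no responder")
  expect_length(out, 0)
})

test_that("exact_null_count matches brute-force enumeration on small universes", {
  expect_equal(exact_null_count(4, 2, 3), 1)   # only {1,2}
  expect_equal(exact_null_count(5, 2, 5), 4)   # {1,2},{1,3},{1,4},{2,3}
  expect_equal(exact_null_count(99, 8, 35), 0) # below the minimum sum 36
  for (n in c(6, 9, 12)) {
    for (k in c(1, 2, 3, n - 1)) {
      sums <- colSums(rbind(utils::combn(n, k)))
      for (s in seq(min(sums) - 1, max(sums) + 1, by = 3))
        expect_equal(exact_null_count(n, k, s), sum(sums <= s))
    }
  }
  expect_error(exact_null_count(5, 6, 10), "k <= n")
  expect_error(exact_null_count(5, 2, -1), "s >= 0")
})

test_that("exact_null_pvalue is a proper nondecreasing tail with known endpoints", {
  expect_equal(exact_null_pvalue(99, 8, 36), 1 / choose(99, 8))
  expect_equal(exact_null_pvalue(4, 2, 3), 1 / 6)
  n <- 12; k <- 4
  s_max <- k * n - k * (k - 1) / 2
  p <- vapply(seq(k * (k + 1) / 2, s_max), function(s) exact_null_pvalue(n, k, s),
              numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_equal(p[length(p)], 1)
  # symmetry of the null: count(s) = C(n,k) - count(S_max + S_min - s - 1)
  s_min <- k * (k + 1) / 2
  for (s in seq(s_min, s_max, by = 2))
    expect_equal(exact_null_count(n, k, s),
                 choose(n, k) - exact_null_count(n, k, s_max + s_min - s - 1))
})

test_that("permutation estimator is seeded, bounded, and converges to the exact null", {
  mc1 <- permutation_pvalue(10, 3, 6, n_perm = 1e6, seed = 42)
  mc2 <- permutation_pvalue(10, 3, 6, n_perm = 1e6, seed = 42)
  expect_identical(mc1$estimate, mc2$estimate)
  expect_lt(abs(mc1$estimate - 1 / choose(10, 3)), 3 * mc1$mc_se + 1e-12)

  # maximum rank sum: every permutation is a hit
  mc_max <- permutation_pvalue(10, 3, 10 + 9 + 8, n_perm = 1e4, seed = 1)
  expect_identical(mc_max$estimate, 1)

  # convergence to the exact null on a (n, k, s) grid
  for (case in list(c(20, 4, 30), c(50, 5, 80), c(15, 7, 50))) {
    ex <- exact_null_pvalue(case[1], case[2], case[3])
    mc <- permutation_pvalue(case[1], case[2], case[3], n_perm = 2e5, seed = 99)
    expect_lt(abs(mc$estimate - ex), 3 * sqrt(ex * (1 - ex) / 2e5) + 1e-12)
  }
})

test_that("rank_sum_test combines statistic, exact tail, and Monte-Carlo tail", {
  scores <- scores_with_ranks(30)
  res <- rank_sum_test(scores, names(scores)[1:4], n_perm = 1e5, seed = 3)
  expect_identical(res$rank_sum, 10L)
  expect_equal(res$p_exact, 1 / choose(30, 4))
  expect_lt(abs(res$p_mc - res$p_exact), 3 * res$mc_se + 1e-12)
})

test_that("genome-wide scan ranks a phenotype-matched gene first", {
  # gene 'hit' decreases with days to recurrence, so the two longest-recurrence
  # samples take its two lowest values: rank sum 1 + 2 = 3, the minimum.
  days <- c(s1 = 10, s2 = 2000, s3 = 50, s4 = 1500, s5 = 200)
  x <- rbind(hit = -days / 1000,
             bg1 = c(3, 1, 4, 7, 5),
             bg2 = c(9, 2, 6, 5, 3),
             bg3 = c(5, 8, 7, 2, 6))
  colnames(x) <- names(days)
  subset <- c("s2", "s4")
  scan <- genome_wide_scan(x, subset)
  expect_identical(scan$gene_id[1], "hit")
  expect_equal(scan$rank_sum[scan$gene_id == "hit"], 3)

  # brute-force verification of every gene's rank sum
  for (g in rownames(x)) {
    ord <- order(x[g, ], colnames(x))
    ranks <- integer(5); ranks[ord] <- 1:5
    expect_equal(scan$rank_sum[scan$gene_id == g],
                 sum(ranks[match(subset, colnames(x))]))
  }
})

test_that("scan handles constant genes and single-gene matrices deterministically", {
  x <- make_expr(rep(1, 4), genes = "flat", samples = c("d", "c", "b", "a"))
  scan <- genome_wide_scan(x, c("a", "b"))
  # all-tied expression: ranks follow sample-ID order a<b<c<d
  expect_equal(scan$rank_sum, 3)
  expect_identical(nrow(scan), 1L)
})
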