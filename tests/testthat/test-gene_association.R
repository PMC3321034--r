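test_that("pearson p-value follows the t-distribution formula", {
  # perfect linearity
  x <- 1:10
  res <- pearson_pvalue(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)

  # brute-force arithmetic oracle on a 3-point fixture
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_oracle <- r_oracle * sqrt(1 / (1 - r_oracle^2))
  res <- pearson_pvalue(x, y)
  expect_equal(res$r, r_oracle)
  expect_equal(res$p, 2 * stats::pt(-abs(t_oracle), df = 1))
  # library cross-check
  ct <- stats::cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$p, ct$p.value)

  expect_error(pearson_pvalue(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_pvalue(1:3, 1:4), "equal length")
})

test_that("pearson p-values are uniform under independence", {
  set.seed(5)
  p <- replicate(200, pearson_pvalue(rnorm(200), rnorm(200))$p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("mutual information matches closed forms and is bias-corrected", {
  set.seed(10)
  x <- rnorm(10000)
  # identical variables: diagonal contingency table, MI -> log2(8) = 3 bits
  expect_lt(abs(mutual_information(x, x) - 3), 0.1)
  # independent variables: near zero after Miller-Madow correction
  expect_lt(mutual_information(x, rnorm(10000)), 0.05)
  # constant input
  expect_warning(mi0 <- mutual_information(x, rep(1, 10000)), "constant")
  expect_identical(mi0, 0)
  expect_error(mutual_information(1:10, 1:10), "n >= 4")
})

test_that("mutual information is symmetric and rank-invariant", {
  set.seed(11)
  x <- rnorm(500); y <- x + rnorm(500)
  expect_equal(mutual_information(x, y), mutual_information(y, x))
  # strictly monotone transforms leave quantile bins unchanged
  expect_equal(mutual_information(exp(x), y), mutual_information(x, y))
  expect_equal(mutual_information(x, y^3 + 2 * y), mutual_information(x, y))
})

test_that("plug-in MI of the binned table matches a direct entropy oracle", {
  set.seed(12)
  x <- rnorm(400); y <- x + rnorm(400, sd = 0.5)
  bins <- 8; n <- length(x)
  b <- function(v) ceiling(rank(v, ties.method = "first") * bins / n)
  tab <- table(b(x), b(y)) / n
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  mi_plug <- H(rowSums(tab)) + H(colSums(tab)) - H(tab)
  mm <- ((sum(rowSums(tab) > 0) - 1) + (sum(colSums(tab) > 0) - 1) -
           (sum(tab > 0) - 1)) / (2 * n * log(2))
  expect_equal(mutual_information(x, y), mi_plug + mm)
})

test_that("MI ranking puts coexpressed signature genes above background", {
  sig <- small_signature(6)
  p <- sim_params(n_samples = 300, n_background_genes = 30, signature = sig,
                  loadings = rep(2.5, 6), noise_sd = 0.5, seed = 14)
  co <- simulate_cohort(p)
  rk <- mi_rank_genes(co$expression, sig$genes[1])
  expect_false(sig$genes[1] %in% rk$gene_id)   # target excluded
  expect_identical(nrow(rk), nrow(co$expression) - 1L)
  expect_true(all(rk$gene_id[1:5] %in% sig$genes[-1]))
  expect_identical(attr(rk, "score_kind"), "mutual_information_bits")

  x2 <- co$expression[1:2, ]
  rk2 <- mi_rank_genes(x2, rownames(x2)[1])
  expect_identical(nrow(rk2), 1L)
  expect_error(mi_rank_genes(co$expression, "NOPE"), "target gene")
})

test_that("fold-change ranking reports linear ratios of group means", {
  x <- make_expr(c(5, 2, 5, 2, 3, 2, 3, 2), genes = c("up", "flat"),
                 samples = c("a1", "a2", "b1", "b2"))
  rk <- log2_fold_change_ranking(x, c("a1", "a2"), c("b1", "b2"))
  expect_equal(rk$score[rk$gene_id == "up"], 4)    # 2^(5-3)
  expect_equal(rk$score[rk$gene_id == "flat"], 1)  # identical groups
  # reciprocal under group exchange
  rk_rev <- log2_fold_change_ranking(x, c("b1", "b2"), c("a1", "a2"))
  m <- match(rk$gene_id, rk_rev$gene_id)
  expect_equal(rk$score, 1 / rk_rev$score[m])
  expect_error(log2_fold_change_ranking(x, c("a1", "b1"), c("b1", "b2")),
               "overlap")
})

test_that("signature genes dominate fold-change ranking between activity groups", {
  sig <- small_signature(6)
  p <- sim_params(n_samples = 200, n_background_genes = 40, signature = sig,
                  loadings = rep(2, 6), noise_sd = 0.5, seed = 15)
  co <- simulate_cohort(p)
  m <- co$truth$latent_activity
  hi <- names(m)[m > 0.8]; lo <- names(m)[m < 0.2]
  rk <- log2_fold_change_ranking(co$expression, hi, lo)
  expect_true(all(rk$gene_id[1:6] %in% sig$genes))
})

test_that("hypergeometric tail agrees with complete enumeration and phyper", {
  # N=10, K=4, n=3, k=3: C(4,3)/C(10,3) = 1/30
  expect_equal(hypergeometric_enrichment(10, 4, 3, 3)$tail_p, 1 / 30)
  expect_equal(hypergeometric_enrichment(10, 4, 3, 0)$tail_p, 1)

  # complete enumeration oracle on a small universe: draw every n-subset
  N <- 11; K <- 4; n <- 5
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K) # first K elements are the signature
  for (k in 0:min(K, n))
    expect_equal(hypergeometric_enrichment(N, K, n, k)$tail_p,
                 mean(hits >= k))

  # library cross-check across a grid, and monotonicity in k
  for (N in c(15, 25)) {
    K <- 6; n <- 8
    p <- vapply(0:min(K, n), function(k)
      hypergeometric_enrichment(N, K, n, k)$tail_p, numeric(1))
    expect_equal(p, stats::phyper(-1:(min(K, n) - 1), K, N - K, n,
                                  lower.tail = FALSE))
    expect_true(all(diff(p) <= 1e-15))
  }

  expect_error(hypergeometric_enrichment(10, 4, 3, 4), "k <= min")
  expect_error(hypergeometric_enrichment(10, 12, 3, 1), "K <= N")
})
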