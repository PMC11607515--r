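test_that("wilcoxon rank-sum matches the exact permutation distribution", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)  # 2/20 rank assignments at complete separation
  expect_equal(r$direction, 1L)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$direction, 0L)
  # exact branch agrees with R's exact test on tie-free small samples
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(4); y <- rnorm(5)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 wilcox.test(y, x, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # large-sample branch agrees with R's normal approximation
  set.seed(6)
  for (i in 1:10) {
    x <- rnorm(25); y <- rnorm(30, 0.3)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 wilcox.test(y, x, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("Welch t-test reproduces the definitional statistic", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
  r <- t_test_welch(x, y)
  tdef <- (mean(y) - mean(x)) / sqrt(var(x) / 4 + var(y) / 4)
  expect_equal(r$statistic, tdef, tolerance = 1e-12)
  expect_equal(r$p_value, t.test(y, x)$p.value, tolerance = 1e-12)
  expect_equal(t_test_welch(x, x)$p_value, 1)
  # separation limit: p shrinks as the shift grows
  set.seed(1)
  base <- rnorm(6, sd = 1e-3)
  p1 <- t_test_welch(base, base + 1)$p_value
  p2 <- t_test_welch(base, base + 10)$p_value
  expect_lt(p2, p1)
})

test_that("Kruskal-Wallis reproduces the rank formula and base R", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  r <- kruskal_wallis(g)
  expect_equal(r$statistic, unname(kruskal.test(g)$statistic),
               tolerance = 1e-12)
  expect_equal(r$p_value, kruskal.test(g)$p.value, tolerance = 1e-12)
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1), c(1, 1)))$p_value, 1)
  set.seed(2)
  g2 <- list(rnorm(8), rnorm(7), c(rnorm(5), rnorm(3)))  # with ties below
  g2 <- lapply(g2, round, digits = 1)
  expect_equal(kruskal_wallis(g2)$statistic,
               unname(kruskal.test(g2)$statistic), tolerance = 1e-12)
})

test_that("Jonckheere-Terpstra exact enumeration and symmetry hold", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  r <- jonckheere_terpstra(g)
  expect_equal(r$statistic, 12)              # maximal 4+4+4 pairwise counts
  expect_equal(r$p_value, 2 / 90, tolerance = 1e-12)
  expect_equal(r$direction, 1L)
  expect_equal(jonckheere_terpstra(list(c(1, 1), c(1, 1), c(1, 1)))$p_value, 1)
  # reversing the group order negates direction and preserves p
  set.seed(3)
  g2 <- list(rnorm(3), rnorm(3, 1), rnorm(3, 2))
  fwd <- jonckheere_terpstra(g2)
  rev_ <- jonckheere_terpstra(rev(g2))
  expect_equal(rev_$p_value, fwd$p_value, tolerance = 1e-12)
  expect_equal(rev_$direction, -fwd$direction)
  expect_error(jonckheere_terpstra(list(1:3, 4:6)), ">= 3")
})

test_that("chi-squared matches published baseline-table p-values", {
  totals <- c(36, 64, 46)
  rows <- list(gender = c(22, 51, 36), smoker = c(14, 39, 26),
               stroke = c(0, 2, 6), diabetes = c(5, 18, 17),
               pad = c(1, 20, 13), metformin = c(2, 11, 7),
               ppi = c(2, 10, 7))
  printed <- c(0.097, 0.097, 0.020, 0.066, 0.003, 0.251, 0.309)
  for (i in seq_along(rows)) {
    tab <- rbind(rows[[i]], totals - rows[[i]])
    expect_equal(round(chi_square_contingency(tab)$p_value, 3), printed[i])
  }
  expect_equal(chi_square_contingency(rbind(c(5, 5), c(5, 5)))$statistic, 0)
  expect_equal(chi_square_contingency(rbind(c(5, 5), c(5, 5)))$p_value, 1)
  expect_error(chi_square_contingency(rbind(c(0, 0), c(1, 2))),
               "degenerate margin")
})

test_that("Fisher's exact test sums the hypergeometric tail correctly", {
  r <- fisher_exact_2x2(rbind(c(1, 9), c(11, 3)))
  expect_equal(r$p_value, fisher.test(rbind(c(1, 9), c(11, 3)))$p.value,
               tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5)))$p_value, 1)
  expect_error(fisher_exact_2x2(rbind(c(0, 0), c(1, 2))), "degenerate")
  expect_error(fisher_exact_2x2(matrix(1, 3, 3)), "2 x 2")
  set.seed(7)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 8) + 1, 2, 2)
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("fold-change gates are strict and unrounded", {
  expect_equal(fold_change(rep(10, 3), rep(12, 3)), 1.2)
  expect_false(fold_change(rep(10, 3), rep(12, 3)) > 1.2)   # boundary fails
  expect_equal(fold_change(1:4, 1:4), 1)
  fc <- fold_change(rep(12, 3), rep(10, 3))
  expect_equal(fc, 10 / 12)
  expect_false(fc < 0.83)                                   # 0.8333 >= 0.83
  expect_error(fold_change(c(0, 0), c(0, 0)), "undefined")
  expect_error(fold_change(c(0, 0), c(1, 1), 0), "pseudocount")
})

test_that("BH adjustment matches the definitional step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
  }
  # NA p-values stay NA and do not change the family size
  p <- c(0.01, NA, 0.04)
  expect_equal(bh_adjust(p), c(0.02, NA, 0.04))
})

test_that("null p-values are approximately uniform for the rank tests", {
  set.seed(11)
  reps <- 2000
  pw <- pk <- pj <- numeric(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(15); y <- rnorm(15)
    pw[i] <- wilcoxon_rank_sum(x, y)$p_value
    g <- list(rnorm(10), rnorm(10), rnorm(10))
    pk[i] <- kruskal_wallis(g)$p_value
    pj[i] <- jonckheere_terpstra(g)$p_value
  }
  for (p in list(pw, pk, pj)) {
    expect_gt(mean(p), 0.45); expect_lt(mean(p), 0.55)
    expect_true(abs(mean(p < 0.05) - 0.05) < 0.02)
  }
})
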