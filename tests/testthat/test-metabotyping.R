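test_that("cross-comparison selection is the union of its two branches", {
  co <- generate_cohort(small_design(seed = 51))
  cfg <- pipeline_config(random_seed = 51)
  cc <- cross_comparison_filter(co$metabolite, co$meta, cfg)
  expect_identical(cc$selected, cc$setA_pass | cc$setB_pass)
  excl <- cc$feature_id[which(cc$selected)[1]]
  cc2 <- cross_comparison_filter(co$metabolite, co$meta, cfg,
                                 exclude = excl)
  expect_false(cc2$selected[cc2$feature_id == excl])
  expect_identical(cc2$selected[cc2$feature_id != excl],
                   cc$selected[cc$feature_id != excl])
})

test_that("trend-only and pairwise-only signals land in the right branches", {
  # 3 groups of 12; one feature with a weak monotone trend, one with a
  # single large non-monotone pairwise shift
  set.seed(52)
  n <- 36
  g <- rep(c("HC", "SCAD", "MI"), each = 12)
  gi <- rep(0:2, each = 12)
  trend <- exp(0.32 * gi + rnorm(n, 0, 0.35))
  bump <- exp(ifelse(g == "SCAD", 1.6, 0) + rnorm(n, 0, 0.3))
  m <- rbind(trend = trend, bump = bump, noise = exp(rnorm(n, 0, 0.3)))
  colnames(m) <- paste0("S", 1:n)
  meta <- cohort_metadata(paste0("S", 1:n), g)
  cc <- cross_comparison_filter(abundance_table(m, "metabolite"), meta,
                                pipeline_config())
  expect_true(cc$setB_pass[cc$feature_id == "trend"])
  expect_true(cc$setA_pass[cc$feature_id == "bump"])
})

test_that("signed adjacency hits its endpoints and is affine-invariant", {
  n <- 20
  set.seed(53)
  base <- rnorm(n)
  m <- rbind(f1 = exp(base), f2 = exp(2 * base + 3),  # r = 1 on log scale
             f3 = exp(-base), f4 = exp(rnorm(n)))
  colnames(m) <- paste0("S", 1:n)
  a <- adjacency(abundance_table(m, "metabolite"), beta = 14)
  expect_equal(a["f1", "f2"], 1, tolerance = 1e-9)   # perfect correlation
  expect_equal(a["f1", "f3"], 0, tolerance = 1e-9)   # perfect anticorrelation
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(0.5^14, ((1 + 0) / 2)^14)             # r = 0 maps to 0.5^beta
  expect_lt(a["f1", "f4"], 0.05)
})

test_that("topological overlap matches a hand-computed 4-node case", {
  a <- matrix(c(1, .8, .3, .1,
                .8, 1, .5, .2,
                .3, .5, 1, .6,
                .1, .2, .6, 1), 4, 4)
  tom <- topological_overlap(a)
  k <- rowSums(a) - 1
  for (i in 1:4) for (j in 1:4) {
    if (i == j) { expect_equal(tom[i, j], 1); next }
    u <- setdiff(1:4, c(i, j))
    hand <- (sum(a[i, u] * a[u, j]) + a[i, j]) /
      (min(k[i], k[j]) + 1 - a[i, j])
    expect_equal(tom[i, j], hand, tolerance = 1e-12)
  }
  expect_true(all(tom >= 0 & tom <= 1))
  d <- 1 - tom
  expect_equal(d, t(d)); expect_true(all(diag(d) == 0))
  # no off-diagonal edges: all off-diagonal TOM = 0
  tom_id <- topological_overlap(diag(4))
  expect_true(all(tom_id[upper.tri(tom_id)] == 0))
  # two nodes connected only to each other with a = 1: TOM = 1
  a2 <- diag(2); a2[1, 2] <- a2[2, 1] <- 1
  expect_equal(topological_overlap(a2)[1, 2], 1)
  expect_error(topological_overlap(matrix(1:6, 2, 3)), "square")
})

test_that("dynamic tree cut recovers well-separated factors deterministically", {
  set.seed(54)
  n <- 40
  fac <- matrix(rnorm(3 * n), 3, n)
  truth <- rep(1:3, each = 12)
  X <- exp(0.9 * fac[truth, ] + matrix(rnorm(36 * n, 0, 0.4), 36, n))
  dimnames(X) <- list(paste0("f", 1:36), paste0("S", 1:n))
  tab <- abundance_table(X, "metabolite")
  tom <- topological_overlap(adjacency(tab, beta = 14))
  asg <- dynamic_tree_cut(1 - tom, deep_split = 4, min_cluster_size = 5)
  expect_equal(length(attr(asg, "sizes")), 3)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(asg$cluster, truth), 1)
  # labels are ordered by size and deterministic
  asg2 <- dynamic_tree_cut(1 - tom, deep_split = 4, min_cluster_size = 5)
  expect_identical(asg$cluster, asg2$cluster)
  expect_true(all(sort(unique(asg$cluster)) %in% c("0", "M01", "M02", "M03")))
  # a min size above n leaves everything unassigned
  asg3 <- dynamic_tree_cut(1 - tom, deep_split = 4, min_cluster_size = 37)
  expect_true(all(asg3$cluster == "0"))
  # increasing deepSplit never decreases the assigned cluster count here
  counts <- vapply(0:4, function(ds)
    length(attr(dynamic_tree_cut(1 - tom, ds, 5), "sizes")), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("eigen-features summarize their clusters with oriented PC1", {
  set.seed(55)
  n <- 30
  f <- rnorm(n)
  X <- exp(rbind(f + rnorm(n, 0, 0.01), f + rnorm(n, 0, 0.01),
                 f + rnorm(n, 0, 0.01)))
  dimnames(X) <- list(paste0("m", 1:3), paste0("S", 1:n))
  tab <- abundance_table(X, "metabolite")
  asg <- data.frame(feature_id = paste0("m", 1:3), cluster = "M01",
                    stringsAsFactors = FALSE)
  E <- eigen_feature(tab, asg)
  for (i in 1:3)
    expect_gt(cor(E["M01", ], log(X[i, ])), 0.999)
  # PC1 explains at least as much variance as any single member direction
  expect_gte(attr(E, "var_explained")["M01"], 0.99)
  # negating the (log-scale) features negates the eigen-feature
  X2 <- exp(-log(X))
  E2 <- eigen_feature(abundance_table(X2, "metabolite"), asg)
  expect_equal(unname(E2["M01", ]), unname(-E["M01", ]), tolerance = 1e-6)
  # singleton cluster: standardized feature itself
  asg1 <- data.frame(feature_id = "m1", cluster = "M01",
                     stringsAsFactors = FALSE)
  E1 <- eigen_feature(tab, asg1)
  z <- log(X[1, ]); z <- (z - mean(z)) / sd(z)
  expect_equal(unname(E1["M01", ]), unname(z), tolerance = 1e-12)
})

test_that("scale-free fit is high for power-law connectivity, low for uniform", {
  set.seed(56)
  # build an adjacency whose connectivity follows an exact power law
  n <- 120
  k_target <- sort(30 * (1:n)^(-0.7))
  a <- outer(k_target, k_target) / sum(k_target)
  diag(a) <- 1
  a <- pmin(a, 1)
  fit_pl <- scale_free_fit(a)
  u <- matrix(runif(n * n, 0.3, 0.7), n, n); u <- (u + t(u)) / 2; diag(u) <- 1
  fit_unif <- scale_free_fit(u)
  expect_gt(fit_pl, 0.9)
  expect_lt(fit_unif, fit_pl)
  expect_true(fit_unif >= 0 && fit_unif <= 1)
  expect_true(is.na(scale_free_fit(matrix(1, 30, 30))))
})

test_that("the full chain recovers planted latent clusters", {
  skip_if_not_installed("mclust")
  co <- generate_cohort(cohort_design(seed = 57))
  cfg <- pipeline_config(random_seed = 57)
  mt <- suppressWarnings(metabotype(co$metabolite, co$meta, cfg))
  truth <- co$truth$metabotype_assignments[mt$assignment$feature_id]
  ari <- mclust::adjustedRandIndex(mt$assignment$cluster, truth)
  expect_gte(ari, 0.8)
  expect_identical(mt$selection$selected,
                   mt$selection$setA_pass | mt$selection$setB_pass)
})
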