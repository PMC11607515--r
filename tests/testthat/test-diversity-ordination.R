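test_that("Shannon and Simpson indices match closed forms and are scale-free", {
  expect_equal(shannon_index(rep(1, 4)), log(4))
  expect_equal(shannon_index(c(5)), 0)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.5 * log(2))
  expect_equal(simpson_index(c(7)), 0)
  expect_equal(simpson_index(rep(1, 8)), 1 - 1 / 8)
  expect_equal(simpson_index(c(0.5, 0.5)), 0.5)
  set.seed(1)
  v <- rexp(10)
  expect_equal(shannon_index(v), shannon_index(13.7 * v))
  expect_equal(simpson_index(v), simpson_index(0.01 * v))
  expect_error(shannon_index(c(0, 0)), "degenerate")
})

test_that("Bray-Curtis matches the definition and vegan", {
  m <- rbind(a = c(1, 2, 1, 0), b = c(2, 1, 0, 1))
  colnames(m) <- paste0("S", 1:4)
  d <- bray_curtis(abundance_table(m, "species"))
  expect_equal(d$values["S1", "S2"], 1 / 3)          # (1,2) vs (2,1)
  expect_equal(d$values["S1", "S1"], 0)
  expect_equal(d$values["S3", "S4"], 1)              # disjoint supports
  expect_equal(d$values, t(d$values))
  skip_if_not_installed("vegan")
  set.seed(2)
  X <- matrix(rexp(60), 6, 10,
              dimnames = list(paste0("f", 1:6), paste0("S", 1:10)))
  ours <- bray_curtis(abundance_table(X, "species"))$values
  ref <- as.matrix(vegan::vegdist(t(X), method = "bray"))
  expect_equal(ours, ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCoA recovers planar configurations and flags negatives", {
  set.seed(3)
  P <- matrix(rnorm(24), 12, 2)
  D <- as.matrix(dist(P))
  dimnames(D) <- list(paste0("S", 1:12), paste0("S", 1:12))
  res <- pcoa(distance_matrix(D))
  expect_lt(max(abs(as.matrix(dist(res$scores[, 1:2])) - D)), 1e-8)
  expect_true(all(diff(res$prop_explained) <= 1e-12))
  expect_lte(sum(res$prop_explained), 1 + 1e-12)
  # three equidistant samples: two equal positive eigenvalues
  D3 <- matrix(1, 3, 3) - diag(3)
  dimnames(D3) <- list(paste0("S", 1:3), paste0("S", 1:3))
  r3 <- pcoa(distance_matrix(D3))
  expect_equal(r3$eigenvalues[1], r3$eigenvalues[2], tolerance = 1e-12)
  # duplicated sample coincides in the embedding
  P2 <- rbind(P, P[1, ])
  D2 <- as.matrix(dist(P2))
  dimnames(D2) <- list(paste0("S", 1:13), paste0("S", 1:13))
  r2 <- pcoa(distance_matrix(D2))
  expect_lt(max(abs(r2$scores["S13", ] - r2$scores["S1", ])), 1e-8)
})

test_that("perMANOVA matches vegan and saturates under separation", {
  co <- generate_cohort(small_design(seed = 4))
  bc <- bray_curtis(to_relative(co$species))
  pm <- permanova(bc, co$meta$group, n_perm = 199, seed = 1)
  expect_gt(pm$p_value, 0); expect_lte(pm$p_value, 1)
  skip_if_not_installed("vegan")
  ad <- vegan::adonis2(as.dist(bc$values) ~ g,
                       data = data.frame(g = co$meta$group),
                       permutations = 199)
  expect_equal(pm$statistic, ad$F[1], tolerance = 1e-10)
  expect_equal(attr(pm, "R2"), ad$R2[1], tolerance = 1e-10)
  # two groups drawn far apart: minimum attainable p
  X <- cbind(matrix(rexp(40), 4, 10), matrix(rexp(40) + 50, 4, 10))
  colnames(X) <- paste0("S", 1:20); rownames(X) <- paste0("f", 1:4)
  d2 <- bray_curtis(abundance_table(X, "species"))
  pm2 <- permanova(d2, rep(c("A", "B"), each = 10), n_perm = 199, seed = 2)
  expect_equal(pm2$p_value, 1 / 200)
  expect_error(permanova(d2, c("A", rep("B", 19)), 199, 1), ">= 2 samples")
})

test_that("perMANOVA permutation p matches the exhaustive split oracle", {
  # 6 samples, groups of 3: 20 ordered label permutations; with enough
  # random permutations the p converges on the exhaustive value
  set.seed(9)
  P <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(P)); dimnames(D) <- list(paste0("S", 1:6),
                                               paste0("S", 1:6))
  g <- rep(c("A", "B"), each = 3)
  splits <- combn(6, 3, simplify = FALSE)
  f_of <- function(lab) {
    ss <- micromet:::.permanova_ss(D^2, lab)
    (ss["among"] / 1) / (ss["within"] / 4)
  }
  f_obs <- f_of(g)
  f_all <- vapply(splits, function(ix) {
    lab <- rep("B", 6); lab[ix] <- "A"; f_of(lab)
  }, numeric(1))
  p_exh <- mean(f_all >= f_obs - 1e-12)
  pm <- permanova(distance_matrix(D), g, n_perm = 9999, seed = 3)
  expect_lt(abs(pm$p_value - p_exh), 0.02)
})

test_that("dbRDA constrained inertia equals the among-group sum of squares", {
  set.seed(5)
  P <- matrix(rnorm(36), 18, 2)
  g <- rep(c("A", "B", "C"), each = 6)
  D <- as.matrix(dist(P))
  dimnames(D) <- list(paste0("S", 1:18), paste0("S", 1:18))
  dm <- distance_matrix(D)
  db <- dbrda(dm, g)
  ss <- micromet:::.permanova_ss(D^2, g)
  total <- sum(pcoa(dm)$eigenvalues)
  expect_equal(db$constrained_proportion * total, unname(ss["among"]),
               tolerance = 1e-6)
  expect_lte(ncol(db$scores), 2)           # #groups - 1 constrained axes
  # permuting labels leaves total inertia unchanged
  db2 <- dbrda(dm, sample(g))
  expect_equal(sum(pcoa(dm)$eigenvalues), total)
  # near-identical groups: constrained proportion ~ 0
  gg <- rep(c("A", "B"), 9)
  X <- matrix(rexp(72), 4, 18,
              dimnames = list(paste0("f", 1:4), paste0("S", 1:18)))
  db3 <- dbrda(bray_curtis(abundance_table(X, "species")), gg)
  expect_lt(db3$constrained_proportion, 0.15)
  expect_error(dbrda(dm, rep("A", 18)), "2 groups")
})
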