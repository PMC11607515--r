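test_that("abundance tables round-trip through TSV for every table kind", {
  for (kind in c("species", "ko", "metabolite")) {
    tab <- tiny_table(kind)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_abundance_table(tab, path)
    back <- read_abundance_table(path, kind)
    expect_identical(back$kind, kind)
    expect_equal(back$values, tab$values)
  }
})

test_that("table validation rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tS1\tS1", "f1\t1\t2", "f2\t0\t3"), path)
  expect_error(read_abundance_table(path, "species"), "duplicate sample")
  writeLines(c("feature_id\tS1\tS2", "f1\t1\t2", "f2\t0"), path)
  expect_error(read_abundance_table(path, "species"), "ragged")
  writeLines(c("feature_id\tS1\tS2", "f1\t1\tx", "f2\t0\t3"), path)
  expect_error(read_abundance_table(path, "species"), "non-numeric")
  m <- rbind(f1 = c(1, -2, 3))
  colnames(m) <- paste0("S", 1:3)
  expect_error(abundance_table(m, "species"), "non-negative")
})

test_that("to_relative closes samples to one, preserves zeros, is idempotent", {
  m <- rbind(a = c(2, 0, 0), b = c(2, 5, 1))
  colnames(m) <- paste0("S", 1:3)
  rel <- to_relative(abundance_table(m, "species"))
  expect_equal(unname(colSums(rel$values)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(rel$values[, 1]), c(0.5, 0.5))
  expect_equal(unname(rel$values[, 2]), c(0, 1))
  expect_equal(to_relative(rel)$values, rel$values)
  m0 <- rbind(a = c(1, 0), b = c(1, 0))
  colnames(m0) <- c("S1", "Sbad")
  expect_error(to_relative(abundance_table(m0, "species")), "Sbad")
})

test_that("prevalence filtering is strictly exclusive at the gate", {
  m <- rbind(two_of_20 = c(rep(1, 2), rep(0, 18)),
             one_of_20 = c(1, rep(0, 19)),
             all = rep(1, 20))
  colnames(m) <- paste0("S", 1:20)
  tab <- abundance_table(m, "ko")
  kept <- feature_ids(filter_prevalence(tab, 0.05))
  expect_true("two_of_20" %in% kept)      # 0.10 > 0.05
  expect_false("one_of_20" %in% kept)     # 0.05 not > 0.05
  kept0 <- feature_ids(filter_prevalence(tab, 0))
  expect_setequal(kept0, rownames(m))
  # output is always a row-subset in original order
  expect_identical(kept, intersect(rownames(m), kept))
})

test_that("sample alignment warns on partial overlap and errors on none", {
  tab <- tiny_table()
  meta <- tiny_meta()
  extra <- cohort_metadata(c(paste0("S", 1:6), "S99"),
                           c("HC", "HC", "SCAD", "SCAD", "MI", "MI", "MI"))
  expect_warning(al <- align_samples(tab, extra), "non-overlapping")
  expect_identical(al$meta$sample_id, paste0("S", 1:6))
  other <- cohort_metadata(paste0("X", 1:4), rep(c("HC", "MI"), 2))
  expect_error(align_samples(tab, other), "no overlap")
})

test_that("metadata and module map readers validate and round-trip", {
  meta <- tiny_meta()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(meta, path)
  back <- read_metadata(path)
  expect_equal(as.character(back$group), as.character(meta$group))
  expect_equal(back$Gensini, meta$Gensini)
  expect_true(is.ordered(back$group))
  expect_error(cohort_metadata("S1", "XX"), "outside the declared")
  expect_error(module_map(c("K1", "K1"), c("M1", "M1")), "duplicate")
  mm <- module_map(c("K1", "K1", "K2"), c("M1", "M2", "M1"))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_module_map(mm, p2)
  expect_equal(as.data.frame(read_module_map(p2)), as.data.frame(mm))
})

test_that("configuration validates thresholds and reads from YAML", {
  expect_error(pipeline_config(p_species = 1.2), "p_species")
  expect_error(pipeline_config(fc_high = 0.9), "fc_low < 1 < fc_high")
  expect_error(pipeline_config(deep_split = 5), "deep_split")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("p_species: 0.05", "soft_power_beta: 6", "random_seed: 42"),
             path)
  cfg <- read_config(path)
  expect_equal(cfg$p_species, 0.05)
  expect_equal(cfg$soft_power_beta, 6)
  expect_equal(cfg$random_seed, 42L)
  expect_equal(cfg$fc_high, 1.2)  # untouched default
  writeLines("nonsense_key: 1", path)
  expect_error(read_config(path), "unknown configuration key")
})
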