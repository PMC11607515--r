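# small in-code fixtures shared across test files

tiny_table <- function(kind = "species") {
  m <- rbind(spA = c(2, 0, 1, 4, 0, 3),
             spB = c(2, 5, 0, 1, 1, 0),
             spC = c(0, 5, 9, 5, 9, 7))
  colnames(m) <- paste0("S", 1:6)
  abundance_table(m, kind)
}

tiny_meta <- function() {
  cohort_metadata(paste0("S", 1:6),
                  c("HC", "HC", "SCAD", "SCAD", "MI", "MI"),
                  data.frame(Gensini = c(1, 2, 10, 12, 30, 28)))
}

# fast, small synthetic design for unit tests (not the study defaults)
small_design <- function(seed = 1L, ...) {
  cohort_design(group_sizes = c(HC = 10L, SCAD = 12L, MI = 10L),
                n_species = 40L, n_kos = 120L, n_modules = 8L,
                kos_per_module = 6L, n_metabolites = 60L,
                n_latent_clusters = 3L, n_diff_species = 6L,
                n_enriched_modules = 2L,
                cluster_shifts = c(1.2, -1.2, 0.8),
                seed = seed, ...)
}

# definitional step-up BH oracle: q_i = min_{j: p_j >= p_i} m * p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  ranked <- p[o] * m / seq_len(m)
  for (i in seq_len(m)) q[o[i]] <- min(1, min(ranked[i:m]))
  q
}

# brute-force JT statistic: explicit double loop over ordered group pairs
jt_stat_oracle <- function(groups) {
  k <- length(groups)
  s <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    for (a in groups[[i]]) for (b in groups[[j]])
      s <- s + (a < b) + 0.5 * (a == b)
  s
}

# exact JT null distribution by enumerating all distinct label
# arrangements of the pooled values (iterative stack, independent of the
# package's enumeration)
jt_exact_p_oracle <- function(groups) {
  pooled <- unlist(groups)
  ni <- lengths(groups)
  N <- sum(ni)
  obs <- jt_stat_oracle(groups)
  mu <- (N^2 - sum(ni^2)) / 4
  splits <- function(ids, sizes) {
    if (length(sizes) == 1L) return(list(list(ids)))
    first <- utils::combn(ids, sizes[1], simplify = FALSE)
    out <- list()
    for (f in first)
      for (rest in splits(setdiff(ids, f), sizes[-1]))
        out[[length(out) + 1L]] <- c(list(f), rest)
    out
  }
  all_jt <- vapply(splits(seq_len(N), ni), function(parts)
    jt_stat_oracle(lapply(parts, function(ix) pooled[ix])), numeric(1))
  min(1, 2 * min(mean(all_jt <= obs), mean(all_jt >= obs)))
}
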