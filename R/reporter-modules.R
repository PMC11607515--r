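#' Per-KO differential testing
#'
#' Two-group Wilcoxon rank-sum test on every KO of a prevalence-filtered
#' functional profile, with BH q-values across the KO family and the
#' package's direction convention (+1 = elevated in the case group).
#'
#' @param ko_table KO `abundance_table`.
#' @param meta a `cohort_metadata`.
#' @param reference,case group labels of the comparison (pooled if several).
#' @param config a [pipeline_config()]; supplies the prevalence gate.
#' @return data.frame `ko_id`, `p_value`, `q_value`, `direction`.
#' @export
ko_differential <- function(ko_table, meta, reference = "HC",
                            case = c("SCAD", "MI"),
                            config = pipeline_config()) {
  al <- align_samples(ko_table, meta)
  ko_table <- al$table; meta <- al$meta
  bad <- setdiff(c(reference, case), levels(meta$group))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  filt <- filter_prevalence(ko_table, config$prevalence_min)
  ref_idx <- meta$group %in% reference
  case_idx <- meta$group %in% case
  if (!any(ref_idx) || !any(case_idx))
    stop("comparison group absent from the cohort")
  kos <- feature_ids(filt)
  p <- numeric(length(kos)); dir <- integer(length(kos))
  for (i in seq_along(kos)) {
    r <- wilcoxon_rank_sum(filt$values[i, ref_idx], filt$values[i, case_idx])
    p[i] <- r$p_value; dir[i] <- r$direction
  }
  data.frame(ko_id = kos, p_value = p, q_value = bh_adjust(p),
             direction = dir, stringsAsFactors = FALSE)
}

#' KEGG-module reporter scores
#'
#' Aggregates per-KO two-sided p-values into signed module-level scores:
#' each KO contributes `z = qnorm(1 - p/2) * direction` (p floored at 1e-15
#' so the inverse-normal stays finite); a module of k tested KOs has raw
#' score `sum(z) / sqrt(k)`, which is centred and scaled against the mean
#' and sd of the same statistic over `background_draws` random size-k KO
#' sets drawn from all tested KOs. Modules with
#' `|score| > config$reporter_threshold` (default 1.6, ~95% normal
#' confidence per tail) are flagged significant; depleted modules score
#' negative.
#'
#' @param kos output of [ko_differential()].
#' @param map a `module_map`.
#' @param config a [pipeline_config()]; `random_seed` fixes the background
#'   draws, making scores bit-reproducible.
#' @return data.frame of class `reporter_result`: `module_id`, `n_kos`,
#'   `raw_z`, `reporter_score`, `direction`, `significant`.
#' @export
reporter_score <- function(kos, map, config = pipeline_config()) {
  stopifnot(is.data.frame(kos), all(c("ko_id", "p_value", "direction")
                                    %in% names(kos)))
  p <- pmax(kos$p_value, 1e-15)
  z_all <- setNames(qnorm(p / 2, lower.tail = FALSE) * kos$direction,
                    kos$ko_id)
  z_all <- z_all[order(names(z_all))]  # canonical order: row order must not
                                       # affect the seeded background draws
  mods <- split(map$ko_id, map$module_id)
  tested <- lapply(mods, intersect, y = kos$ko_id)
  empty <- lengths(tested) == 0L
  if (any(empty)) {
    warning("dropping module(s) with no tested KO: ",
            paste(names(tested)[empty], collapse = ", "))
    tested <- tested[!empty]
  }
  if (length(tested) == 0L) stop("no module retains a tested KO")
  sizes <- sort(unique(lengths(tested)))
  bg <- with_seed(config$random_seed, {
    out <- list()
    N <- length(z_all)
    for (k in sizes) {
      rawz <- vapply(seq_len(config$background_draws),
                     function(b) sum(z_all[sample.int(N, k)]) / sqrt(k),
                     numeric(1L))
      out[[as.character(k)]] <- c(mu = mean(rawz), sigma = sd(rawz))
    }
    out
  })
  module_id <- names(tested)
  n_kos <- lengths(tested)
  raw_z <- vapply(tested, function(ids) sum(z_all[ids]) / sqrt(length(ids)),
                  numeric(1L))
  mu <- vapply(as.character(n_kos), function(k) bg[[k]]["mu"], numeric(1L))
  sg <- vapply(as.character(n_kos), function(k) bg[[k]]["sigma"], numeric(1L))
  score <- (raw_z - mu) / sg
  out <- data.frame(module_id = module_id, n_kos = as.integer(n_kos),
                    raw_z = unname(raw_z), reporter_score = unname(score),
                    direction = as.integer(sign(score)),
                    significant = abs(score) > config$reporter_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$module_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("reporter_result", "data.frame")
  out
}

#' Per-sample module activity scores
#'
#' Sample-level proxy of module activity for correlation analyses: the sum
#' of the module's KO relative abundances in each sample. (Reporter scores
#' are group-level contrasts; association grids need per-sample vectors.)
#'
#' @param ko_table KO `abundance_table`.
#' @param map a `module_map`.
#' @return Matrix modules x samples.
#' @export
module_activity <- function(ko_table, map) {
  rel <- to_relative(ko_table)
  mods <- split(map$ko_id, map$module_id)
  mods <- lapply(mods, intersect, y = feature_ids(rel))
  mods <- mods[lengths(mods) > 0L]
  if (length(mods) == 0L) stop("no module KO is present in the table")
  t(vapply(mods, function(ids)
    colSums(rel$values[ids, , drop = FALSE]),
    numeric(ncol(rel$values))))
}
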