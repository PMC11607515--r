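#' Differential-abundance screen of microbial species
#'
#' For every prevalent species, a two-group Wilcoxon rank-sum test between
#' a reference and a case group plus a fold change (case over reference,
#' pseudocounted group means). A species passes when its raw p-value is
#' below `config$p_species` AND its fold change is strictly above
#' `config$fc_high` or strictly below `config$fc_low`. BH q-values across
#' the screen are attached for reporting; the pass gate uses raw p.
#'
#' @param table species `abundance_table` (converted to relative
#'   abundances internally).
#' @param meta a `cohort_metadata` aligned by sample identifiers.
#' @param reference,case character vectors of group labels forming the
#'   comparison; multiple labels are pooled (e.g. `case = c("SCAD", "MI")`
#'   for an all-disease comparison).
#' @param config a [pipeline_config()].
#' @return data.frame of class `differential_screen` with one row per
#'   tested feature: `feature_id`, `comparison`, `p_value`, `q_value`,
#'   `fold_change`, `enriched_in`, `passes`.
#' @export
screen_species <- function(table, meta, reference = "HC",
                           case = c("SCAD", "MI"),
                           config = pipeline_config()) {
  al <- align_samples(table, meta)
  table <- al$table; meta <- al$meta
  known <- levels(meta$group)
  bad <- setdiff(c(reference, case), known)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  rel <- to_relative(table)
  rel <- filter_prevalence(rel, config$prevalence_min)
  ref_idx <- meta$group %in% reference
  case_idx <- meta$group %in% case
  if (sum(ref_idx) < 3L || sum(case_idx) < 3L)
    stop("both comparison groups need at least 3 samples")
  pc <- resolve_pseudocount(config, rel$values)
  cmp <- paste(paste(reference, collapse = "+"), "vs",
               paste(case, collapse = "+"))
  feats <- feature_ids(rel)
  p <- fc <- numeric(length(feats))
  for (i in seq_along(feats)) {
    x <- rel$values[i, ref_idx]
    y <- rel$values[i, case_idx]
    p[i] <- wilcoxon_rank_sum(x, y)$p_value
    fc[i] <- fold_change(x, y, pc)
  }
  q <- bh_adjust(p)
  passes <- (p < config$p_species) &
    (fc > config$fc_high | fc < config$fc_low)
  out <- data.frame(feature_id = feats, comparison = cmp,
                    p_value = p, q_value = q, fold_change = fc,
                    enriched_in = ifelse(fc > 1,
                                         paste(case, collapse = "+"),
                                         paste(reference, collapse = "+")),
                    passes = passes, stringsAsFactors = FALSE)
  class(out) <- c("differential_screen", "data.frame")
  out
}

#' Spearman correlation of selected species with clinical phenotypes
#'
#' Pairwise-complete Spearman rank correlation between each selected
#' feature's abundance and each phenotype, with a single BH family across
#' the whole matrix. Cells with fewer than 4 paired observations are
#' returned as `NA`.
#'
#' @param table an `abundance_table` (any kind).
#' @param meta a `cohort_metadata` carrying the phenotype columns.
#' @param features feature identifiers to correlate (default all).
#' @param phenotypes phenotype column names (default all numeric columns).
#' @return A list of class `correlation_matrix` with matrices `rho`, `p`,
#'   `q` (features x phenotypes) and `n` (paired observations).
#' @export
species_phenotype_correlation <- function(table, meta,
                                          features = feature_ids(table),
                                          phenotypes = NULL) {
  al <- align_samples(table, meta)
  table <- al$table; meta <- al$meta
  if (is.null(phenotypes))
    phenotypes <- setdiff(names(meta), c("sample_id", "group"))
  missing_f <- setdiff(features, feature_ids(table))
  if (length(missing_f))
    stop("feature(s) not in table: ", paste(missing_f, collapse = ", "))
  missing_p <- setdiff(phenotypes, names(meta))
  if (length(missing_p))
    stop("phenotype(s) not in metadata: ", paste(missing_p, collapse = ", "))
  rho <- p <- nmat <- matrix(NA_real_, length(features), length(phenotypes),
                             dimnames = list(features, phenotypes))
  for (j in seq_along(phenotypes)) {
    ph <- meta[[phenotypes[j]]]
    for (i in seq_along(features)) {
      x <- table$values[features[i], ]
      ok <- !is.na(x) & !is.na(ph)
      nmat[i, j] <- sum(ok)
      if (sum(ok) < 4L) next
      if (sd(x[ok]) == 0 || sd(ph[ok]) == 0) {  # constant cell: no rank
        rho[i, j] <- 0; p[i, j] <- 1            # signal, flagged null
        next
      }
      rho[i, j] <- cor(x[ok], ph[ok], method = "spearman")
      p[i, j] <- suppressWarnings(
        cor.test(x[ok], ph[ok], method = "spearman", exact = FALSE)$p.value)
    }
  }
  q <- matrix(bh_adjust(as.vector(p)), nrow(p), ncol(p),
              dimnames = dimnames(p))
  structure(list(rho = rho, p = p, q = q, n = nmat),
            class = "correlation_matrix")
}
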