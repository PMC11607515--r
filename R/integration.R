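# FDR tier ladder shared by the association outputs: the only coherent
# ordering of the published legend's annotation scheme
assign_tier <- function(q) {
  ifelse(is.na(q), "ns",
         ifelse(q < 0.001, "strong",
                ifelse(q < 0.05, "moderate",
                       ifelse(q < 0.1, "weak", "ns"))))
}

#' Associate sample-level feature scores with a clinical phenotype
#'
#' For a two-group contrast the per-feature test is Mann-Whitney
#' (Wilcoxon rank-sum) with the direction sign; for a continuous phenotype
#' it is Spearman correlation. BH q-values are computed across the feature
#' family and annotated with the tier ladder (q < 0.001 strong, < 0.05
#' moderate, < 0.1 weak, else ns); the default significance gate is
#' `config$fdr_phenotype` (FDR < 0.1).
#'
#' @param scores matrix features x samples (e.g. metabotype eigen-features
#'   or module activities), with sample colnames.
#' @param meta a `cohort_metadata`.
#' @param phenotype either the name of a numeric metadata column, or a
#'   character vector of two group labels defining a contrast (second
#'   label = case).
#' @param config a [pipeline_config()].
#' @return data.frame of class `association_cells`: `row_id`, `phenotype`,
#'   `rho` (Spearman rho, or the direction sign for contrasts), `p_value`,
#'   `q_value`, `tier`, `significant`.
#' @export
phenotype_association <- function(scores, meta, phenotype,
                                  config = pipeline_config()) {
  stopifnot(is.matrix(scores), !is.null(colnames(scores)))
  shared <- intersect(colnames(scores), meta$sample_id)
  if (length(shared) == 0L) stop("no shared samples")
  scores <- scores[, shared, drop = FALSE]
  m <- meta[match(shared, meta$sample_id), , drop = FALSE]
  contrast <- length(phenotype) == 2L && all(phenotype %in% levels(m$group))
  if (!contrast && !(length(phenotype) == 1L && phenotype %in% names(m)))
    stop("`phenotype` must name a metadata column or two group labels")
  rows <- rownames(scores)
  if (is.null(rows)) rows <- paste0("feature", seq_len(nrow(scores)))
  p <- rho <- rep(NA_real_, length(rows))
  if (contrast) {
    a <- m$group == phenotype[1L]
    b <- m$group == phenotype[2L]
    for (i in seq_along(rows)) {
      r <- wilcoxon_rank_sum(scores[i, a], scores[i, b])
      p[i] <- r$p_value
      rho[i] <- r$direction
    }
    label <- paste(phenotype, collapse = " vs ")
  } else {
    ph <- m[[phenotype]]
    for (i in seq_along(rows)) {
      x <- scores[i, ]
      ok <- !is.na(x) & !is.na(ph)
      if (sum(ok) < 4L) next
      if (sd(x[ok]) == 0) { p[i] <- 1; rho[i] <- 0; next }
      rho[i] <- cor(x[ok], ph[ok], method = "spearman")
      p[i] <- suppressWarnings(
        cor.test(x[ok], ph[ok], method = "spearman", exact = FALSE)$p.value)
    }
    label <- phenotype
  }
  q <- bh_adjust(p)
  out <- data.frame(row_id = rows, phenotype = label, rho = rho,
                    p_value = p, q_value = q, tier = assign_tier(q),
                    significant = !is.na(q) & q < config$fdr_phenotype,
                    stringsAsFactors = FALSE)
  class(out) <- c("association_cells", "data.frame")
  out
}

#' Module-by-metabotype Spearman association grid
#'
#' Full Spearman grid between per-sample module activities and metabotype
#' eigen-features over the shared samples, with a SINGLE BH family across
#' every cell of the grid, annotated with the FDR tier ladder.
#'
#' @param module_scores matrix modules x samples (see [module_activity()]).
#' @param metabotype_eigens matrix metabotypes x samples (see
#'   [eigen_feature()]).
#' @param config a [pipeline_config()].
#' @return An object of class `association_grid`: list of matrices `rho`,
#'   `p`, `q`, `tier` (modules x metabotypes) plus `n_samples`.
#' @export
module_metabotype_grid <- function(module_scores, metabotype_eigens,
                                   config = pipeline_config()) {
  shared <- intersect(colnames(module_scores), colnames(metabotype_eigens))
  if (length(shared) == 0L) stop("no shared samples between the two layers")
  if (length(shared) < 8L)
    warning("only ", length(shared),
            " shared samples; associations will be low-powered")
  A <- module_scores[, shared, drop = FALSE]
  B <- metabotype_eigens[, shared, drop = FALSE]
  rho <- p <- matrix(NA_real_, nrow(A), nrow(B),
                     dimnames = list(rownames(A), rownames(B)))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    ok <- !is.na(A[i, ]) & !is.na(B[j, ])
    if (sum(ok) < 4L) next
    if (sd(A[i, ok]) == 0 || sd(B[j, ok]) == 0) {
      rho[i, j] <- 0; p[i, j] <- 1; next
    }
    rho[i, j] <- cor(A[i, ok], B[j, ok], method = "spearman")
    p[i, j] <- suppressWarnings(
      cor.test(A[i, ok], B[j, ok], method = "spearman",
               exact = FALSE)$p.value)
  }
  q <- matrix(bh_adjust(as.vector(p)), nrow(p), ncol(p),
              dimnames = dimnames(p))
  tier <- matrix(assign_tier(as.vector(q)), nrow(q), ncol(q),
                 dimnames = dimnames(q))
  structure(list(rho = rho, p = p, q = q, tier = tier,
                 n_samples = length(shared)),
            class = "association_grid")
}

#' @export
print.association_grid <- function(x, ...) {
  cat(sprintf("<association_grid> %d x %d cells over %d samples; tiers: %s\n",
              nrow(x$rho), ncol(x$rho), x$n_samples,
              paste(names(table(x$tier)), table(x$tier),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Long-format view of an association grid
#'
#' @param grid an `association_grid`.
#' @return data.frame `row_id`, `col_id`, `rho`, `p_value`, `q_value`,
#'   `tier`.
#' @export
grid_long <- function(grid) {
  data.frame(row_id = rep(rownames(grid$rho), ncol(grid$rho)),
             col_id = rep(colnames(grid$rho), each = nrow(grid$rho)),
             rho = as.vector(grid$rho), p_value = as.vector(grid$p),
             q_value = as.vector(grid$q), tier = as.vector(grid$tier),
             stringsAsFactors = FALSE)
}
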