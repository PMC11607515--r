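#' Cross-comparison metabolite selection
#'
#' Two-branch screen for disease-associated metabolite features across the
#' ordered stage groups.
#'
#' Set A (pairwise branch): over all pairwise group comparisons, a feature
#' passes if for at least one comparison BOTH the Wilcoxon BH q-value and
#' the Welch t-test BH q-value (each adjusted within its own test family,
#' per comparison) are below `config$q_metabolite` AND the fold change is
#' strictly above `config$fc_high` or below `config$fc_low` in that same
#' comparison. Set B (trend branch): the feature passes if the
#' Jonckheere-Terpstra trend p OR the Kruskal-Wallis p across the ordered
#' groups is below `config$p_setB`. The selected set is the union, minus a
#' user-supplied exclusion list (e.g. drug-derived features).
#'
#' t-tests run on log-transformed intensities; rank tests and fold changes
#' use the raw scale.
#'
#' @param met_table metabolite `abundance_table`.
#' @param meta a `cohort_metadata` with >= 3 groups of >= 3 samples.
#' @param config a [pipeline_config()].
#' @param exclude feature identifiers to drop from the selection.
#' @return data.frame of class `cross_comparison`: `feature_id`,
#'   `setA_pass`, `setB_pass`, `selected`, `best_q_wilcoxon`, `best_q_ttest`,
#'   `best_fold_change`, `p_jt`, `p_kruskal`.
#' @export
cross_comparison_filter <- function(met_table, meta,
                                    config = pipeline_config(),
                                    exclude = character()) {
  al <- align_samples(met_table, meta)
  met_table <- al$table; meta <- al$meta
  grp_levels <- levels(meta$group)[levels(meta$group) %in% meta$group]
  if (length(grp_levels) < 3L)
    stop("cross-comparison needs >= 3 groups present")
  if (any(table(meta$group)[grp_levels] < 3L))
    stop("every group needs >= 3 samples")
  X <- met_table$values
  feats <- rownames(X)
  pc <- resolve_pseudocount(config, X)
  idx <- lapply(grp_levels, function(g) meta$group == g)
  names(idx) <- grp_levels
  pairs <- combn(grp_levels, 2L, simplify = FALSE)

  nfeat <- length(feats)
  setA <- logical(nfeat)
  best_qw <- best_qt <- rep(NA_real_, nfeat)
  best_fc <- rep(NA_real_, nfeat)
  for (pr in pairs) {
    a <- idx[[pr[1L]]]; b <- idx[[pr[2L]]]
    pw <- pt_ <- fc <- numeric(nfeat)
    for (i in seq_len(nfeat)) {
      pw[i] <- wilcoxon_rank_sum(X[i, a], X[i, b])$p_value
      pt_[i] <- t_test_welch(log(X[i, a] + pc), log(X[i, b] + pc))$p_value
      fc[i] <- fold_change(X[i, a], X[i, b], pc)
    }
    qw <- bh_adjust(pw)
    qt <- bh_adjust(pt_)
    hit <- qw < config$q_metabolite & qt < config$q_metabolite &
      (fc > config$fc_high | fc < config$fc_low)
    setA <- setA | hit
    better <- is.na(best_qw) | pmax(qw, qt) < pmax(best_qw, best_qt)
    best_qw[better] <- qw[better]
    best_qt[better] <- qt[better]
    best_fc[better] <- fc[better]
  }
  p_jt <- p_kw <- numeric(nfeat)
  for (i in seq_len(nfeat)) {
    gs <- lapply(grp_levels, function(g) X[i, idx[[g]]])
    p_jt[i] <- jonckheere_terpstra(gs)$p_value
    p_kw[i] <- kruskal_wallis(gs)$p_value
  }
  setB <- p_jt < config$p_setB | p_kw < config$p_setB
  selected <- (setA | setB) & !(feats %in% exclude)
  out <- data.frame(feature_id = feats, setA_pass = setA, setB_pass = setB,
                    selected = selected, best_q_wilcoxon = best_qw,
                    best_q_ttest = best_qt, best_fold_change = best_fc,
                    p_jt = p_jt, p_kruskal = p_kw,
                    stringsAsFactors = FALSE)
  class(out) <- c("cross_comparison", "data.frame")
  out
}

# features x samples matrix of log-transformed, row-standardized
# intensities; zero-variance features dropped with a warning
standardized_log <- function(values) {
  # pseudocount only when zeros are present, so strictly positive
  # intensities keep exact log-scale relations
  pc <- if (any(values == 0)) min(values[values > 0]) / 2 else 0
  L <- log(values + pc)
  sds <- apply(L, 1L, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(rownames(L)[sds == 0], collapse = ", "))
    L <- L[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (L - rowMeans(L)) / sds
}

#' Signed soft-threshold adjacency
#'
#' Pairwise Pearson correlation `r` of log-transformed, standardized
#' features, mapped to a signed adjacency `((1 + r)/2)^beta` (or `|r|^beta`
#' unsigned). The diagonal is set to 1.
#'
#' @param selected_table metabolite `abundance_table` of >= 3 features.
#' @param beta soft-threshold exponent (>= 1); 14 is the signed-network
#'   operating point of the pipeline.
#' @param signed signed (default) or unsigned network.
#' @return Symmetric adjacency matrix in \[0, 1\].
#' @export
adjacency <- function(selected_table, beta = 14, signed = TRUE) {
  if (beta < 1) stop("`beta` must be >= 1")
  Z <- standardized_log(selected_table$values)
  if (nrow(Z) < 3L) stop("adjacency needs >= 3 (non-constant) features")
  r <- cor(t(Z))
  a <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
  diag(a) <- 1
  a
}

#' Scale-free topology fit index
#'
#' R-squared of the log-log regression of binned connectivity frequency on
#' binned mean connectivity, a diagnostic for choosing the soft-threshold
#' exponent.
#'
#' @param adjacency symmetric adjacency matrix (>= 20 features for a
#'   meaningful fit).
#' @param n_bins number of connectivity bins.
#' @return R-squared in \[0, 1\], or `NA` when connectivity is degenerate
#'   (all nodes equally connected).
#' @export
scale_free_fit <- function(adjacency, n_bins = 10L) {
  k <- rowSums(adjacency) - diag(adjacency)
  if (max(k) - min(k) < .Machine$double.eps * max(1, max(abs(k))))
    return(NA_real_)
  cuts <- cut(k, breaks = n_bins)
  freq <- tapply(k, cuts, length)
  mid <- tapply(k, cuts, mean)
  ok <- !is.na(freq) & freq > 0 & mid > 0
  if (sum(ok) < 3L) return(NA_real_)
  fit <- stats::lm(log10(as.numeric(freq[ok])) ~ log10(as.numeric(mid[ok])))
  summary(fit)$r.squared
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k_i = sum_{u != i} a_iu`; the sum excludes `u = i, j`. The
#' diagonal is 1, and `1 - TOM` is the clustering dissimilarity.
#'
#' @param adjacency square symmetric matrix with unit diagonal.
#' @return TOM matrix in \[0, 1\].
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a) || max(abs(a - t(a))) > 1e-12)
    stop("adjacency must be square and symmetric")
  A0 <- a
  diag(A0) <- 0
  L <- A0 %*% A0                     # sum over u != i, j (diag of A0 is 0)
  k <- rowSums(A0)
  kmin <- outer(k, k, pmin)
  tom <- (L + A0) / (kmin + 1 - A0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

# deepSplit level -> quantile of the merge-height distribution used as the
# static cut height; higher levels admit looser merges, so more branches
# survive the minimum-size gate
.deep_split_quantiles <- c(0.64, 0.73, 0.82, 0.91, 0.95)

#' Dynamic tree cut of a dissimilarity matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity, cut at an
#' adaptive height: the `deepSplit`-mapped quantile (0.64, 0.73, 0.82,
#' 0.91, 0.95 for levels 0-4) of the dendrogram merge heights. Branches
#' smaller than `min_cluster_size` are left unassigned (label 0); surviving
#' clusters are relabelled `M01`, `M02`, ... by decreasing size. Fully
#' deterministic.
#'
#' @param dissimilarity square symmetric matrix (e.g. `1 - TOM`).
#' @param deep_split integer 0-4.
#' @param min_cluster_size smallest branch kept as a cluster (>= 2).
#' @return An object of class `metabotype_assignment`: data.frame
#'   `feature_id`, `cluster` (`"M01"`..., or `"0"` for unassigned), with
#'   attributes `sizes` (named cluster sizes) and `cut_height`.
#' @export
dynamic_tree_cut <- function(dissimilarity, deep_split = 4L,
                             min_cluster_size = 5L) {
  if (!deep_split %in% 0:4) stop("`deep_split` must be in {0,...,4}")
  if (min_cluster_size < 2L) stop("`min_cluster_size` must be >= 2")
  d <- as.matrix(dissimilarity)
  feats <- rownames(d)
  if (is.null(feats)) feats <- paste0("f", seq_len(nrow(d)))
  tree <- hclust(as.dist(d), method = "average")
  h_cut <- unname(quantile(tree$height,
                           .deep_split_quantiles[deep_split + 1L]))
  raw <- cutree(tree, h = h_cut)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_cluster_size]
  lab <- rep("0", length(raw))
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(keep))
      lab[raw == as.integer(keep[i])] <- sprintf("M%02d", i)
  }
  out <- data.frame(feature_id = feats, cluster = lab,
                    stringsAsFactors = FALSE)
  cl_sizes <- table(lab[lab != "0"])
  if (length(cl_sizes)) cl_sizes <- cl_sizes[order(names(cl_sizes))]
  attr(out, "sizes") <- cl_sizes
  attr(out, "cut_height") <- h_cut
  class(out) <- c("metabotype_assignment", "data.frame")
  out
}

#' Per-cluster eigen-features
#'
#' The first principal component of the standardized within-cluster feature
#' matrix, as a per-sample score vector, sign-oriented so its mean
#' correlation with cluster members is positive. A singleton cluster's
#' eigen-feature is the standardized feature itself.
#'
#' @param met_table metabolite `abundance_table` containing the assigned
#'   features.
#' @param assignment a `metabotype_assignment`.
#' @return Matrix clusters x samples; attribute `"var_explained"` carries
#'   the PC1 variance fraction per cluster.
#' @export
eigen_feature <- function(met_table, assignment) {
  Z <- standardized_log(met_table$values)
  clusters <- setdiff(sort(unique(assignment$cluster)), "0")
  if (length(clusters) == 0L) stop("no assigned cluster")
  E <- matrix(NA_real_, length(clusters), ncol(Z),
              dimnames = list(clusters, colnames(Z)))
  ve <- setNames(numeric(length(clusters)), clusters)
  for (cl in clusters) {
    ids <- assignment$feature_id[assignment$cluster == cl]
    ids <- intersect(ids, rownames(Z))
    if (length(ids) == 0L) stop("cluster ", cl, " has no usable feature")
    Xc <- Z[ids, , drop = FALSE]
    if (length(ids) == 1L) {
      E[cl, ] <- Xc[1L, ]
      ve[cl] <- 1
      next
    }
    sv <- svd(Xc)
    v <- sv$v[, 1L]
    if (mean(cor(v, t(Xc))) < 0) v <- -v
    E[cl, ] <- v
    ve[cl] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  attr(E, "var_explained") <- ve
  E
}

#' Full metabotyping chain
#'
#' Cross-comparison selection, signed soft-threshold adjacency, topological
#' overlap, average-linkage tree, dynamic cut, eigen-features.
#'
#' @inheritParams cross_comparison_filter
#' @return List with `selection`, `assignment`, `eigen` and the
#'   `scale_free_r2` diagnostic at the configured beta.
#' @export
metabotype <- function(met_table, meta, config = pipeline_config(),
                       exclude = character()) {
  sel <- cross_comparison_filter(met_table, meta, config, exclude)
  keep <- sel$feature_id[sel$selected]
  if (length(keep) < 3L)
    stop("fewer than 3 selected features; nothing to cluster")
  sub <- met_table
  sub$values <- met_table$values[keep, , drop = FALSE]
  a <- adjacency(sub, beta = config$soft_power_beta, signed = TRUE)
  tom <- topological_overlap(a)
  asg <- dynamic_tree_cut(1 - tom, deep_split = config$deep_split,
                          min_cluster_size = config$min_cluster_size)
  eig <- eigen_feature(sub, asg)
  list(selection = sel, assignment = asg, eigen = eig,
       scale_free_r2 = scale_free_fit(a))
}
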