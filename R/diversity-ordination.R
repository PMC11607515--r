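#' Shannon diversity index
#'
#' `H = -sum p_i log p_i` over the positive entries of a (relative or raw)
#' abundance vector, natural log. Invariant to positive rescaling.
#'
#' @param counts non-negative numeric vector with at least one positive
#'   entry.
#' @return Non-negative scalar.
#' @export
shannon_index <- function(counts) {
  if (all(counts == 0)) stop("degenerate sample: all abundances are zero")
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Gini-Simpson diversity index
#'
#' `1 - sum p_i^2`, in \[0, 1).
#'
#' @inheritParams shannon_index
#' @return Scalar in \[0, 1).
#' @export
simpson_index <- function(counts) {
  if (all(counts == 0)) stop("degenerate sample: all abundances are zero")
  p <- counts[counts > 0]
  p <- p / sum(p)
  1 - sum(p^2)
}

#' Per-sample alpha diversity of an abundance table
#'
#' @param table an `abundance_table`.
#' @return data.frame with `sample_id`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(table) {
  data.frame(sample_id = sample_ids(table),
             shannon = apply(table$values, 2L, shannon_index),
             simpson = apply(table$values, 2L, simpson_index),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Construct / validate a sample distance matrix
#'
#' @param d symmetric non-negative matrix with zero diagonal and sample
#'   dimnames.
#' @return An object of class `distance_matrix`.
#' @export
distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix needs sample identifiers")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be exactly 0")
  if (any(d < 0)) stop("distances must be non-negative")
  structure(list(values = d, sample_ids = rownames(d)),
            class = "distance_matrix")
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(a, b) = sum |a_i - b_i| / sum (a_i + b_i)` over features; bounded in
#' \[0, 1\] for non-negative inputs.
#'
#' @param table an `abundance_table` with >= 2 samples.
#' @return A `distance_matrix`.
#' @export
bray_curtis <- function(table) {
  X <- table$values
  tot <- colSums(X)
  if (any(tot == 0)) {
    zz <- colnames(X)[tot == 0]
    stop("undefined Bray-Curtis distance for all-zero sample(s): ",
         paste(zz, collapse = ", "))
  }
  n <- ncol(X)
  # |a-b| = (a+b) - 2*min(a,b); vectorize via cross-products of mins
  d <- matrix(0, n, n, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(n - 1L)) {
    xi <- X[, i]
    rest <- (i + 1L):n
    s_min <- colSums(pmin(X[, rest, drop = FALSE], xi))
    dij <- 1 - 2 * s_min / (tot[i] + tot[rest])
    d[i, rest] <- dij
    d[rest, i] <- dij
  }
  distance_matrix(d)
}

#' Principal coordinates analysis (classical MDS)
#'
#' Eigendecomposition of the Gower double-centred matrix of squared
#' distances. Negative eigenvalues (possible for non-Euclidean inputs such
#' as Bray-Curtis) are truncated from the scores and from the
#' proportion-explained denominator, and reported separately.
#'
#' @param dist a `distance_matrix` of at least 3 samples.
#' @return An `ordination_result`: list with `scores` (samples x axes),
#'   `eigenvalues`, `prop_explained`, `negative_eigenvalues`, `constrained
#'   = FALSE`.
#' @export
pcoa <- function(dist) {
  D <- dist$values
  n <- nrow(D)
  if (n < 3L) stop("PCoA needs at least 3 samples")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  lam <- e$values[pos]
  scores <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lam), sum(pos))
  dimnames(scores) <- list(rownames(D), paste0("PCo", seq_len(sum(pos))))
  structure(list(scores = scores,
                 eigenvalues = lam,
                 prop_explained = lam / sum(lam),
                 negative_eigenvalues = e$values[e$values < -tol],
                 constrained = FALSE),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result>%s %d axes; first axes explain %s\n",
              if (x$constrained) " constrained;" else "",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * head(x$prop_explained, 3L)),
                    collapse = ", ")))
  invisible(x)
}

# among/within decomposition of squared distances for a label vector;
# returns c(SS_among, SS_within, SS_total)
.permanova_ss <- function(D2, groups) {
  n <- nrow(D2)
  ss_tot <- sum(D2[upper.tri(D2)]) / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ng <- length(idx)
    ss_w <- ss_w + sum(D2[idx, idx]) / (2 * ng)
  }
  c(among = ss_tot - ss_w, within = ss_w, total = ss_tot)
}

#' Permutational multivariate analysis of variance
#'
#' Pseudo-F from the among/within decomposition of squared distances, with
#' a permutation p-value using the `(1 + exceedances) / (1 + n_perm)`
#' convention (never exactly zero).
#'
#' @param dist a `distance_matrix`.
#' @param groups per-sample labels (>= 2 groups, each of size >= 2).
#' @param n_perm number of label permutations (>= 99).
#' @param seed integer seed fixing the permutation stream.
#' @return A `test_result` (method `"anova"`) with `statistic` = pseudo-F;
#'   attribute `"R2"` carries the among-group fraction of total sum of
#'   squares.
#' @export
permanova <- function(dist, groups, n_perm = 9999L, seed = 1L) {
  D <- dist$values
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(D))
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L))
    stop("perMANOVA needs >= 2 groups each with >= 2 samples")
  if (n_perm < 99L) stop("n_perm must be >= 99")
  k <- length(tab)
  n <- nrow(D)
  D2 <- D^2
  ss <- .permanova_ss(D2, groups)
  f_obs <- (ss["among"] / (k - 1)) / (ss["within"] / (n - k))
  # vectorized permutation F: SS_within per permutation via indicator
  # matrix products
  gl <- lapply(names(tab), function(g) groups == g)
  f_perm <- with_seed(seed, {
    P <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
    ssw <- numeric(n_perm)
    for (gi in seq_len(k)) {
      pos <- P[gl[[gi]], , drop = FALSE]
      Ig <- matrix(0, n, n_perm)
      Ig[cbind(as.vector(pos), rep(seq_len(n_perm), each = tab[gi]))] <- 1
      ssw <- ssw + colSums(Ig * (D2 %*% Ig)) / (2 * tab[gi])
    }
    ((ss["total"] - ssw) / (k - 1)) / (ssw / (n - k))
  })
  # count float-level ties as exceedances (conservative convention)
  eps <- 1e-9 * max(1, abs(f_obs))
  p <- (1 + sum(f_perm >= f_obs - eps)) / (1 + n_perm)
  res <- test_result(f_obs, p, 0L, "anova")
  attr(res, "R2") <- unname(ss["among"] / ss["total"])
  res
}

#' Distance-based redundancy analysis
#'
#' Constrained ordination: the positive-eigenvalue PCoA embedding is
#' regressed on group indicator variables; the constrained axes are the
#' principal directions of the fitted values. The constrained inertia
#' equals the perMANOVA among-group sum of squares on the same embedding.
#'
#' @param dist a `distance_matrix`.
#' @param groups per-sample labels with >= 2 distinct values.
#' @return An `ordination_result` with `constrained = TRUE`; `scores` hold
#'   the constrained axes (at most #groups - 1), `prop_explained` their
#'   share of the total (positive-eigenvalue) inertia, and attribute
#'   `"constrained_proportion"` the total constrained share.
#' @export
dbrda <- function(dist, groups) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L)
    stop("dbRDA needs at least 2 groups to constrain on")
  emb <- pcoa(dist)
  Y <- emb$scores
  stopifnot(length(groups) == nrow(Y))
  G <- stats::model.matrix(~ groups)
  H <- G %*% solve(crossprod(G)) %*% t(G)   # hat matrix of the constraint
  Yhat <- H %*% Y
  total_inertia <- sum(Y^2)
  sv <- svd(Yhat)
  k <- min(length(unique(groups)) - 1L, sum(sv$d > max(sv$d) * 1e-9))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k)
  dimnames(scores) <- list(rownames(Y), paste0("dbRDA", seq_len(k)))
  lam <- sv$d[seq_len(k)]^2
  structure(list(scores = scores,
                 eigenvalues = lam,
                 prop_explained = lam / total_inertia,
                 negative_eigenvalues = emb$negative_eigenvalues,
                 constrained = TRUE,
                 constrained_proportion = sum(Yhat^2) / total_inertia),
            class = "ordination_result")
}
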