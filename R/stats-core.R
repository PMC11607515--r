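#' Hypothesis-test result record
#'
#' Uniform return type for all statistical primitives. `direction` is +1
#' when the second (later-ordered) group's central tendency exceeds the
#' first's, -1 when it is lower, and 0 on an exact tie, so that positive
#' directions read as "elevated with disease stage".
#'
#' @param statistic test statistic.
#' @param p_value two-sided p-value in \[0, 1\].
#' @param direction -1, 0 or +1.
#' @param method one of `"wilcoxon"`, `"ttest"`, `"kruskal"`, `"jt"`,
#'   `"chi2"`, `"fisher"`, `"anova"`.
#' @return A list of class `test_result`.
#' @export
test_result <- function(statistic, p_value, direction, method) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12, direction %in% c(-1, 0, 1))
  structure(list(statistic = unname(statistic),
                 p_value = min(unname(p_value), 1),
                 direction = as.integer(direction),
                 method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic=%.6g, p=%.4g, direction=%+d\n",
              x$method, x$statistic, x$p_value, x$direction))
  invisible(x)
}

#' Two-sample Wilcoxon (Mann-Whitney) rank-sum test
#'
#' Two-sided test on the Mann-Whitney U statistic of `y` versus `x`. For
#' small tie-free samples (combined n below `exact_max`) the exact
#' permutation distribution is enumerated; otherwise a normal approximation
#' with tie-corrected variance and continuity correction is used.
#'
#' @param x,y numeric vectors (reference and case group).
#' @param exact_max largest combined sample size for automatic exact
#'   enumeration (tie-free data only).
#' @return A `test_result` with `statistic` = U of `y` over `x`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- length(x); m <- length(y)
  if (n < 1L || m < 1L || n + m < 2L)
    stop("both groups must be non-empty with combined length >= 2")
  z <- c(x, y)
  if (length(unique(z)) == 1L)
    return(test_result(n * m / 2, 1, 0L, "wilcoxon"))
  r <- rank(z)
  u_y <- sum(r[(n + 1L):(n + m)]) - m * (m + 1) / 2
  mu <- n * m / 2
  dir <- sign(u_y - mu)
  ties <- any(duplicated(z))
  if (!ties && n + m <= exact_max) {
    # exact null distribution of U by enumerating rank assignments
    idx <- combn(n + m, m)
    rr <- seq_len(n + m)
    us <- colSums(matrix(rr[idx], nrow = m)) - m * (m + 1) / 2
    p <- min(1, 2 * min(mean(us <= u_y), mean(us >= u_y)))
    return(test_result(u_y, p, dir, "wilcoxon"))
  }
  N <- n + m
  tab <- table(z)
  tie_term <- sum(tab^3 - tab) / (N * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(test_result(u_y, 1, 0L, "wilcoxon"))
  zstat <- (abs(u_y - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-max(zstat, 0)))
  test_result(u_y, p, dir, "wilcoxon")
}

#' Welch two-sample t-test
#'
#' Two-sided t-test with the Welch-Satterthwaite degrees of freedom.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return A `test_result` with `statistic` = t of `y` minus `x`.
#' @export
t_test_welch <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations")
  mx <- mean(x); my <- mean(y)
  vx <- var(x); vy <- var(y)
  dir <- sign(my - mx)
  if (vx == 0 && vy == 0) {
    if (mx == my) return(test_result(0, 1, 0L, "ttest"))
    return(test_result(sign(my - mx) * Inf, 0, dir, "ttest"))
  }
  se2 <- vx / length(x) + vy / length(y)
  tstat <- (my - mx) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x)^2 * (length(x) - 1)) +
                   vy^2 / (length(y)^2 * (length(y) - 1)))
  p <- min(1, 2 * pt(-abs(tstat), df))
  test_result(tstat, p, dir, "ttest")
}

#' Kruskal-Wallis k-group rank test
#'
#' H statistic with tie correction, referred to a chi-squared distribution
#' with k - 1 degrees of freedom.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return A `test_result`; `direction` compares the mean ranks of the last
#'   versus first group.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L || any(lengths(groups) == 0L))
    stop("need >= 2 non-empty groups")
  z <- unlist(groups, use.names = FALSE)
  N <- length(z)
  if (length(unique(z)) == 1L)
    return(test_result(0, 1, 0L, "kruskal"))
  r <- rank(z)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  H <- 12 / (N * (N + 1)) * sum(lengths(groups) * (rbar - (N + 1) / 2)^2)
  tab <- table(z)
  corr <- 1 - sum(tab^3 - tab) / (N^3 - N)
  H <- H / corr
  p <- pchisq(H, df = length(groups) - 1L, lower.tail = FALSE)
  dir <- sign(rbar[length(groups)] - rbar[1L])
  test_result(H, p, dir, "kruskal")
}

# JT statistic: sum over ordered group pairs of Mann-Whitney counts
# (#{earlier < later} + 0.5 #{ties}), computed from a pooled "less-than"
# matrix for reuse by the exact enumeration.
jt_statistic_from_matrix <- function(L, group_index, k) {
  s <- 0
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    s <- s + sum(L[group_index == i, group_index == j])
  s
}

#' Jonckheere-Terpstra trend test for ordered groups
#'
#' Tests for a monotone location trend across >= 3 groups in a declared
#' order (e.g. HC < SCAD < MI). The statistic is the sum of pairwise
#' Mann-Whitney counts over ordered group pairs. For combined n <=
#' `exact_max` the exact two-sided p is computed by full enumeration of
#' group-label assignments; otherwise a normal approximation with
#' tie-adjusted variance and continuity correction is used.
#'
#' @param groups ordered list of >= 3 non-empty numeric vectors.
#' @param exact_max largest combined n for automatic exact enumeration.
#' @return A `test_result` with `statistic` = JT.
#' @export
jonckheere_terpstra <- function(groups, exact_max = 12L) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[lengths(groups) > 0L]
  k <- length(groups)
  if (k < 3L) stop("the ordered trend test needs >= 3 non-empty groups")
  z <- unlist(groups, use.names = FALSE)
  ni <- lengths(groups)
  N <- length(z)
  if (length(unique(z)) == 1L)
    return(test_result(sum(ni %o% ni * upper.tri(diag(k))) / 2, 1, 0L, "jt"))
  gi <- rep(seq_len(k), ni)
  L <- outer(z, z, "<") + 0.5 * outer(z, z, "==")
  jt <- jt_statistic_from_matrix(L, gi, k)
  mu <- (N^2 - sum(ni^2)) / 4
  dir <- sign(jt - mu)
  if (N <= exact_max) {
    perms <- label_arrangements(ni)
    jts <- vapply(perms, function(g) jt_statistic_from_matrix(L, g, k),
                  numeric(1L))
    p <- min(1, 2 * min(mean(jts <= jt), mean(jts >= jt)))
    return(test_result(jt, p, dir, "jt"))
  }
  # tie-adjusted null variance (Hollander & Wolfe)
  tj <- as.numeric(table(z))
  A <- N * (N - 1) * (2 * N + 5) -
    sum(ni * (ni - 1) * (2 * ni + 5)) -
    sum(tj * (tj - 1) * (2 * tj + 5))
  B <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2))
  C <- sum(ni * (ni - 1)) * sum(tj * (tj - 1))
  V <- A / 72 + B / (36 * N * (N - 1) * (N - 2)) + C / (8 * N * (N - 1))
  if (V <= 0) return(test_result(jt, 1, 0L, "jt"))
  zstat <- (abs(jt - mu) - 0.5) / sqrt(V)
  p <- min(1, 2 * pnorm(-max(zstat, 0)))
  test_result(jt, p, dir, "jt")
}

# all distinct assignments of N pooled positions into groups of sizes `ni`,
# returned as integer group-index vectors
label_arrangements <- function(ni) {
  k <- length(ni)
  N <- sum(ni)
  out <- list()
  recurse <- function(remaining, assign, g) {
    if (g == k) {
      assign[remaining] <- k
      out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    picks <- combn(length(remaining), ni[g])
    for (cc in seq_len(ncol(picks))) {
      a <- assign
      sel <- remaining[picks[, cc]]
      a[sel] <- g
      recurse(setdiff(remaining, sel), a, g + 1L)
    }
  }
  recurse(seq_len(N), integer(N), 1L)
  out
}

#' Pearson chi-squared test on an r x c contingency table
#'
#' No continuity correction; degrees of freedom (r-1)(c-1). Reproduces the
#' published baseline-table p-values for categorical cohort variables.
#'
#' @param counts non-negative integer matrix, at least 2 x 2.
#' @return A `test_result`.
#' @export
chi_square_contingency <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table must be at least 2 x 2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("contingency counts must be non-negative integers")
  if (sum(counts) < 1) stop("contingency table grand total must be >= 1")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate margin: a row or column sums to zero")
  E <- outer(rs, cs) / sum(counts)
  stat <- sum((counts - E)^2 / E)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  test_result(stat, p, 0L, "chi2")
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Two-sided p as the sum of hypergeometric probabilities of tables (with
#' the same margins) no more probable than the observed one.
#'
#' @param counts 2 x 2 non-negative integer matrix.
#' @return A `test_result` with `statistic` = the sample odds ratio.
#' @export
fisher_exact_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)))
    stop("Fisher's exact test here requires a 2 x 2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("contingency counts must be non-negative integers")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate margin: a row or column sums to zero")
  N <- sum(counts)
  a_obs <- counts[1L, 1L]
  a_all <- max(0L, cs[1L] - rs[2L]):min(rs[1L], cs[1L])
  probs <- dhyper(a_all, rs[1L], rs[2L], cs[1L])
  p_obs <- dhyper(a_obs, rs[1L], rs[2L], cs[1L])
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- (counts[1L, 1L] * counts[2L, 2L]) / (counts[1L, 2L] * counts[2L, 1L])
  dir <- if (!is.finite(or)) 1L else sign(or - 1)
  test_result(or, p, dir, "fisher")
}

#' Fold change of a case group over a reference group
#'
#' Ratio of group means with an additive pseudocount:
#' `(mean(y) + pc) / (mean(x) + pc)`.
#'
#' @param x reference-group values.
#' @param y case-group values.
#' @param pseudocount additive constant; must be > 0 whenever a group mean
#'   is zero.
#' @return A strictly positive scalar.
#' @export
fold_change <- function(x, y, pseudocount = 0) {
  mx <- mean(x, na.rm = TRUE); my <- mean(y, na.rm = TRUE)
  if (mx + pseudocount == 0 && my + pseudocount == 0)
    stop("undefined fold change: both group means are zero with no pseudocount")
  if (mx + pseudocount == 0 || my + pseudocount == 0)
    stop("fold change requires a positive pseudocount when a group mean is zero")
  (my + pseudocount) / (mx + pseudocount)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns monotone q-values; `NA` p-values are preserved as `NA` and do not
#' enter the family size.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  out <- rep(NA_real_, length(p_values))
  if (m == 0L) return(out)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  out[ok] <- q
  out
}
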