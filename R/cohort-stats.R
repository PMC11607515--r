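#' Variable specification for the baseline table
#'
#' Declares how a metadata variable is summarized and tested:
#' `continuous_normal` (mean +/- sd, one-way ANOVA), `continuous_skewed`
#' (median (IQR), Kruskal-Wallis), `categorical` (n (%), chi-squared, or
#' Fisher for 2 x 2 tables with a small expected count). `auto` picks
#' between the two continuous types with a Shapiro-Wilk normality gate at
#' alpha = 0.05 within each group, and `categorical` for non-numeric
#' columns.
#'
#' @param name metadata column name.
#' @param type one of `"auto"`, `"continuous_normal"`,
#'   `"continuous_skewed"`, `"categorical"`.
#' @return A list of class `variable_spec`.
#' @export
variable_spec <- function(name, type = c("auto", "continuous_normal",
                                         "continuous_skewed",
                                         "categorical")) {
  structure(list(name = name, type = match.arg(type)),
            class = "variable_spec")
}

.resolve_type <- function(x, groups, type) {
  if (type != "auto") return(type)
  if (!is.numeric(x)) return("categorical")
  # low-cardinality numerics (0/1 indicators, small ordinal codes) are
  # treated as categorical
  if (length(unique(x[!is.na(x)])) <= 4L) return("categorical")
  normal <- vapply(split(x, groups), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3L || sd(v) == 0) return(TRUE)
    shapiro.test(v)$p.value >= 0.05
  }, logical(1L))
  if (all(normal)) "continuous_normal" else "continuous_skewed"
}

.summarise_var <- function(x, type) {
  if (type == "continuous_normal")
    return(sprintf("%.2f ± %.2f", mean(x, na.rm = TRUE),
                   sd(x, na.rm = TRUE)))
  if (type == "continuous_skewed") {
    qs <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
    return(sprintf("%.2f (%.2f, %.2f)", qs[2L], qs[1L], qs[3L]))
  }
  stop("internal: categorical summaries handled separately")
}

#' Baseline characteristics table
#'
#' Group-wise summaries and an across-group p-value for each declared
#' variable, following the standard cohort-table conventions: one-way
#' ANOVA for normal continuous variables, Kruskal-Wallis for skewed ones,
#' chi-squared (no continuity correction) for categorical variables with
#' Fisher's exact test substituted for 2 x 2 tables containing an expected
#' count below 5.
#'
#' @param meta a `cohort_metadata`.
#' @param specs list of [variable_spec()]s (or bare column names, treated
#'   as `auto`).
#' @return data.frame of class `baseline_table`: one row per variable with
#'   a summary column per group, the resolved `type`, `test`, `p_value`
#'   and a 3-decimal `p_display`.
#' @export
baseline_table <- function(meta, specs) {
  specs <- lapply(specs, function(s)
    if (inherits(s, "variable_spec")) s else variable_spec(s))
  groups <- meta$group
  glev <- levels(groups)[levels(groups) %in% groups]
  rows <- lapply(specs, function(sp) {
    if (!sp$name %in% names(meta))
      stop("variable '", sp$name, "' not found in metadata")
    x <- meta[[sp$name]]
    type <- .resolve_type(x, groups, sp$type)
    if (type == "categorical") {
      tab <- table(x, groups)[, glev, drop = FALSE]
      use_fisher <- all(dim(tab) == 2L) &&
        any(outer(rowSums(tab), colSums(tab)) / sum(tab) < 5)
      res <- if (use_fisher) fisher_exact_2x2(tab)
      else chi_square_contingency(tab)
      lev1 <- rownames(tab)[nrow(tab)]  # summarize the last level's share
      summ <- vapply(glev, function(g) {
        n <- tab[lev1, g]
        sprintf("%d (%.1f%%)", n, 100 * n / sum(tab[, g]))
      }, character(1L))
      test <- res$method
    } else {
      gs <- split(x, groups)[glev]
      if (type == "continuous_normal") {
        if (all(vapply(gs, function(v) sd(v, na.rm = TRUE), 1) == 0) &&
            length(unique(unlist(gs))) == 1L) {
          res <- test_result(0, 1, 0L, "anova")
        } else {
          fit <- aov(x ~ groups)
          pv <- summary(fit)[[1L]][["Pr(>F)"]][1L]
          st <- summary(fit)[[1L]][["F value"]][1L]
          if (is.na(pv)) { pv <- 1; st <- 0 }
          res <- test_result(st, pv, 0L, "anova")
        }
      } else {
        res <- kruskal_wallis(gs)
      }
      summ <- vapply(gs, .summarise_var, character(1L), type = type)
      test <- res$method
    }
    c(list(variable = sp$name, type = type), as.list(summ),
      list(test = test, p_value = res$p_value,
           p_display = sprintf("%.3f", round(res$p_value, 3L))))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("baseline_table", "data.frame")
  out
}

#' Pairwise group contrasts for one variable
#'
#' Two-group tests for each requested pair (default all ordered pairs):
#' Welch t-test for normal continuous variables, Mann-Whitney otherwise.
#' Pairs are flagged `a`, `b`, `c`, ... in order when p < 0.05, following
#' the usual baseline-table footnote scheme.
#'
#' @param meta a `cohort_metadata`.
#' @param spec a [variable_spec()] or column name.
#' @param pairs list of 2-vectors of group labels; default all ordered
#'   pairs of the observed groups.
#' @param alpha flag threshold.
#' @return data.frame `pair`, `statistic`, `p_value`, `direction`, `flag`.
#' @export
pairwise_contrasts <- function(meta, spec, pairs = NULL, alpha = 0.05) {
  if (!inherits(spec, "variable_spec")) spec <- variable_spec(spec)
  if (!spec$name %in% names(meta))
    stop("variable '", spec$name, "' not found in metadata")
  x <- meta[[spec$name]]
  groups <- meta$group
  glev <- levels(groups)[levels(groups) %in% groups]
  if (is.null(pairs)) pairs <- combn(glev, 2L, simplify = FALSE)
  type <- .resolve_type(x, groups, spec$type)
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    if (!all(pr %in% glev)) stop("pair references an absent group")
    a <- x[groups == pr[1L]]; b <- x[groups == pr[2L]]
    if (length(a) == 0L || length(b) == 0L)
      stop("empty group in pair ", paste(pr, collapse = "-"))
    res <- if (type == "continuous_normal") t_test_welch(a, b)
    else wilcoxon_rank_sum(a, b)
    data.frame(pair = paste(pr, collapse = " vs "),
               statistic = res$statistic, p_value = res$p_value,
               direction = res$direction,
               flag = if (res$p_value < alpha) letters[i] else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
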