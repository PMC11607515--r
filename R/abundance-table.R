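#' Construct an abundance table
#'
#' The common carrier for the three omics layers: a dense non-negative
#' numeric matrix of features (rows) by samples (columns) together with a
#' layer tag (`"species"`, `"ko"` or `"metabolite"`).
#'
#' @param values numeric matrix, features x samples, with unique rownames
#'   (feature identifiers) and unique colnames (sample identifiers). All
#'   entries must be finite and >= 0.
#' @param kind one of `"species"`, `"ko"`, `"metabolite"`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, kind = c("species", "ko", "metabolite")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry feature rownames and sample colnames")
  if (nrow(values) < 1L || ncol(values) < 2L)
    stop("an abundance table needs at least 1 feature and 2 samples")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("abundance values must be finite")
  if (any(values < 0))
    stop("abundance values must be non-negative")
  structure(list(values = values, kind = kind), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> kind=%s: %d features x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname abundance_table
#' @param x an `abundance_table`.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname abundance_table
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read an abundance table from tab-separated text
#'
#' Expects a header row of sample identifiers, a first column of feature
#' identifiers, and a numeric body.
#'
#' @param path path to a TSV file.
#' @inheritParams abundance_table
#' @return An `abundance_table`.
#' @export
read_abundance_table <- function(path, kind = c("species", "ko", "metabolite")) {
  kind <- match.arg(kind)
  nf <- utils::count.fields(path, sep = "\t", quote = "\"")
  if (length(unique(nf)) > 1L)
    stop("ragged rows in ", path, ": field counts ",
         paste(unique(nf), collapse = "/"))
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 3L) stop("expected a feature-id column plus >= 2 samples")
  hdr <- colnames(df)[-1L]
  if (anyDuplicated(hdr))   # data.frame extraction would silently rename
    stop("duplicate sample identifiers: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  feats <- df[[1L]]
  body <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(body) <- "double")
  if (anyNA(body)) {
    bad <- which(is.na(body), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at feature '%s', sample '%s'",
                 feats[bad[1L]], colnames(body)[bad[2L]]))
  }
  rownames(body) <- feats
  abundance_table(body, kind)
}

#' Write an abundance table as tab-separated text
#'
#' @param table an `abundance_table`.
#' @param path output file path.
#' @param id_column name for the feature-identifier column.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path, id_column = "feature_id") {
  df <- data.frame(rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a table to per-sample relative abundances
#'
#' Each sample column is divided by its total so that it sums to one; zeros
#' are preserved. Idempotent.
#'
#' @param table an `abundance_table`.
#' @return An `abundance_table` with unit column sums.
#' @export
to_relative <- function(table) {
  tot <- colSums(table$values)
  if (any(tot == 0))
    stop("degenerate sample(s) with all-zero abundance: ",
         paste(colnames(table$values)[tot == 0], collapse = ", "))
  out <- sweep(table$values, 2L, tot, "/")
  abundance_table(out, table$kind)
}

#' Filter features by prevalence
#'
#' Retains features observed (non-zero) in strictly more than
#' `min_prevalence` of the samples; the boundary is exclusive, so a feature
#' present in exactly 5% of samples is dropped at the default gate.
#'
#' @param table an `abundance_table`.
#' @param min_prevalence fraction in \[0, 1\].
#' @return An `abundance_table` restricted to the retained features, in the
#'   original order. An empty result is allowed and reported via a message.
#' @export
filter_prevalence <- function(table, min_prevalence = 0.05) {
  if (min_prevalence < 0 || min_prevalence > 1)
    stop("`min_prevalence` must lie in [0, 1]")
  prev <- rowMeans(table$values > 0)
  keep <- prev > min_prevalence
  if (!any(keep))
    message("filter_prevalence: no feature exceeds prevalence ", min_prevalence)
  out <- table
  out$values <- table$values[keep, , drop = FALSE]
  out
}
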