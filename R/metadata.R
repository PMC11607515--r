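#' Per-sample cohort metadata
#'
#' Holds the ordered disease-stage label for every sample plus any number of
#' continuous clinical phenotype columns (Gensini, Syntax, cTnI, TIMI, ...).
#' Missing phenotype values are allowed and are excluded pairwise downstream.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param group character or factor of per-sample stage labels.
#' @param phenotypes optional data.frame of numeric phenotype columns, one
#'   row per sample in the same order as `sample_ids`.
#' @param levels the ordered stage labels, from least to most severe.
#' @return An object of class `cohort_metadata`: a data.frame with columns
#'   `sample_id`, `group` (ordered factor) and the phenotype columns.
#' @export
cohort_metadata <- function(sample_ids, group, phenotypes = NULL,
                            levels = c("HC", "SCAD", "MI")) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers in metadata")
  group <- as.character(group)
  if (length(group) != length(sample_ids))
    stop("`group` must have one label per sample")
  bad <- setdiff(unique(group), levels)
  if (length(bad))
    stop("group labels outside the declared ordered set: ",
         paste(bad, collapse = ", "))
  df <- data.frame(sample_id = sample_ids,
                   group = factor(group, levels = levels, ordered = TRUE),
                   stringsAsFactors = FALSE)
  if (!is.null(phenotypes)) {
    phenotypes <- as.data.frame(phenotypes)
    if (nrow(phenotypes) != length(sample_ids))
      stop("`phenotypes` must have one row per sample")
    if (!all(vapply(phenotypes, is.numeric, logical(1L))))
      stop("phenotype columns must be numeric")
    df <- cbind(df, phenotypes)
  }
  class(df) <- c("cohort_metadata", "data.frame")
  df
}

#' @export
print.cohort_metadata <- function(x, ...) {
  cat(sprintf("<cohort_metadata> %d samples; groups: %s; phenotypes: %s\n",
              nrow(x), paste(levels(x$group), collapse = " < "),
              paste(setdiff(names(x), c("sample_id", "group")), collapse = ", ")))
  invisible(x)
}

#' @rdname cohort_metadata
#' @param path TSV path with a `sample_id` column, a mandatory `group`
#'   column, and numeric phenotype columns.
#' @export
read_metadata <- function(path, levels = c("HC", "SCAD", "MI")) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("metadata must contain 'sample_id' and 'group' columns")
  ph <- df[, setdiff(names(df), c("sample_id", "group")), drop = FALSE]
  if (ncol(ph) == 0L) ph <- NULL
  cohort_metadata(df$sample_id, df$group, ph, levels = levels)
}

#' @rdname cohort_metadata
#' @param meta a `cohort_metadata`.
#' @export
write_metadata <- function(meta, path) {
  out <- as.data.frame(meta)
  out$group <- as.character(out$group)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align an abundance table with cohort metadata
#'
#' Samples are matched by identifier intersection; non-overlapping samples
#' on either side are dropped with a warning, and an empty intersection is
#' an error.
#'
#' @param table an `abundance_table`.
#' @param meta a `cohort_metadata`.
#' @return A list with the subsetted `table` and `meta`, sample order taken
#'   from the table.
#' @export
align_samples <- function(table, meta) {
  shared <- intersect(sample_ids(table), meta$sample_id)
  if (length(shared) == 0L)
    stop("no overlap between table samples and metadata samples")
  n_drop <- (ncol(table$values) - length(shared)) +
    (nrow(meta) - length(shared))
  if (n_drop > 0L)
    warning(sprintf("align_samples: dropping %d non-overlapping sample(s)", n_drop))
  shared <- sample_ids(table)[sample_ids(table) %in% shared]
  tab <- table
  tab$values <- table$values[, shared, drop = FALSE]
  m <- meta[match(shared, meta$sample_id), , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- class(meta)
  list(table = tab, meta = m)
}

#' KO to KEGG-module membership map
#'
#' Many-to-many membership of KEGG Orthology identifiers in KEGG modules.
#'
#' @param ko_id,module_id character vectors of equal length; duplicated
#'   (ko, module) pairs are an error.
#' @param module_names optional named character vector, module_id -> label.
#' @return An object of class `module_map`: a data.frame with columns
#'   `ko_id` and `module_id`.
#' @export
module_map <- function(ko_id, module_id, module_names = NULL) {
  ko_id <- as.character(ko_id)
  module_id <- as.character(module_id)
  if (length(ko_id) != length(module_id))
    stop("`ko_id` and `module_id` must be the same length")
  if (length(ko_id) == 0L) stop("module map must contain at least one entry")
  key <- paste(ko_id, module_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (ko_id, module_id) pairs in module map")
  df <- data.frame(ko_id = ko_id, module_id = module_id,
                   stringsAsFactors = FALSE)
  attr(df, "module_names") <- module_names
  class(df) <- c("module_map", "data.frame")
  df
}

#' @rdname module_map
#' @param path a 2-column TSV (ko_id, module_id) with a header.
#' @export
read_module_map <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("module map TSV needs two columns (ko_id, module_id)")
  module_map(df[[1L]], df[[2L]])
}

#' @rdname module_map
#' @param map a `module_map`.
#' @export
write_module_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
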