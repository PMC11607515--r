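#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis chain in one validated
#' list. Defaults are the published operating points of the workflow:
#' raw p < 0.01 with fold change > 1.2 or < 0.83 for the species screen,
#' q < 0.05 for the metabolite cross-comparison (set A), p < 0.05 for the
#' trend/k-group branch (set B), |reporter score| > 1.6, soft-threshold
#' power beta = 14 with deepSplit 4 for metabotyping, 9999 permutations for
#' perMANOVA, a strict 5% prevalence gate, and FDR < 0.1 for phenotype
#' associations.
#'
#' @param p_species raw p-value gate of the species screen.
#' @param fc_high,fc_low strict fold-change gates (case/reference ratio).
#' @param q_metabolite BH q gate for cross-comparison set A.
#' @param p_setB raw p gate for the trend / k-group branch (set B).
#' @param reporter_threshold absolute reporter-score significance cut.
#' @param soft_power_beta soft-threshold exponent of the signed adjacency.
#' @param deep_split dynamic tree cut sensitivity level, integer 0-4.
#' @param n_permutations label permutations for perMANOVA.
#' @param prevalence_min strict prevalence gate (fraction of samples).
#' @param fdr_phenotype BH FDR gate for phenotype associations.
#' @param background_draws random KO sets per module size for the
#'   reporter-score background correction.
#' @param min_cluster_size smallest branch kept as a metabotype.
#' @param pseudocount additive pseudocount for fold changes; `NULL` means
#'   half the smallest non-zero value of the table at hand.
#' @param random_seed integer seed governing every stochastic step.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(p_species = 0.01,
                            fc_high = 1.2,
                            fc_low = 0.83,
                            q_metabolite = 0.05,
                            p_setB = 0.05,
                            reporter_threshold = 1.6,
                            soft_power_beta = 14,
                            deep_split = 4L,
                            n_permutations = 9999L,
                            prevalence_min = 0.05,
                            fdr_phenotype = 0.1,
                            background_draws = 1000L,
                            min_cluster_size = 5L,
                            pseudocount = NULL,
                            random_seed = 1L) {
  cfg <- list(p_species = p_species, fc_high = fc_high, fc_low = fc_low,
              q_metabolite = q_metabolite, p_setB = p_setB,
              reporter_threshold = reporter_threshold,
              soft_power_beta = soft_power_beta,
              deep_split = as.integer(deep_split),
              n_permutations = as.integer(n_permutations),
              prevalence_min = prevalence_min,
              fdr_phenotype = fdr_phenotype,
              background_draws = as.integer(background_draws),
              min_cluster_size = as.integer(min_cluster_size),
              pseudocount = pseudocount,
              random_seed = as.integer(random_seed))
  for (nm in c("p_species", "q_metabolite", "p_setB", "prevalence_min",
               "fdr_phenotype")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop("`", nm, "` must lie in (0, 1)")
  }
  if (!(cfg$fc_low < 1 && 1 < cfg$fc_high))
    stop("fold-change gates must satisfy fc_low < 1 < fc_high")
  if (!cfg$deep_split %in% 0:4) stop("`deep_split` must be in {0,...,4}")
  if (cfg$n_permutations < 99L) stop("`n_permutations` must be >= 99")
  if (cfg$background_draws < 100L) stop("`background_draws` must be >= 100")
  if (cfg$reporter_threshold <= 0) stop("`reporter_threshold` must be > 0")
  if (cfg$soft_power_beta < 1) stop("`soft_power_beta` must be >= 1")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %s\n", nm,
                if (is.null(x[[nm]])) "auto" else format(x[[nm]])))
  invisible(x)
}

#' Read a pipeline configuration from a YAML key-value file
#'
#' Keys mirror the arguments of [pipeline_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Resolve the fold-change pseudocount for a table
#'
#' The default convention is half the smallest non-zero value.
#'
#' @param config a `pipeline_config`.
#' @param values numeric matrix of abundances.
#' @return A positive scalar.
#' @keywords internal
resolve_pseudocount <- function(config, values) {
  if (!is.null(config$pseudocount)) return(config$pseudocount)
  pos <- values[values > 0]
  if (length(pos) == 0L) stop("cannot derive a pseudocount from an all-zero table")
  min(pos) / 2
}
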