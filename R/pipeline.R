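#' Run the full multi-omics analysis pipeline
#'
#' Orchestrates the analysis chain on either a directory of input TSVs
#' (`species.tsv`, `ko.tsv`, `metabolite.tsv`, `metadata.tsv`,
#' `module_map.tsv`) or a synthetic cohort generated on the fly. Stages:
#' `simulate` (or load), `diversity`, `screen`, `reporter`, `metabotype`,
#' `integrate`, `baseline`. Every stage writes TSV outputs into
#' `output_dir` and the run ends with a JSON manifest (`manifest.json`)
#' echoing the configuration, the seed and the per-stage output paths.
#'
#' @param output_dir directory for all outputs (created if absent).
#' @param config a [pipeline_config()].
#' @param input_dir directory of input TSVs; `NULL` for a synthetic run.
#' @param design a [cohort_design()] used when `input_dir` is `NULL`; its
#'   seed is overridden by `config$random_seed`.
#' @param stages character vector selecting stages to run (dependencies are
#'   loaded from earlier stage logic in-memory, so later stages require the
#'   earlier ones in the same call).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(output_dir,
                         config = pipeline_config(),
                         input_dir = NULL,
                         design = cohort_design(),
                         stages = c("diversity", "screen", "reporter",
                                    "metabotype", "integrate", "baseline")) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(packageVersion("micromet")),
                   seed = config$random_seed,
                   config = unclass(config),
                   synthetic = is.null(input_dir),
                   stages = list())
  note <- function(stage, paths, secs) {
    manifest$stages[[stage]] <<- list(outputs = paths,
                                      elapsed_s = round(secs, 3L))
  }
  t0 <- proc.time()[["elapsed"]]
  if (is.null(input_dir)) {
    design$seed <- config$random_seed
    cohort <- generate_cohort(design)
    dir.create(file.path(output_dir, "inputs"), showWarnings = FALSE)
    write_cohort(cohort, file.path(output_dir, "inputs"))
    note("simulate", file.path(output_dir, "inputs",
                               c("species.tsv", "ko.tsv", "metabolite.tsv",
                                 "metadata.tsv", "module_map.tsv")),
         proc.time()[["elapsed"]] - t0)
  } else {
    need <- c("species.tsv", "ko.tsv", "metabolite.tsv", "metadata.tsv",
              "module_map.tsv")
    missing <- need[!file.exists(file.path(input_dir, need))]
    if (length(missing))
      stop("stage load: missing input file(s): ",
           paste(missing, collapse = ", "))
    cohort <- list(
      species = read_abundance_table(file.path(input_dir, "species.tsv"),
                                     "species"),
      ko = read_abundance_table(file.path(input_dir, "ko.tsv"), "ko"),
      metabolite = read_abundance_table(
        file.path(input_dir, "metabolite.tsv"), "metabolite"),
      meta = read_metadata(file.path(input_dir, "metadata.tsv")),
      map = read_module_map(file.path(input_dir, "module_map.tsv")))
    note("load", file.path(input_dir, need),
         proc.time()[["elapsed"]] - t0)
  }
  meta <- cohort$meta
  eigens <- NULL
  mod_act <- NULL

  run_stage <- function(stage, fn) {
    if (!stage %in% stages) return(invisible())
    t1 <- proc.time()[["elapsed"]]
    paths <- tryCatch(fn(), error = function(e)
      stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))
    note(stage, paths, proc.time()[["elapsed"]] - t1)
  }

  run_stage("diversity", function() {
    rel <- to_relative(cohort$species)
    div <- alpha_diversity(rel)
    bc <- bray_curtis(rel)
    ord <- pcoa(bc)
    pm <- permanova(bc, meta$group, n_perm = config$n_permutations,
                    seed = config$random_seed)
    db <- dbrda(bc, meta$group)
    p1 <- file.path(output_dir, "alpha_diversity.tsv")
    write.table(div, p1, sep = "\t", quote = FALSE, row.names = FALSE)
    p2 <- file.path(output_dir, "bray_curtis.tsv")
    write.table(data.frame(sample_id = rownames(bc$values), bc$values,
                           check.names = FALSE),
                p2, sep = "\t", quote = FALSE, row.names = FALSE)
    p3 <- file.path(output_dir, "pcoa_scores.tsv")
    write.table(data.frame(sample_id = rownames(ord$scores), ord$scores,
                           check.names = FALSE),
                p3, sep = "\t", quote = FALSE, row.names = FALSE)
    p4 <- file.path(output_dir, "permanova.json")
    jsonlite::write_json(
      list(pseudo_F = res_num(pm$statistic), p_value = res_num(pm$p_value),
           R2 = res_num(attr(pm, "R2")),
           n_permutations = config$n_permutations,
           dbrda_constrained_proportion =
             res_num(db$constrained_proportion)),
      p4, auto_unbox = TRUE, digits = NA)
    c(p1, p2, p3, p4)
  })

  screen <- NULL
  run_stage("screen", function() {
    screen <<- screen_species(cohort$species, meta, config = config)
    hits <- screen$feature_id[screen$passes]
    p1 <- file.path(output_dir, "species_screen.tsv")
    write.table(as.data.frame(screen), p1, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- p1
    if (length(hits) >= 1L) {
      corr <- species_phenotype_correlation(cohort$species, meta,
                                            features = hits)
      p2 <- file.path(output_dir, "species_phenotype_rho.tsv")
      p3 <- file.path(output_dir, "species_phenotype_q.tsv")
      write.table(data.frame(feature_id = rownames(corr$rho), corr$rho,
                             check.names = FALSE),
                  p2, sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(data.frame(feature_id = rownames(corr$q), corr$q,
                             check.names = FALSE),
                  p3, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p2, p3)
    }
    paths
  })

  run_stage("reporter", function() {
    kd <- ko_differential(cohort$ko, meta, config = config)
    rs <- reporter_score(kd, cohort$map, config = config)
    mod_act <<- module_activity(cohort$ko, cohort$map)
    p1 <- file.path(output_dir, "ko_differential.tsv")
    p2 <- file.path(output_dir, "reporter_scores.tsv")
    write.table(kd, p1, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(rs), p2, sep = "\t", quote = FALSE,
                row.names = FALSE)
    c(p1, p2)
  })

  run_stage("metabotype", function() {
    mt <- metabotype(cohort$metabolite, meta, config = config)
    eigens <<- mt$eigen
    p1 <- file.path(output_dir, "metabotype_assignment.tsv")
    p2 <- file.path(output_dir, "metabotype_eigen.tsv")
    p3 <- file.path(output_dir, "metabotype_diagnostics.json")
    write.table(as.data.frame(mt$assignment), p1, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(cluster = rownames(mt$eigen), mt$eigen,
                           check.names = FALSE),
                p2, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(scale_free_r2 = res_num(mt$scale_free_r2),
           n_selected = sum(mt$selection$selected),
           cluster_sizes = as.list(attr(mt$assignment, "sizes"))),
      p3, auto_unbox = TRUE, digits = NA)
    c(p1, p2, p3)
  })

  run_stage("integrate", function() {
    if (is.null(eigens) || is.null(mod_act))
      stop("requires the reporter and metabotype stages")
    grid <- module_metabotype_grid(mod_act, eigens, config)
    paths <- character()
    for (layer in c("rho", "q", "tier")) {
      p <- file.path(output_dir, sprintf("grid_%s.tsv", layer))
      write.table(data.frame(module_id = rownames(grid[[layer]]),
                             grid[[layer]], check.names = FALSE),
                  p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
    p <- file.path(output_dir, "grid_long.tsv")
    write.table(grid_long(grid), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
    phen <- setdiff(names(meta), c("sample_id", "group"))
    assoc <- do.call(rbind, c(
      lapply(phen, function(ph)
        rbind(phenotype_association(mod_act, meta, ph, config),
              phenotype_association(eigens, meta, ph, config))),
      list(rbind(
        phenotype_association(mod_act, meta,
                              head(levels(meta$group), 2L), config),
        phenotype_association(eigens, meta,
                              head(levels(meta$group), 2L), config)))))
    p2 <- file.path(output_dir, "phenotype_associations.tsv")
    write.table(assoc, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    c(paths, p2)
  })

  run_stage("baseline", function() {
    phen <- setdiff(names(meta), c("sample_id", "group"))
    if (length(phen) == 0L) return(character())
    bt <- baseline_table(meta, as.list(phen))
    p1 <- file.path(output_dir, "baseline_table.tsv")
    write.table(as.data.frame(bt), p1, sep = "\t", quote = FALSE,
                row.names = FALSE)
    p1
  })

  mpath <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

# strip names/attributes for JSON scalars
res_num <- function(x) as.numeric(unname(x))
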