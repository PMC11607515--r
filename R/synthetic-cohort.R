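#' Synthetic cohort design
#'
#' Parameters of the planted-truth generator that emulates a three-stage
#' disease cohort (healthy controls, stable disease, infarction) profiled by
#' species-level metagenomics, KEGG-Orthology functional profiles, and
#' untargeted serum metabolomics.
#'
#' The defaults mirror the cohort layout the pipeline targets: 36/64/46
#' samples across HC < SCAD < MI. Species abundances are heavy-tailed
#' log-normal compositions; ten planted species carry a multiplicative
#' disease effect applied before compositional closure, ramped monotonically
#' over the stages (square root of the full effect in SCAD, full effect in
#' MI). KO abundances are induced from species through a sparse binary
#' incidence matrix, with the KOs of planted "enriched" modules carried by
#' the planted species of matching direction. Metabolite features follow a
#' latent-factor model (loading 0.8, residual sd 0.6 on the log scale) with
#' stage-monotone mean shifts on the latent factors, exponentiated to
#' positive intensities. Clinical phenotypes are stage-monotone with noise.
#'
#' @param group_sizes named integer vector `(HC, SCAD, MI)`.
#' @param n_species,n_kos,n_metabolites table dimensions.
#' @param n_modules number of KEGG modules in the map.
#' @param kos_per_module KOs mapped to each module (disjoint sets).
#' @param n_latent_clusters number of latent metabolite co-abundance
#'   clusters (features split evenly).
#' @param n_diff_species planted differential species (60% enriched in
#'   disease, the rest depleted).
#' @param species_effect multiplicative abundance effect in the MI group for
#'   planted species (SCAD receives its square root); must be > 0.
#' @param n_enriched_modules planted modules (half up, half down).
#' @param carriers_per_ko species carrying each KO.
#' @param cluster_shifts per-cluster latent-factor mean shift per stage
#'   step (recycled/truncated to `n_latent_clusters`); 0 disables a shift.
#' @param loading,metab_noise_sd latent-factor loading and residual sd.
#' @param species_meanlog_sd spread of per-species baseline log abundance.
#' @param species_noise_sd per-sample log-normal noise sd of species.
#' @param ko_noise_sd extra log-normal noise on induced KO abundances.
#' @param phenotype_effect stage-step effect size (in residual sd units) of
#'   the simulated clinical phenotypes.
#' @param seed integer master seed; species, KO, metabolite and phenotype
#'   streams use independent sub-seeds so regenerating one layer does not
#'   perturb the others.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(group_sizes = c(HC = 36L, SCAD = 64L, MI = 46L),
                          n_species = 100L,
                          n_kos = 400L,
                          n_modules = 20L,
                          kos_per_module = 8L,
                          n_metabolites = 200L,
                          n_latent_clusters = 5L,
                          n_diff_species = 10L,
                          species_effect = 4,
                          n_enriched_modules = 4L,
                          carriers_per_ko = 3L,
                          cluster_shifts = c(1.2, -1.2, 0.8, -0.8, 0.5),
                          loading = 0.8,
                          metab_noise_sd = 0.6,
                          species_meanlog_sd = 1.5,
                          species_noise_sd = 1,
                          ko_noise_sd = 0.3,
                          phenotype_effect = 1,
                          seed = 20260101L) {
  d <- as.list(environment())
  if (any(d$group_sizes <= 0L)) stop("all group sizes must be positive")
  if (sum(d$group_sizes) < 10L) stop("cohort must contain at least 10 samples")
  if (d$species_effect <= 0)
    stop("design error: multiplicative species effects must be positive")
  if (d$n_modules * d$kos_per_module > d$n_kos)
    stop("not enough KOs for the requested module map")
  if (d$n_diff_species > d$n_species)
    stop("more planted species than species")
  if (d$n_enriched_modules > d$n_modules)
    stop("more planted modules than modules")
  d$cluster_shifts <- rep_len(d$cluster_shifts, d$n_latent_clusters)
  class(d) <- "cohort_design"
  d
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Produces the three abundance tables, the cohort metadata, a KO-to-module
#' map, and a `truth` record listing every planted effect so downstream
#' recovery can be scored. Fully reproducible from `design$seed`.
#'
#' @param design a [cohort_design()].
#' @return A list with elements `species`, `ko`, `metabolite`
#'   (`abundance_table`s), `meta` (`cohort_metadata`), `map` (`module_map`)
#'   and `truth`.
#' @export
generate_cohort <- function(design = cohort_design()) {
  stopifnot(inherits(design, "cohort_design"))
  d <- design
  n <- sum(d$group_sizes)
  grp <- rep(names(d$group_sizes), d$group_sizes)
  gidx <- rep(seq_along(d$group_sizes) - 1L, d$group_sizes)  # 0,1,2
  samples <- sprintf("S%03d", seq_len(n))
  species_ids <- sprintf("sp%03d", seq_len(d$n_species))
  ko_ids <- sprintf("K%05d", seq_len(d$n_kos))
  met_ids <- sprintf("feat%04d", seq_len(d$n_metabolites))
  mod_ids <- sprintf("M%05d", seq_len(d$n_modules))

  ## --- planted structure (master seed) ---------------------------------
  plan <- with_seed(d$seed, {
    diff_sp <- if (d$n_diff_species > 0L)
      sample(species_ids, d$n_diff_species) else character()
    n_up <- ceiling(d$n_diff_species * 0.6)
    sp_dir <- rep(c(1L, -1L), c(n_up, d$n_diff_species - n_up))
    planted_mod <- if (d$n_enriched_modules > 0L)
      sample(mod_ids, d$n_enriched_modules) else character()
    mod_dir <- rep_len(c(1L, -1L), d$n_enriched_modules)
    list(diff_sp = diff_sp, sp_dir = sp_dir,
         planted_mod = planted_mod, mod_dir = mod_dir)
  })
  sp_effect <- setNames(rep(1, d$n_species), species_ids)
  # stage ramp: effect^(1/2) in SCAD, effect in MI (monotone trend)
  eff_by_stage <- function(e, g) e^(g / 2)

  ## --- species table (sub-seed +1) -------------------------------------
  species_abs <- with_seed(d$seed + 1L, {
    meanlog <- rnorm(d$n_species, 0, d$species_meanlog_sd)
    noise <- matrix(rnorm(d$n_species * n, 0, d$species_noise_sd),
                    d$n_species, n)
    A <- exp(meanlog + noise)
    if (length(plan$diff_sp)) {
      for (i in seq_along(plan$diff_sp)) {
        s <- plan$diff_sp[i]
        e <- if (plan$sp_dir[i] > 0) d$species_effect else 1 / d$species_effect
        row <- match(s, species_ids)
        A[row, ] <- A[row, ] * eff_by_stage(e, gidx)
      }
    }
    if (any(A < 0)) stop("design error: negative species abundance generated")
    dimnames(A) <- list(species_ids, samples)
    A
  })
  species_rel <- sweep(species_abs, 2L, colSums(species_abs), "/")
  species_tab <- abundance_table(species_rel, "species")

  ## --- KO table (sub-seed +2) ------------------------------------------
  map_df <- data.frame(
    ko_id = ko_ids[seq_len(d$n_modules * d$kos_per_module)],
    module_id = rep(mod_ids, each = d$kos_per_module),
    stringsAsFactors = FALSE)
  up_sp <- plan$diff_sp[plan$sp_dir > 0]
  dn_sp <- plan$diff_sp[plan$sp_dir < 0]
  neutral_sp <- setdiff(species_ids, plan$diff_sp)
  ko_tab <- with_seed(d$seed + 2L, {
    carriers <- vector("list", d$n_kos)
    names(carriers) <- ko_ids
    mod_of_ko <- setNames(map_df$module_id, map_df$ko_id)
    for (ko in ko_ids) {
      mod <- mod_of_ko[ko]
      pool <- if (!is.na(mod) && mod %in% plan$planted_mod) {
        # planted modules: KOs concentrated in planted species of the
        # matching direction
        if (plan$mod_dir[match(mod, plan$planted_mod)] > 0) up_sp else dn_sp
      } else if (!is.na(mod)) {
        # mapped but unplanted modules: carriers independent of the
        # planted taxa so module-level signal is attributable to the plan
        neutral_sp
      } else {
        species_ids
      }
      carriers[[ko]] <- sample(pool, min(d$carriers_per_ko, length(pool)))
    }
    Z <- matrix(0, d$n_species, d$n_kos, dimnames = list(species_ids, ko_ids))
    for (ko in ko_ids) Z[carriers[[ko]], ko] <- 1
    K <- t(Z) %*% species_abs
    K <- K * exp(matrix(rnorm(d$n_kos * n, 0, d$ko_noise_sd), d$n_kos, n))
    dimnames(K) <- list(ko_ids, samples)
    K
  })
  ko_tab <- abundance_table(ko_tab, "ko")

  ## --- metabolite table (sub-seed +3) ----------------------------------
  met_cluster <- rep(seq_len(d$n_latent_clusters),
                     length.out = d$n_metabolites)
  met_cluster <- sort(met_cluster)
  met_tab <- with_seed(d$seed + 3L, {
    fac <- matrix(rnorm(d$n_latent_clusters * n), d$n_latent_clusters, n)
    fac <- fac + outer(d$cluster_shifts, gidx)
    X <- d$loading * fac[met_cluster, , drop = FALSE] +
      matrix(rnorm(d$n_metabolites * n, 0, d$metab_noise_sd),
             d$n_metabolites, n)
    M <- exp(X)  # positive intensities, log-normal about the factor model
    dimnames(M) <- list(met_ids, samples)
    M
  })
  met_tab <- abundance_table(met_tab, "metabolite")

  ## --- metadata (sub-seed +4) ------------------------------------------
  meta <- with_seed(d$seed + 4L, {
    e <- d$phenotype_effect
    ph <- data.frame(
      Gensini = 20 + 30 * e * gidx + rnorm(n, 0, 15),
      Syntax  = 5 + 6 * e * gidx + rnorm(n, 0, 4),
      cTnI    = pmax(0, 0.05 + 0.15 * e * gidx + rnorm(n, 0, 0.1)),
      TIMI    = 5 + 2.5 * e * gidx + rnorm(n, 0, 2))
    cohort_metadata(samples, grp, ph, levels = names(d$group_sizes))
  })

  truth <- list(
    differential_species = if (length(plan$diff_sp)) data.frame(
      species_id = plan$diff_sp,
      direction = plan$sp_dir,
      effect = ifelse(plan$sp_dir > 0, d$species_effect,
                      1 / d$species_effect),
      stringsAsFactors = FALSE) else
        data.frame(species_id = character(), direction = integer(),
                   effect = numeric()),
    enriched_modules = if (length(plan$planted_mod)) data.frame(
      module_id = plan$planted_mod, direction = plan$mod_dir,
      stringsAsFactors = FALSE) else
        data.frame(module_id = character(), direction = integer()),
    metabotype_assignments = setNames(met_cluster, met_ids),
    shifted_clusters = data.frame(cluster = seq_len(d$n_latent_clusters),
                                  shift = d$cluster_shifts),
    phenotype_links = data.frame(
      feature = rep(paste0("cluster", seq_len(d$n_latent_clusters)),
                    times = 4L),
      phenotype = rep(c("Gensini", "Syntax", "cTnI", "TIMI"),
                      each = d$n_latent_clusters),
      sign = rep(sign(d$cluster_shifts), 4L) *
        sign(d$phenotype_effect)))

  list(species = species_tab, ko = ko_tab, metabolite = met_tab,
       meta = meta, map = module_map(map_df$ko_id, map_df$module_id),
       truth = truth, design = d)
}

#' Generate a matched null cohort
#'
#' Same generative process as [generate_cohort()] with every planted effect
#' zeroed; the truth record lists no differential features.
#'
#' @inheritParams generate_cohort
#' @return As [generate_cohort()].
#' @export
generate_null_cohort <- function(design = cohort_design()) {
  d <- design
  d$n_diff_species <- 0L
  d$n_enriched_modules <- 0L
  d$cluster_shifts <- rep(0, d$n_latent_clusters)
  d$phenotype_effect <- 0
  generate_cohort(d)
}

#' Write a generated cohort to a directory of TSV files
#'
#' Materializes the same dialects the readers consume: `species.tsv`,
#' `ko.tsv`, `metabolite.tsv`, `metadata.tsv`, `module_map.tsv`.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_abundance_table(cohort$species, file.path(dir, "species.tsv"))
  write_abundance_table(cohort$ko, file.path(dir, "ko.tsv"))
  write_abundance_table(cohort$metabolite, file.path(dir, "metabolite.tsv"))
  write_metadata(cohort$meta, file.path(dir, "metadata.tsv"))
  write_module_map(cohort$map, file.path(dir, "module_map.tsv"))
  invisible(dir)
}
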