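#' Profile estimation against a selected reference set
#'
#' Paints target individuals against the reference members as donors,
#' aggregates to the reference set's basis populations, and estimates
#' simplex profiles against the group mean copyvectors. Reference members
#' are estimated leave-one-out (their group mean recomputed without them);
#' other individuals are estimated against the full groups.
#'
#' @param panel a `haplotype_panel` containing targets and references.
#' @param refset a `reference_set` from [select_reference_groups()].
#' @param ids target individual ids (default: all panel members).
#' @param method passed to [estimate_profile()].
#' @param switch_rate,mutation_prob copying-model parameters (use the same
#'   values the reference set was built with).
#' @return matrix of profiles, rows = targets, columns = reference groups.
#' @export
estimate_panel_profiles <- function(panel, refset, ids = NULL,
                                    method = "simplex-ls",
                                    switch_rate = 3720.27,
                                    mutation_prob = 0.00014) {
  if (is.null(ids)) ids <- panel$individual_ids
  members <- unlist(refset$groups, use.names = FALSE)
  basis <- refset$basis[members]
  X_ref <- copyvector_matrix(panel, members, members, basis,
                             switch_rate = switch_rate,
                             mutation_prob = mutation_prob)
  model <- group_copyvectors(X_ref, refset$groups)
  ref_targets <- intersect(ids, members)
  other_targets <- setdiff(ids, members)
  P <- matrix(0, length(ids), nrow(model$V),
              dimnames = list(ids, rownames(model$V)))
  if (length(ref_targets)) {
    loo <- leave_one_out_profiles(X_ref, refset$groups, method = method)
    P[ref_targets, ] <- loo[ref_targets, , drop = FALSE]
  }
  if (length(other_targets)) {
    X_t <- copyvector_matrix(panel, other_targets, members, basis,
                             switch_rate = switch_rate,
                             mutation_prob = mutation_prob)
    for (id in other_targets) {
      P[id, ] <- estimate_profile(X_t[id, ], model, method = method)
    }
  }
  P
}

#' Build an ancestry estimator for simulated individuals
#'
#' Returns a closure that paints a [simulate_descendant()] result against
#' the reference members and estimates its profile against the reference
#' set's group mean copyvectors; used as the `estimator` of
#' [run_scenario()].
#'
#' @inheritParams estimate_panel_profiles
#' @return function taking a `simulate_descendant()` result and returning
#'   a named simplex profile.
#' @export
make_scenario_estimator <- function(panel, refset, method = "simplex-ls",
                                    switch_rate = 3720.27,
                                    mutation_prob = 0.00014) {
  members <- unlist(refset$groups, use.names = FALSE)
  basis <- refset$basis[members]
  X_ref <- copyvector_matrix(panel, members, members, basis,
                             switch_rate = switch_rate,
                             mutation_prob = mutation_prob)
  model <- group_copyvectors(X_ref, refset$groups)
  function(sim) {
    cv <- paint_recipient(sim$chromosomes, panel, donor_ids = members,
                          switch_rate = switch_rate,
                          mutation_prob = mutation_prob, donor_units = basis)
    estimate_profile(cv$chunk_counts, model, method = method)
  }
}

#' Configuration for an end-to-end synthetic run
#'
#' Collects every tunable parameter of the pipeline; each stage reads its
#' parameters only from the config, and one global seed fans out to
#' deterministic per-stage seeds so any stage is reproducible in isolation.
#'
#' @param seed global integer seed.
#' @param n_populations,n_per_pop,n_variants,fst_to_root,founder_pool_size
#'   synthetic-panel shape.
#' @param maf_min,hwe_alpha,miss_max variant QC thresholds.
#' @param het_f_bounds,sample_miss_max sample QC thresholds; the F bounds
#'   default wider than the dense-chip convention of [sample_qc()] because
#'   the sampling noise of the inbreeding coefficient scales inversely with
#'   the square root of the variant count.
#' @param local_radius,local_max,global_radius,global_max spatial caps.
#' @param max_parent_sep_km candidate eligibility threshold.
#' @param switch_rate,mutation_prob copying-model parameters; the switch
#'   rate defaults to a value matched to the synthetic marker density
#'   rather than the dense-chip default of [paint_recipient()].
#' @param K_start,basis_level,pop_identity_min,member_min reference
#'   selection parameters.
#' @param shrink_threshold small-proportion shrink rule threshold.
#' @param loess_span,split_year temporal-analysis parameters.
#' @param scenario_G,scenario_replicates pedigree-scenario shape.
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_populations = 2L, n_per_pop = 24L,
                       n_variants = 400L, fst_to_root = 0.05,
                       founder_pool_size = 30L,
                       maf_min = 0.05, hwe_alpha = 1e-6, miss_max = 0.01,
                       het_f_bounds = c(-0.25, 0.25), sample_miss_max = 0.005,
                       local_radius = 5, local_max = 15,
                       global_radius = 30, global_max = 40,
                       max_parent_sep_km = 80,
                       switch_rate = 50, mutation_prob = 1e-4,
                       K_start = 2L, basis_level = 20L,
                       pop_identity_min = 0.5, member_min = 0.7,
                       shrink_threshold = 0.05,
                       loess_span = 0.5, split_year = 1950,
                       scenario_G = 1:3, scenario_replicates = 5L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

stage_seed <- function(cfg, k) (cfg$seed * 101L + k) %% .Machine$integer.max

#' Run the full synthetic workflow
#'
#' Executes simulate -> QC -> spatial thinning -> painting/coancestry ->
#' tree -> reference selection -> profile estimation (leave-one-out for
#' reference members) -> pedigree scenarios -> birth-year curves, entropy
#' trends, inbreeding and F_ST -> municipal profiles, writing each stage's
#' artifact as plain text under `out_dir` together with a JSON manifest of
#' the configuration and per-file checksums.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  save_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <<- c(artifacts, p)
    p
  }

  # 1. synthetic panel
  centers <- cbind(seq(0, by = 120, length.out = config$n_populations), 0)
  specs <- lapply(seq_len(config$n_populations), function(k) {
    population_spec(paste0("pop", LETTERS[k]), centers[k, ],
                    dispersion_km = 15, n_individuals = config$n_per_pop,
                    founder_pool_size = config$founder_pool_size,
                    fst_to_root = config$fst_to_root)
  })
  gm <- uniform_genetic_map(stats::setNames(rep(50e6, 4), paste0("chr", 1:4)))
  sim <- simulate_panel(specs, config$n_variants, gm, seed = stage_seed(config, 1L))
  save_tsv(sim$metadata, "metadata.tsv")

  # 2. QC
  vq <- variant_qc(sim$panel, config$maf_min, config$hwe_alpha, config$miss_max)
  sq <- sample_qc(vq$panel, het_f_bounds = config$het_f_bounds,
                  miss_max = config$sample_miss_max)
  panel <- sq$panel
  meta <- sim$metadata[sim$metadata$id %in% panel$individual_ids, ]
  qc_path <- file.path(out_dir, "qc_report.json")
  jsonlite::write_json(list(variant = unclass(vq$report), sample = unclass(sq$report)),
                       qc_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artifacts <- c(artifacts, qc_path)

  # 3. spatial thinning of reference candidates
  loc <- candidate_locations(meta, config$max_parent_sep_km)
  elig <- loc[loc$eligible, ]
  thin <- spatial_thin(elig[, c("x", "y")],
                       config$local_radius, config$local_max,
                       config$global_radius, config$global_max,
                       seed = stage_seed(config, 3L))
  candidates <- elig$id[thin$kept]
  save_tsv(data.frame(id = candidates), "reference_candidates.tsv")

  # 4. coancestry and population tree
  co <- coancestry(panel, candidates,
                   switch_rate = config$switch_rate,
                   mutation_prob = config$mutation_prob)
  save_tsv(data.frame(id = rownames(co), co, check.names = FALSE),
           "coancestry.tsv")
  tree <- build_population_tree(co)
  tree_path <- file.path(out_dir, "population_tree.nwk")
  write_tree_newick(tree, tree_path)
  artifacts <- c(artifacts, tree_path)

  # 5. reference selection
  coords <- as.matrix(elig[match(candidates, elig$id), c("x", "y")])
  rownames(coords) <- candidates
  refset <- select_reference_groups(
    tree, panel, K_start = config$K_start,
    pop_identity_min = config$pop_identity_min,
    member_min = config$member_min, basis_level = config$basis_level,
    coords = coords, switch_rate = config$switch_rate,
    mutation_prob = config$mutation_prob)
  audit_path <- file.path(out_dir, "refset_audit.json")
  jsonlite::write_json(refset$audit, audit_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  artifacts <- c(artifacts, audit_path)

  # 6. ancestry profiles for everyone (LOO for reference members)
  profiles <- estimate_panel_profiles(panel, refset,
                                      switch_rate = config$switch_rate,
                                      mutation_prob = config$mutation_prob)
  shrunk <- t(apply(profiles, 1, shrink_profile, threshold = config$shrink_threshold))
  prof_df <- data.frame(
    id = rep(rownames(profiles), times = ncol(profiles)),
    group = rep(colnames(profiles), each = nrow(profiles)),
    proportion = as.vector(profiles),
    proportion_shrunk = as.vector(shrunk),
    stringsAsFactors = FALSE
  )
  save_tsv(prof_df, "ancestry_profiles.tsv")

  # 7. pedigree scenarios: ancestors from non-candidate individuals
  set.seed(stage_seed(config, 7L))
  truth_origin <- sim$truth$origin
  free_ids <- setdiff(panel$individual_ids, unlist(refset$groups))
  pools <- split(free_ids, unname(truth_origin[free_ids]))
  estimator <- make_scenario_estimator(panel, refset,
                                       switch_rate = config$switch_rate,
                                       mutation_prob = config$mutation_prob)
  scen <- NULL
  if (length(pools) >= 2L &&
      min(lengths(pools)) >= 2^max(config$scenario_G)) {
    all_res <- run_scenario(pools[[1]], NULL, panel, estimator,
                            n_replicates = config$scenario_replicates,
                            G_range = config$scenario_G)
    all_res$scenario <- paste0("All-", names(pools)[1])
    almost_res <- run_scenario(pools[[1]], pools[[2]], panel, estimator,
                               n_replicates = config$scenario_replicates,
                               G_range = config$scenario_G)
    almost_res$scenario <- paste0("Almost-", names(pools)[1])
    scen <- rbind(all_res, almost_res)
    save_tsv(scen, "scenario_results.tsv")
  }

  # 8. temporal analyses per region
  by_region <- split(meta$id, meta$region)
  curves <- list(); trends <- list()
  for (r in names(by_region)) {
    ids_r <- intersect(by_region[[r]], rownames(profiles))
    if (length(ids_r) < 10L) next
    yrs <- meta$birth_year[match(ids_r, meta$id)]
    cr <- loess_curves(profiles[ids_r, , drop = FALSE], yrs, span = config$loess_span)
    cr$region <- r
    curves[[r]] <- cr
    ye <- yearly_entropy(profiles[ids_r, , drop = FALSE], yrs)
    for (per in c("full", "pre", "post")) {
      tr <- tryCatch(heterogeneity_slope(ye$entropy, ye$n, per, config$split_year),
                     error = function(e) NULL)
      if (!is.null(tr)) {
        trends[[paste(r, per)]] <- data.frame(
          region = r, period = per, slope = tr$slope, se = tr$se,
          n_years = tr$n_years, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(curves)) save_tsv(do.call(rbind, curves), "ancestry_curves.tsv")
  if (length(trends)) save_tsv(do.call(rbind, trends), "entropy_trends.tsv")

  region_assign <- stats::setNames(meta$region, meta$id)
  save_tsv(mean_inbreeding(panel, region_assign), "mean_inbreeding.tsv")
  fst <- pairwise_fst(panel, region_assign)
  save_tsv(data.frame(group = rownames(fst$fst), fst$fst, check.names = FALSE),
           "pairwise_fst.tsv")

  # 9. municipal profiles at the population centres
  muni <- data.frame(municipality_id = seq_len(config$n_populations),
                     x = centers[, 1], y = centers[, 2])
  xy <- as.matrix(meta[match(rownames(profiles), meta$id), c("x", "y")])
  keep <- stats::complete.cases(xy)
  mp <- municipal_average(profiles[keep, , drop = FALSE], xy[keep, , drop = FALSE], muni)
  save_tsv(mp, "municipal_profiles.tsv")

  # manifest
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    config_checksum = unname(tools::md5sum(cfg_path)),
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(p) unname(tools::md5sum(p)))
  )
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(panel = panel, metadata = meta, refset = refset,
                 profiles = profiles, scenario = scen,
                 fst = fst, manifest = man_path))
}
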