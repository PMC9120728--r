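#' Default pipeline configuration
#'
#' Parameters of the end-to-end analysis. `fwhm` is the analysis
#' smoothing applied to the input maps; `data_fwhm` is the smoothness
#' the maps already carry (the generator's noise FWHM for synthetic
#' bundles; 0 when unknown). Monte Carlo null fields are smoothed with
#' the quadrature combination `sqrt(fwhm^2 + data_fwhm^2)` so their
#' spatial autocorrelation matches the analysed maps. Iteration and
#' permutation counts default to a desk scale; the reference analysis
#' scale is 10,000 for both.
#'
#' @param fwhm analysis smoothing FWHM (mesh units).
#' @param data_fwhm smoothness already present in the input maps.
#' @param vertex_p_threshold vertex-wise cluster-forming threshold.
#' @param cluster_alpha cluster-wise significance level.
#' @param n_cluster_iter Monte Carlo iterations for the cluster null.
#' @param n_perm spin permutations.
#' @param epicenter_alpha epicenter significance level.
#' @param weight_mode weighted-degree mode.
#' @param run_posthoc run the post hoc covariate variants and the
#'   functional-weakness subgroup rerun.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fwhm = 0, data_fwhm = 0.35,
                            vertex_p_threshold = 0.001,
                            cluster_alpha = 0.05,
                            n_cluster_iter = 1000, n_perm = 1000,
                            epicenter_alpha = 0.01,
                            weight_mode = "positive_only",
                            run_posthoc = TRUE, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

null_fwhm <- function(cfg) sqrt(cfg$fwhm^2 + cfg$data_fwhm^2)

#' Run the full morphometry + network-mapping pipeline
#'
#' Executes the analysis sequence on an input bundle: surface
#' smoothing, two-class (case vs control) and one-class (severity)
#' vertex-wise GLMs adjusted for age, sex and eTIV, cluster extraction
#' at the vertex threshold with Monte Carlo cluster-wise correction,
#' post hoc covariate variants (BDI + trait anxiety, antidepressant
#' use, subtype) and the functional-weakness subgroup rerun, parcel
#' aggregation of the severity partial-correlation map, weighted-degree
#' centrality similarity with spin inference, and disease-epicenter
#' mapping. All result tables and a JSON run manifest are written to
#' `output_dir` when one is given.
#'
#' @param inputs list with `mesh`, `atlas`, `cohort`, `volumes`,
#'   `connectome` (objects, or file paths readable by the `read_*`
#'   functions).
#' @param config a [pipeline_config()].
#' @param output_dir directory for result tables (created if missing);
#'   NULL skips writing.
#' @param timestamp include a timestamp in the manifest.
#' @return list with the stat maps, cluster tables, region-level
#'   atrophy map, centrality similarity, epicenter table and manifest.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(),
                         output_dir = NULL, timestamp = TRUE) {
  mesh <- if (is.character(inputs$mesh)) read_mesh(inputs$mesh) else
    inputs$mesh
  atlas <- if (is.character(inputs$atlas)) {
    read_atlas(inputs$atlas, mesh = mesh)
  } else inputs$atlas
  cohort <- if (is.character(inputs$cohort)) {
    read_cohort(inputs$cohort)
  } else inputs$cohort
  volumes <- if (is.character(inputs$volumes)) {
    read_vertex_matrix(inputs$volumes, cohort)
  } else inputs$volumes
  conn <- if (is.character(inputs$connectome)) {
    read_connectome(inputs$connectome, atlas)
  } else inputs$connectome
  if (is.null(atlas$mesh)) atlas$mesh <- mesh
  if (ncol(volumes) != n_vertices(mesh)) {
    stop("volumes column count does not match the mesh vertex count")
  }

  cfg <- config
  op <- smoothing_operator(mesh, cfg$fwhm)
  sm <- smooth_surface(volumes, mesh, op = op)

  # shared Monte Carlo cluster null, matched to the data smoothness
  null <- simulate_null_clusters(mesh, null_fwhm(cfg),
                                 cfg$vertex_p_threshold,
                                 cfg$n_cluster_iter,
                                 seed = derive_seed(cfg$seed, 31))

  analyze <- function(design) {
    stats <- fit_vertex_glm(sm, cohort, design)
    cl <- extract_clusters(stats, mesh, cfg$vertex_p_threshold)
    if (nrow(cl)) {
      cl$p_cluster <- cluster_pvalue(cl, null,
                                     fwhm = null$fwhm,
                                     vertex_p_threshold =
                                       cfg$vertex_p_threshold)
      cl$peak_r <- stats$r_partial[cl$peak_vertex]
      # cluster-average partial r alongside the peak summary
      mem <- attr(cl, "members")
      cl$mean_r <- vapply(mem, function(v) mean(stats$r_partial[v]),
                          numeric(1))
    }
    list(stats = stats, clusters = cl)
  }

  group <- analyze(design_spec("group_contrast"))
  sev_rows <- severity_subset(cohort)
  sev <- analyze(design_spec("severity", subset = sev_rows))

  variants <- list()
  if (isTRUE(cfg$run_posthoc)) {
    vspec <- list(
      bdi_stai = c("bdi", "stai_trait"),
      antidepressant = "antidepressant",
      subtype = "subtype_weakness"
    )
    for (nm in names(vspec)) {
      variants[[nm]] <- analyze(
        design_spec("severity", extra_nuisance = vspec[[nm]],
                    subset = sev_rows))
    }
    weak_rows <- sev_rows & cohort$subtype_weakness == 1
    if (sum(weak_rows) > 8) {
      variants[["weakness_subgroup"]] <-
        analyze(design_spec("severity", subset = weak_rows))
    }
  }

  atrophy <- parcel_means(sev$stats$r_partial, atlas, mesh = mesh)
  sim <- centrality_similarity(atrophy, conn, atlas,
                               n_perm = cfg$n_perm,
                               seed = derive_seed(cfg$seed, 32),
                               mode = cfg$weight_mode)
  epi <- epicenter_map(conn, atrophy, atlas, n_perm = cfg$n_perm,
                       alpha = cfg$epicenter_alpha,
                       seed = derive_seed(cfg$seed, 33))

  manifest <- list(
    tool = paste("atrophynet",
                 as.character(utils::packageVersion("atrophynet"))),
    parameters = cfg[setdiff(names(cfg), "run_posthoc")],
    null_fwhm = null_fwhm(cfg),
    stage_seeds = list(cluster_null = derive_seed(cfg$seed, 31),
                       centrality_spin = derive_seed(cfg$seed, 32),
                       epicenter_spin = derive_seed(cfg$seed, 33)),
    n_subjects = nrow(cohort),
    n_severity_used = sum(sev_rows),
    variants = names(variants)
  )
  if (timestamp) manifest$timestamp <- format(Sys.time(), tz = "UTC")

  result <- list(group = group, severity = sev, variants = variants,
                 atrophy = atrophy, centrality_similarity = sim,
                 epicenters = epi, null = null, manifest = manifest)
  if (!is.null(output_dir)) {
    write_pipeline_outputs(result, output_dir)
  }
  result
}

write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wtab <- function(df, name) {
    utils::write.csv(as.data.frame(df),
                     file.path(output_dir, name), row.names = FALSE)
  }
  wtab(result$group$stats, "statmap_group.csv")
  wtab(result$severity$stats, "statmap_severity.csv")
  wtab(result$group$clusters, "clusters_group.csv")
  wtab(result$severity$clusters, "clusters_severity.csv")
  for (nm in names(result$variants)) {
    wtab(result$variants[[nm]]$clusters,
         sprintf("clusters_severity_%s.csv", nm))
  }
  wtab(data.frame(region = seq_along(result$atrophy),
                  atrophy = result$atrophy), "region_atrophy.csv")
  sim <- result$centrality_similarity
  wtab(data.frame(region = seq_along(attr(sim, "centrality")),
                  weighted_degree = attr(sim, "centrality")),
       "centrality.csv")
  jsonlite::write_json(
    list(observed_r = sim$observed, p_spin = sim$p,
         n_perm = sim$n_perm, mode = attr(sim, "mode")),
    file.path(output_dir, "centrality_similarity.json"),
    auto_unbox = TRUE, digits = NA)
  wtab(result$epicenters, "epicenters.csv")
  jsonlite::write_json(result$manifest,
                       file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}

#' Simulate and write a complete input bundle
#'
#' Generates mesh, atlas, cohort, vertex matrix, connectome and (when
#' an epicenter is planted) the ground-truth atrophy map, writing all
#' of them as plain-text files plus a ground-truth JSON.
#'
#' @param config a [simulation_config()].
#' @param output_dir directory to write into.
#' @return (invisibly) list of generated objects and file paths.
#' @export
simulate_bundle <- function(config, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  mesh <- make_cortex(config$mesh_level, radius = config$radius)
  atlas <- make_atlas(mesh, config$n_regions_per_hemisphere,
                      seed = derive_seed(config$seed, 1))
  conn <- simulate_connectome(config, atlas)
  # couple the severity effect to the planted epicenter's profile so
  # the network-mapping stage has a recoverable ground truth
  epi_region <- config$epicenter_region
  if (identical(epi_region, "hub")) {
    epi_region <- which.max(weighted_degree(conn))
  }
  weights <- if (!is.null(epi_region)) {
    epicenter_effect_weights(conn, epi_region, atlas,
                             centrality_mix = config$centrality_mix %||% 0)
  }
  sim <- simulate_cohort(config, mesh, atlas, effect_weights = weights)
  paths <- list(
    mesh = file.path(output_dir, "mesh.off"),
    atlas = file.path(output_dir, "atlas.csv"),
    cohort = file.path(output_dir, "cohort.csv"),
    volumes = file.path(output_dir, "volumes.csv"),
    connectome = file.path(output_dir, "connectome.csv")
  )
  write_mesh(mesh, paths$mesh)
  write_atlas(atlas, paths$atlas)
  write_cohort(sim$cohort, paths$cohort)
  write_vertex_matrix(sim$volumes, sim$cohort$subject_id,
                      paths$volumes)
  write_connectome(conn, paths$connectome)
  truth <- list(effect_vertices = sim$effect_vertices,
                effect_center = sim$effect_center,
                beta_severity = sim$beta_severity,
                rho = config$rho,
                epicenter_region = epi_region,
                centrality_mix = config$centrality_mix %||% 0,
                lambda = config$lambda, seed = config$seed)
  jsonlite::write_json(truth, file.path(output_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(mesh = mesh, atlas = atlas, cohort = sim$cohort,
                 volumes = sim$volumes, connectome = conn,
                 truth = truth, paths = paths))
}
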