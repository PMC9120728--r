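#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator with defaults
#' emulating the study conditions the pipeline is designed for: a
#' 53-case / 50-control cohort (3 cases lacking a severity rating), an
#' S-FMDRS-like severity score truncated to \[0, 54\], age/sex/eTIV
#' nuisance structure, a planted negative severity-volume effect inside
#' a contiguous geodesic disc, spatially smooth noise fields, and a
#' 68-region bilateral connectome with distance-decay and modular
#' structure plus an optional planted epicenter.
#'
#' The planted `rho` is the *partial* correlation between severity and
#' volume after the nuisance covariates: severity is drawn
#' independently of the covariates, so scaling the severity coefficient
#' as `beta = rho / sqrt(1 - rho^2) * noise_sd / sd(severity)` makes
#' rho the single interpretable effect-size knob.
#'
#' @param mesh_level icosphere subdivision level per hemisphere.
#' @param radius sphere radius in mm (100 approximates fsaverage).
#' @param n_regions_per_hemisphere atlas granularity.
#' @param n_cases,n_controls cohort sizes.
#' @param n_severity_missing cases without a severity rating.
#' @param severity_mean,severity_sd truncated-normal severity
#'   parameters on \[0, 54\].
#' @param age_mean_case,age_sd_case,age_mean_control,age_sd_control
#'   age distributions (years).
#' @param female_prop_case,female_prop_control sex mix (sex coded 1 =
#'   female).
#' @param etiv_mean,etiv_sd eTIV distribution (mm^3).
#' @param antidep_prop_case,antidep_prop_control antidepressant use.
#' @param weakness_prop proportion of cases with functional weakness.
#' @param baseline mean vertex volume (mm^3).
#' @param beta_age,beta_sex,beta_etiv nuisance effects on volume.
#' @param rho planted partial correlation (severity vs volume) inside
#'   the effect disc; 0 plants nothing.
#' @param effect_center seed vertex of the effect disc (NULL picks the
#'   first right-hemisphere vertex).
#' @param effect_radius geodesic disc radius, radians.
#' @param group_effect mean case-control volume difference inside the
#'   disc (0: no group difference, as in the motivating study).
#' @param noise_sd marginal SD of the smooth vertex noise (mm^3).
#' @param noise_fwhm spatial smoothness of the noise, mesh units.
#' @param n_modules connectome community count.
#' @param within_weight,between_weight mean edge weights within /
#'   between modules before distance decay.
#' @param decay distance-decay rate (per radian).
#' @param conn_noise_sd SD of edge-weight noise.
#' @param epicenter_region planted epicenter: a region index, "hub"
#'   (the highest weighted-degree region of the simulated connectome),
#'   or NULL for none.
#' @param lambda epicenter mixing coefficient in \[0, 1\].
#' @param centrality_mix weight of the (negated, standardised)
#'   weighted-degree map blended into the planted effect profile when
#'   building a coupled bundle; makes severity-related atrophy fall
#'   preferentially on hubs, the study condition behind the
#'   centrality-similarity analysis.
#' @param seed master seed; all stage seeds derive from it.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(
    mesh_level = 3, radius = 1,
    n_regions_per_hemisphere = 34,
    n_cases = 53, n_controls = 50, n_severity_missing = 3,
    severity_mean = 15, severity_sd = 9,
    age_mean_case = 43.7, age_sd_case = 10.1,
    age_mean_control = 44.5, age_sd_control = 10.0,
    female_prop_case = 42 / 53, female_prop_control = 36 / 50,
    etiv_mean = 1.5e6, etiv_sd = 1.5e5,
    antidep_prop_case = 24 / 53, antidep_prop_control = 16 / 50,
    weakness_prop = 34 / 53,
    baseline = 2.5, beta_age = -0.005, beta_sex = 0.10,
    beta_etiv = 2e-7,
    rho = -0.43, effect_center = NULL, effect_radius = 0.35,
    group_effect = 0,
    noise_sd = 0.30, noise_fwhm = 0.35,
    n_modules = 4, within_weight = 0.45, between_weight = 0.12,
    decay = 0.6, conn_noise_sd = 0.08,
    epicenter_region = 40, lambda = 0.7, centrality_mix = 0.4,
    seed = 1) {
  cfg <- as.list(environment())
  if (abs(cfg$rho) >= 1) stop("rho must lie in (-1, 1)")
  if (cfg$lambda < 0 || cfg$lambda > 1) stop("lambda must lie in [0, 1]")
  if (cfg$centrality_mix < 0 || cfg$centrality_mix > 1) {
    stop("centrality_mix must lie in [0, 1]")
  }
  if (cfg$n_cases < 1 || cfg$n_controls < 1) stop("counts must be positive")
  class(cfg) <- "simulation_config"
  cfg
}

# SD of a normal(mean, sd) truncated to [lo, hi]
truncnorm_sd <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m1 <- (da - db) / Z
  sd * sqrt(1 + (a * da - b * db) / Z - m1^2)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd),
                    stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a cohort and its vertex-wise volume maps
#'
#' Vertex volume is `baseline + beta_age*age + beta_sex*sex +
#' beta_etiv*etiv + effect + noise`: the effect term adds
#' `beta_sev * (severity - mean)` at disc vertices for rated cases
#' (scaled so the true partial correlation equals `rho`) plus
#' `group_effect` for all cases; the noise is an independent smooth
#' Gaussian field per subject, restandardised to marginal SD
#' `noise_sd`.
#'
#' When `effect_weights` is supplied (per-vertex weights in \[-1, 1\],
#' e.g. from [epicenter_effect_weights()]), the severity effect is
#' `beta_sev * weight_v * (severity - mean)` instead of the uniform
#' disc, scaling the planted partial correlation per vertex by its
#' weight (the maximum-weight vertex carries exactly `rho`).
#'
#' @param config a [simulation_config()].
#' @param mesh analysis [sphere_mesh()] (both hemispheres expected).
#' @param atlas optional [parcel_atlas()] (unused by the generator but
#'   accepted for interface symmetry).
#' @param effect_weights optional per-vertex effect weights replacing
#'   the geodesic disc.
#' @return list with `cohort` (a [cohort_table()]), `volumes`
#'   (subjects x vertices matrix), `effect_vertices` (planted disc, or
#'   the vertices with |weight| > 0.5) and `beta_severity`.
#' @export
simulate_cohort <- function(config, mesh, atlas = NULL,
                            effect_weights = NULL) {
  cfg <- config
  nv <- n_vertices(mesh)
  n <- cfg$n_cases + cfg$n_controls
  grp <- c(rep("case", cfg$n_cases), rep("control", cfg$n_controls))

  covars <- with_seed(derive_seed(cfg$seed, 11), {
    age <- c(stats::rnorm(cfg$n_cases, cfg$age_mean_case, cfg$age_sd_case),
             stats::rnorm(cfg$n_controls, cfg$age_mean_control,
                          cfg$age_sd_control))
    sex <- c(stats::rbinom(cfg$n_cases, 1, cfg$female_prop_case),
             stats::rbinom(cfg$n_controls, 1, cfg$female_prop_control))
    etiv <- stats::rnorm(n, cfg$etiv_mean, cfg$etiv_sd)
    sev <- rep(NA_real_, n)
    sev[seq_len(cfg$n_cases)] <- rtruncnorm(cfg$n_cases,
                                            cfg$severity_mean,
                                            cfg$severity_sd, 0, 54)
    if (cfg$n_severity_missing > 0) {
      drop <- sample.int(cfg$n_cases, cfg$n_severity_missing)
      sev[drop] <- NA
    }
    bdi <- pmax(0, stats::rnorm(n, 12, 8))
    stai <- pmax(20, stats::rnorm(n, 42, 10))
    antid <- c(stats::rbinom(cfg$n_cases, 1, cfg$antidep_prop_case),
               stats::rbinom(cfg$n_controls, 1,
                             cfg$antidep_prop_control))
    weak <- c(stats::rbinom(cfg$n_cases, 1, cfg$weakness_prop),
              rep(0L, cfg$n_controls))
    list(age = age, sex = sex, etiv = etiv, sev = sev, bdi = bdi,
         stai = stai, antid = antid, weak = weak)
  })

  cohort <- cohort_table(data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = grp,
    severity = covars$sev,
    age = covars$age,
    sex = covars$sex,
    etiv = covars$etiv,
    bdi = covars$bdi,
    stai_trait = covars$stai,
    antidepressant = covars$antid,
    subtype_weakness = covars$weak,
    stringsAsFactors = FALSE
  ))

  # planted effect support: geodesic disc, or supplied vertex weights
  if (is.null(effect_weights)) {
    center <- cfg$effect_center
    if (is.null(center)) center <- which(mesh$hemisphere == "right")[1]
    dc <- geodesic_distance(
      matrix(mesh$vertices[center, ], nv, 3, byrow = TRUE),
      mesh$vertices)
    same_hemi <- mesh$hemisphere == mesh$hemisphere[center]
    disc <- which(dc <= cfg$effect_radius & same_hemi)
    if (cfg$rho != 0 && !length(disc)) {
      stop("configuration error: effect disc is empty (radius too small)")
    }
    weights <- numeric(nv)
    weights[disc] <- 1
  } else {
    if (length(effect_weights) != nv) {
      stop("effect_weights length must equal the mesh vertex count")
    }
    weights <- effect_weights
    center <- which.max(abs(weights))
    disc <- which(abs(weights) > 0.5)
  }

  # effect scaling: rho is the partial correlation after covariates
  sev_sd <- truncnorm_sd(cfg$severity_mean, cfg$severity_sd, 0, 54)
  beta_sev <- if (cfg$rho == 0) 0 else {
    cfg$rho / sqrt(1 - cfg$rho^2) * cfg$noise_sd / sev_sd
  }

  op <- smoothing_operator(mesh, cfg$noise_fwhm)
  noise <- with_seed(derive_seed(cfg$seed, 12), {
    Z <- matrix(stats::rnorm(n * nv), n, nv)
    if (op$iterations > 0L) {
      Z <- (Z %*% op$S) / rep(op$marginal_sd, each = n)
    }
    Z * cfg$noise_sd
  })

  vol <- matrix(cfg$baseline, n, nv) +
    outer(cfg$beta_age * cohort$age + cfg$beta_sex * cohort$sex +
            cfg$beta_etiv * cohort$etiv, rep(1, nv)) +
    noise
  sev_c <- cohort$severity - cfg$severity_mean
  rated <- which(!is.na(cohort$severity))
  if (beta_sev != 0 && any(weights != 0)) {
    vol[rated, ] <- vol[rated, ] +
      outer(beta_sev * sev_c[rated], weights)
  }
  if (cfg$group_effect != 0 && length(disc)) {
    cases <- which(cohort$group == "case")
    vol[cases, disc] <- vol[cases, disc] + cfg$group_effect
  }
  list(cohort = cohort, volumes = vol, effect_vertices = disc,
       effect_center = center, beta_severity = beta_sev)
}

#' Simulate a normative connectome
#'
#' Edge weight between regions i and j is `mu_ij * exp(-decay * d_ij) +
#' noise`, where `mu_ij` is the within- or between-module mean (modules
#' from k-means on the centroids), `d_ij` the centroid geodesic
#' distance, and the noise symmetric Gaussian; the matrix is
#' symmetrised, diagonal-zeroed and clipped to \[-1, 1\].
#'
#' @param config a [simulation_config()].
#' @param atlas a [parcel_atlas()].
#' @return a [connectome()].
#' @export
simulate_connectome <- function(config, atlas) {
  cfg <- config
  cen <- atlas_centroids(atlas)
  r <- atlas$regions$hemisphere == "right"
  cen[r, 1] <- -cen[r, 1]   # mirror-consistent coordinates: modules
  k <- nrow(cen)            # and decay are bilateral/homotopic
  D <- atlas_distances(atlas)
  W <- with_seed(derive_seed(cfg$seed, 21), {
    km <- stats::kmeans(cen, centers = min(cfg$n_modules, k),
                        nstart = 5)
    mod <- km$cluster
    mu <- ifelse(outer(mod, mod, "=="), cfg$within_weight,
                 cfg$between_weight)
    E <- matrix(stats::rnorm(k * k, 0, cfg$conn_noise_sd), k, k)
    E <- (E + t(E)) / sqrt(2)
    mu * exp(-cfg$decay * D) + E
  })
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W <- pmax(pmin(W, 1), -1)
  connectome(W, atlas)
}

#' Vertex-level effect weights following an epicenter's connectivity
#'
#' Converts a planted epicenter's connectivity profile into per-vertex
#' severity-effect weights: vertices in regions strongly connected to
#' the epicenter lose the most volume with increasing severity (weight
#' +1 at the most-connected region), so that the region-level map of
#' severity-volume correlations the analysis recovers mirrors
#' `standardize(-conn[region, ])` — the ground truth the
#' disease-epicenter stage is meant to find.
#'
#' @param conn a [connectome()].
#' @param region epicenter region index.
#' @param atlas a [parcel_atlas()] with vertex assignment.
#' @param centrality_mix optional blend (in \[0, 1\]) of the negated
#'   standardised weighted-degree map into the profile, so the planted
#'   atrophy also tracks hub regions.
#' @return numeric per-vertex weight vector, maximum magnitude 1.
#' @export
epicenter_effect_weights <- function(conn, region, atlas,
                                     centrality_mix = 0) {
  if (is.null(atlas$vertex_assignment)) {
    stop("atlas has no vertex assignment")
  }
  std <- function(x) (x - mean(x)) / stats::sd(x)
  g <- (1 - centrality_mix) * std(-unclass(conn)[region, ]) +
    centrality_mix * std(-as.numeric(weighted_degree(conn)))
  g <- -g   # back to volume-effect sign: positive where atrophied
  g <- g / max(abs(g))
  g[atlas$vertex_assignment]
}

#' Spatially autocorrelated region-level noise map
#'
#' Gaussian map over regions with covariance `exp(-d / length_scale)`
#' in centroid geodesic distance — the smooth random maps used for
#' spin-test calibration and as the noise component of planted
#' scenarios.
#'
#' @param atlas a [parcel_atlas()].
#' @param seed RNG seed.
#' @param length_scale correlation length, radians.
#' @return numeric map (one value per region), zero mean, unit SD.
#' @export
smooth_region_map <- function(atlas, seed = 1, length_scale = 0.5) {
  k <- n_regions(atlas)
  D <- atlas_distances(atlas)
  L <- chol(exp(-D / length_scale) + diag(1e-8, k))
  x <- with_seed(seed, as.numeric(crossprod(L, stats::rnorm(k))))
  (x - mean(x)) / stats::sd(x)
}

#' Map with a planted expected correlation against a target
#'
#' Mixes the standardised target with independent smooth noise so the
#' expected Pearson correlation with the target equals `rho`:
#' `rho * std(target) + sqrt(1 - rho^2) * std(noise)`.
#'
#' @param target region-level map to correlate against.
#' @param rho planted expected correlation in (-1, 1).
#' @param atlas a [parcel_atlas()].
#' @param seed RNG seed.
#' @return numeric map over regions.
#' @export
plant_correlated_map <- function(target, rho, atlas, seed = 1) {
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)")
  std <- function(x) (x - mean(x)) / stats::sd(x)
  noise <- smooth_region_map(atlas, seed)
  rho * std(target) + sqrt(1 - rho^2) * std(noise)
}

#' Plant a disease epicenter in a region-level atrophy map
#'
#' Constructs the ground-truth atrophy map an epicenter analysis should
#' recover: `lambda * standardize(-conn[region, ]) + (1 - lambda) *
#' standardize(smooth noise)`. The sign convention matches an atrophy
#' map expressed as (negative) severity-volume correlations: regions
#' strongly connected to the epicenter carry the most negative values.
#' The noise map is spatially autocorrelated (Gaussian with covariance
#' `exp(-d / 0.5)` over centroid geodesic distances).
#'
#' @param conn a [connectome()].
#' @param region planted epicenter (region index).
#' @param lambda mixing coefficient in \[0, 1\]; 1 is noise-free.
#' @param atlas a [parcel_atlas()] (noise-field geometry).
#' @param seed RNG seed.
#' @return numeric atrophy map with attribute `epicenter_region`.
#' @export
plant_epicenter <- function(conn, region, lambda, atlas, seed = 1) {
  k <- n_regions(atlas)
  if (region < 1 || region > k) stop("region index out of bounds")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  noise <- smooth_region_map(atlas, seed)
  signal <- -unclass(conn)[region, ]
  std <- function(x) (x - mean(x)) / stats::sd(x)
  map <- lambda * std(signal) + (1 - lambda) * std(noise)
  attr(map, "epicenter_region") <- region
  map
}
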