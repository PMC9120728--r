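#' Cortical parcellation atlas
#'
#' A `parcel_atlas` holds the region table (id, name, hemisphere,
#' spherical centroid) and, optionally, the region assignment of every
#' mesh vertex. Region order is the canonical order for all
#' region-level vectors and connectome rows: left-hemisphere regions
#' first, then right, matching a bilateral Desikan-Killiany-style
#' layout.
#'
#' @param regions data.frame with columns `region_id` (unique integer),
#'   `region_name`, `hemisphere` ("left"/"right"), `cx`, `cy`, `cz`
#'   (unit centroid components).
#' @param vertex_assignment optional integer vector: for each mesh
#'   vertex, the row index (1-based, in `regions` order) of its region.
#' @param mesh optional [sphere_mesh()] the assignment refers to.
#' @return an object of class `parcel_atlas`.
#' @export
parcel_atlas <- function(regions, vertex_assignment = NULL, mesh = NULL) {
  req <- c("region_id", "region_name", "hemisphere", "cx", "cy", "cz")
  if (!all(req %in% names(regions))) {
    stop("regions must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(regions$region_id)) {
    stop("region ids must be unique")
  }
  cen <- as.matrix(regions[, c("cx", "cy", "cz")])
  nrm <- sqrt(rowSums(cen^2))
  if (any(abs(nrm - 1) > 1e-9)) {
    stop("invalid geometry: centroids must have unit norm within 1e-9")
  }
  if (!all(regions$hemisphere %in% c("left", "right"))) {
    stop("hemisphere must be 'left' or 'right'")
  }
  if (!is.null(vertex_assignment)) {
    vertex_assignment <- as.integer(vertex_assignment)
    if (any(is.na(vertex_assignment)) ||
          any(vertex_assignment < 1L) ||
          any(vertex_assignment > nrow(regions))) {
      stop("vertex_assignment maps a vertex to a nonexistent region")
    }
    if (!is.null(mesh) && length(vertex_assignment) != n_vertices(mesh)) {
      stop("vertex_assignment length must equal the mesh vertex count")
    }
  }
  structure(
    list(regions = as.data.frame(regions, stringsAsFactors = FALSE),
         vertex_assignment = vertex_assignment,
         mesh = mesh),
    class = "parcel_atlas"
  )
}

#' @export
print.parcel_atlas <- function(x, ...) {
  cat("parcel_atlas:", nrow(x$regions), "regions (",
      sum(x$regions$hemisphere == "left"), "left /",
      sum(x$regions$hemisphere == "right"), "right );",
      if (is.null(x$vertex_assignment)) "no vertex assignment" else
        paste(length(x$vertex_assignment), "vertices assigned"), "\n")
  invisible(x)
}

n_regions <- function(atlas) nrow(atlas$regions)

atlas_centroids <- function(atlas) {
  as.matrix(atlas$regions[, c("cx", "cy", "cz")])
}

# Centroids with the right hemisphere x-mirrored into left-consistent
# coordinates: homotopic regions land near each other, so
# cross-hemisphere distances are anatomically meaningful. This is the
# same mirror convention the spin rotations use.
atlas_distances <- function(atlas) {
  cen <- atlas_centroids(atlas)
  r <- atlas$regions$hemisphere == "right"
  cen[r, 1] <- -cen[r, 1]
  acos(pmin(1, pmax(-1, tcrossprod(cen))))
}

#' Grow a contiguous parcellation on a spherical mesh
#'
#' Geodesic k-means-style parcellation: seed vertices are drawn at
#' random within each hemisphere, every vertex is assigned to the seed
#' with the smallest graph-geodesic distance (edge lengths as weights),
#' and seeds are relocated to the vertex nearest each region's mean
#' direction; repeated until assignments stabilise. Regions are
#' edge-connected by construction of the graph Voronoi diagram.
#'
#' @param mesh a [sphere_mesh()] (one or both hemispheres).
#' @param n_regions_per_hemisphere regions to grow in each hemisphere
#'   present in the mesh (34 mirrors the Desikan-Killiany atlas).
#' @param seed integer RNG seed.
#' @param max_iter maximum Lloyd iterations.
#' @return a [parcel_atlas()] with vertex assignment.
#' @export
make_atlas <- function(mesh, n_regions_per_hemisphere = 34, seed = 1,
                       max_iter = 12) {
  stopifnot(inherits(mesh, "sphere_mesh"))
  hemis <- intersect(c("left", "right"), unique(mesh$hemisphere))
  assign_all <- integer(n_vertices(mesh))
  reg_rows <- list()
  offset <- 0L
  hseed <- 0L
  for (h in hemis) {
    hseed <- hseed + 1L
    vi <- which(mesh$hemisphere == h)
    k <- n_regions_per_hemisphere
    if (k > length(vi)) stop("more regions requested than vertices")
    sub <- hemi_subgraph(mesh, vi)
    res <- with_seed(derive_seed(seed, hseed),
                     grow_parcels(sub$graph,
                                  mesh$vertices[vi, , drop = FALSE],
                                  k, max_iter))
    if (anyNA(res$assignment)) {
      stop("invalid mesh: unassignable (disconnected) vertex")
    }
    assign_all[vi] <- res$assignment + offset
    cen <- res$centroids
    reg_rows[[h]] <- data.frame(
      region_id = offset + seq_len(k),
      region_name = sprintf("%s_region_%02d", substr(h, 1, 1), seq_len(k)),
      hemisphere = h,
      cx = cen[, 1], cy = cen[, 2], cz = cen[, 3],
      stringsAsFactors = FALSE
    )
    offset <- offset + k
  }
  parcel_atlas(do.call(rbind, c(reg_rows, make.row.names = FALSE)),
               vertex_assignment = assign_all, mesh = mesh)
}

hemi_subgraph <- function(mesh, vi) {
  keep <- mesh$edges[, 1] %in% vi & mesh$edges[, 2] %in% vi
  e <- mesh$edges[keep, , drop = FALSE]
  map <- integer(n_vertices(mesh))
  map[vi] <- seq_along(vi)
  el <- cbind(map[e[, 1]], map[e[, 2]])
  d <- mesh$vertices[e[, 1], , drop = FALSE] -
    mesh$vertices[e[, 2], , drop = FALSE]
  w <- sqrt(rowSums(d^2)) * mesh$radius
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = w)
  list(graph = g, weights = w)
}

grow_parcels <- function(graph, verts, k, max_iter) {
  nv <- nrow(verts)
  seeds <- sample.int(nv, k)
  assignment <- rep(NA_integer_, nv)
  for (it in seq_len(max_iter)) {
    dmat <- igraph::distances(graph, v = seeds)  # k x nv
    new_assign <- apply(dmat, 2, which.min)
    new_assign[!is.finite(dmat[cbind(new_assign, seq_len(nv))])] <- NA
    if (identical(new_assign, assignment)) break
    assignment <- new_assign
    # relocate each seed to the member vertex closest to the mean direction
    for (r in seq_len(k)) {
      members <- which(assignment == r)
      if (!length(members)) next
      m <- colMeans(verts[members, , drop = FALSE])
      nm <- sqrt(sum(m^2))
      if (nm < 1e-8) next  # mean direction undefined (whole sphere)
      seeds[r] <- members[which.max(verts[members, , drop = FALSE] %*%
                                      (m / nm))]
    }
  }
  cen <- t(vapply(seq_len(k), function(r) {
    m <- colMeans(verts[assignment == r, , drop = FALSE])
    nm <- sqrt(sum(m^2))
    if (nm < 1e-8) verts[seeds[r], ] else m / nm
  }, numeric(3)))
  list(assignment = assignment, centroids = cen)
}

#' Aggregate a vertex map (or matrix) to region level
#'
#' @param values per-vertex numeric vector, or subjects x vertices
#'   matrix.
#' @param atlas a [parcel_atlas()] with vertex assignment.
#' @param weights "area" (default; weight each vertex by its surface
#'   area, appropriate for extensive quantities like volume) or "equal".
#' @param mesh mesh supplying vertex areas; defaults to the atlas mesh.
#' @return numeric vector (or matrix) with one entry (column) per
#'   region, in atlas region order.
#' @export
parcel_means <- function(values, atlas, weights = c("area", "equal"),
                         mesh = atlas$mesh) {
  weights <- match.arg(weights)
  if (is.null(atlas$vertex_assignment)) {
    stop("atlas has no vertex assignment")
  }
  asg <- atlas$vertex_assignment
  k <- n_regions(atlas)
  if (!all(seq_len(k) %in% asg)) {
    stop("undefined region: some region has zero assigned vertices")
  }
  w <- if (weights == "area") {
    if (is.null(mesh)) stop("area weighting requires a mesh")
    mesh$vertex_area
  } else {
    rep(1, length(asg))
  }
  one <- function(v) {
    as.numeric(tapply(v * w, asg, sum) / tapply(w, asg, sum))
  }
  if (is.matrix(values)) {
    if (ncol(values) != length(asg)) {
      stop("column count must equal the number of assigned vertices")
    }
    t(apply(values, 1, one))
  } else {
    if (length(values) != length(asg)) {
      stop("map length must equal the number of assigned vertices")
    }
    one(values)
  }
}
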