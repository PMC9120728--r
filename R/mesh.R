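#' Triangulated spherical surface meshes
#'
#' A `sphere_mesh` is the geometric substrate for all vertex-wise
#' computations: a triangulated surface whose vertices lie on the unit
#' sphere, with an optional physical radius used to express areas and
#' edge lengths in millimetres. A mesh may carry vertices from one
#' hemisphere or from both (two disconnected spherical components,
#' mirroring FreeSurfer-style per-hemisphere registration; there are
#' never edges between hemispheres).
#'
#' @param vertices numeric matrix (n x 3) of unit vectors.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param hemisphere character vector, one of "left"/"right" per vertex
#'   (recycled if length 1).
#' @param radius physical sphere radius (mm); areas and edge lengths
#'   scale with it. Default 1 (dimensionless unit sphere).
#'
#' @return An object of class `sphere_mesh` with components `vertices`,
#'   `faces`, `hemisphere`, `radius`, `vertex_area` (per-vertex area,
#'   one third of each incident triangle), `neighbors` (adjacency list)
#'   and `edges` (unique edge matrix).
#' @export
sphere_mesh <- function(vertices, faces, hemisphere = "left", radius = 1) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  nv <- nrow(vertices)
  nrm <- sqrt(rowSums(vertices^2))
  if (any(abs(nrm - 1) > 1e-9)) {
    stop("invalid geometry: vertex norms must equal 1 within 1e-9")
  }
  if (any(faces < 1L) || any(faces > nv)) {
    stop("invalid mesh: face references a vertex index outside 1..", nv)
  }
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3])) {
    stop("invalid mesh: degenerate face with a repeated vertex index")
  }
  hemisphere <- rep_len(as.character(hemisphere), nv)
  if (!all(hemisphere %in% c("left", "right"))) {
    stop("hemisphere labels must be 'left' or 'right'")
  }
  edges <- mesh_edges(faces)
  structure(
    list(
      vertices = vertices,
      faces = faces,
      hemisphere = hemisphere,
      radius = as.numeric(radius),
      vertex_area = vertex_areas(vertices, faces) * radius^2,
      neighbors = neighbors_from_edges(edges, nv),
      edges = edges
    ),
    class = "sphere_mesh"
  )
}

#' @export
print.sphere_mesh <- function(x, ...) {
  cat("sphere_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces; hemispheres:",
      paste(unique(x$hemisphere), collapse = "+"),
      sprintf("; radius %g; total area %.4f\n", x$radius,
              sum(x$vertex_area)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

# unique undirected edges of a triangulation, sorted rows
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

neighbors_from_edges <- function(edges, nv) {
  adj <- vector("list", nv)
  idx <- c(edges[, 1], edges[, 2])
  nbr <- c(edges[, 2], edges[, 1])
  ord <- order(idx)
  spl <- split(nbr[ord], factor(idx[ord], levels = seq_len(nv)))
  for (i in seq_len(nv)) adj[[i]] <- sort(unname(spl[[i]]))
  adj
}

# per-vertex area: one third of each incident flat triangle
vertex_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a
  v <- cc - a
  cr <- cbind(
    u[, 2] * v[, 3] - u[, 3] * v[, 2],
    u[, 3] * v[, 1] - u[, 1] * v[, 3],
    u[, 1] * v[, 2] - u[, 2] * v[, 1]
  )
  tri_area <- 0.5 * sqrt(rowSums(cr^2))
  va <- numeric(nrow(vertices))
  for (k in 1:3) {
    tab <- tapply(tri_area, faces[, k], sum)
    ii <- as.integer(names(tab))
    va[ii] <- va[ii] + tab / 3
  }
  va
}

#' Vertex adjacency of a mesh
#'
#' Neighbor sets derived from shared triangle edges; symmetric by
#' construction.
#'
#' @param mesh a [sphere_mesh()].
#' @return list of integer vectors, one per vertex.
#' @export
vertex_neighbors <- function(mesh) {
  stopifnot(inherits(mesh, "sphere_mesh"))
  mesh$neighbors
}

#' Great-circle distance between unit vectors
#'
#' @param a,b unit 3-vectors (or n x 3 matrices of unit rows).
#' @param tol tolerance on the unit-norm precondition.
#' @return angle(s) in radians, in \[0, pi\].
#' @export
geodesic_distance <- function(a, b, tol = 1e-6) {
  a <- rbind(a); b <- rbind(b)
  if (any(abs(sqrt(rowSums(a^2)) - 1) > tol) ||
        any(abs(sqrt(rowSums(b^2)) - 1) > tol)) {
    stop("invalid geometry: inputs must be unit vectors")
  }
  d <- rowSums(a * b)
  out <- acos(pmin(1, pmax(-1, d)))
  if (length(out) == 1L) out[[1]] else out
}

# mean Euclidean edge length in physical units (chord length x radius)
mean_edge_length <- function(mesh) {
  e <- mesh$edges
  d <- mesh$vertices[e[, 1], , drop = FALSE] -
    mesh$vertices[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2))) * mesh$radius
}

# ---- icosphere construction -------------------------------------------

icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v / sqrt(rowSums(v^2))
}

icosahedron_faces <- function() {
  matrix(c(
    1, 12, 6,  1, 6, 2,   1, 2, 8,   1, 8, 11,  1, 11, 12,
    2, 6, 10,  6, 12, 5,  12, 11, 3, 11, 8, 7,  8, 2, 9,
    4, 10, 5,  4, 5, 3,   4, 3, 7,   4, 7, 9,   4, 9, 10,
    5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,   10, 9, 2
  ), ncol = 3, byrow = TRUE)
}

#' Recursively subdivided icosahedral sphere mesh
#'
#' Each subdivision splits every triangle into four and projects the new
#' midpoints to the sphere, giving `10 * 4^level + 2` vertices and
#' `20 * 4^level` faces.
#'
#' @param level subdivision level (>= 0); level 0 is the icosahedron.
#' @param hemisphere label attached to every vertex.
#' @param radius physical radius (mm).
#' @return a [sphere_mesh()].
#' @export
make_icosphere <- function(level = 3, hemisphere = "left", radius = 1) {
  if (level < 0) stop("level must be >= 0")
  v <- icosahedron_vertices()
  f <- icosahedron_faces()
  for (l in seq_len(level)) {
    res <- subdivide_once(v, f)
    v <- res$vertices
    f <- res$faces
  }
  sphere_mesh(v, f, hemisphere = hemisphere, radius = radius)
}

subdivide_once <- function(v, f) {
  nv <- nrow(v)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ukey <- unique(key)
  mid_id <- match(key, ukey) + nv
  ue <- e[!duplicated(key), , drop = FALSE]
  mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  nf <- nrow(f)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m13 <- mid_id[2 * nf + seq_len(nf)]
  faces <- rbind(
    cbind(f[, 1], m12, m13),
    cbind(f[, 2], m23, m12),
    cbind(f[, 3], m13, m23),
    cbind(m12, m23, m13)
  )
  list(vertices = rbind(v, mids), faces = faces)
}

#' Two-hemisphere cortical surface
#'
#' Concatenates a left and a right icosphere into one mesh whose two
#' components are disconnected (no cross-hemisphere edges), the way
#' FreeSurfer keeps the hemispheres as separately registered spheres.
#'
#' @inheritParams make_icosphere
#' @return a [sphere_mesh()] with both hemispheres.
#' @export
make_cortex <- function(level = 3, radius = 1) {
  lh <- make_icosphere(level, "left", radius)
  rh <- make_icosphere(level, "right", radius)
  nv <- n_vertices(lh)
  sphere_mesh(
    rbind(lh$vertices, rh$vertices),
    rbind(lh$faces, rh$faces + nv),
    hemisphere = c(lh$hemisphere, rh$hemisphere),
    radius = radius
  )
}
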