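#' Read and write pipeline inputs
#'
#' All formats are plain text: OFF meshes (with a small JSON sidecar
#' carrying hemisphere labels and radius), CSV tables for atlas, cohort
#' and connectome, and a dense CSV for the subjects x vertices matrix.
#' Every reader enforces the type invariants at load time and fails
#' with the offending row/column named; nothing is silently coerced.
#'
#' @name io
NULL

#' @rdname io
#' @param mesh a [sphere_mesh()].
#' @param path output file path (`.off`; a `<path>.json` sidecar is
#'   written alongside).
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(n_vertices(mesh), nrow(mesh$faces), 0), con)
  utils::write.table(format(mesh$vertices, digits = 17), con,
                     row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con,
                     row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(hemisphere = mesh$hemisphere, radius = mesh$radius),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname io
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  if (!identical(trimws(lines[1]), "OFF")) {
    stop("not an OFF file: ", path)
  }
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  verts <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE),
                  nv, 3, byrow = TRUE)
  fl <- matrix(scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE),
               nf, 4, byrow = TRUE)
  if (any(fl[, 1] != 3)) stop("non-triangular face in ", path)
  meta_path <- paste0(path, ".json")
  hemisphere <- "left"; radius <- 1
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    hemisphere <- meta$hemisphere
    radius <- meta$radius
  }
  sphere_mesh(verts, fl[, 2:4] + 1L, hemisphere = hemisphere,
              radius = radius)
}

#' @rdname io
#' @param atlas a [parcel_atlas()].
#' @export
write_atlas <- function(atlas, path) {
  utils::write.csv(atlas$regions, path, row.names = FALSE)
  if (!is.null(atlas$vertex_assignment)) {
    utils::write.csv(
      data.frame(vertex = seq_along(atlas$vertex_assignment),
                 region_id = atlas$regions$region_id[
                   atlas$vertex_assignment]),
      sub("\\.csv$", "_vertices.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname io
#' @param mesh optional mesh to attach to the loaded atlas.
#' @export
read_atlas <- function(path, mesh = NULL) {
  regions <- utils::read.csv(path, stringsAsFactors = FALSE)
  vpath <- sub("\\.csv$", "_vertices.csv", path)
  assign <- NULL
  if (file.exists(vpath)) {
    vtab <- utils::read.csv(vpath)
    assign <- match(vtab$region_id[order(vtab$vertex)],
                    regions$region_id)
    if (anyNA(assign)) {
      stop("vertex assignment references unknown region_id at vertex ",
           which(is.na(assign))[1])
    }
  }
  parcel_atlas(regions, vertex_assignment = assign, mesh = mesh)
}

#' @rdname io
#' @param cohort a [cohort_table()].
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_cohort <- function(path) {
  cohort_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname io
#' @param volumes subjects x vertices matrix; rows named by subject.
#' @param subject_id subject identifiers for the rows.
#' @export
write_vertex_matrix <- function(volumes, subject_id, path) {
  df <- data.frame(subject_id = subject_id,
                   format(volumes, digits = 17, trim = TRUE),
                   stringsAsFactors = FALSE)
  names(df) <- c("subject_id", paste0("v", seq_len(ncol(volumes))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @param cohort optional [cohort_table()]; when given, row order is
#'   checked to be a bijection with the cohort's subjects.
#' @export
read_vertex_matrix <- function(path, cohort = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!is.null(cohort)) {
    if (!setequal(ids, cohort$subject_id) ||
          length(ids) != nrow(cohort)) {
      stop("vertex matrix rows are not a bijection with the cohort")
    }
    m <- m[match(cohort$subject_id, ids), , drop = FALSE]
  }
  m
}

#' @rdname io
#' @param conn a [connectome()].
#' @export
write_connectome <- function(conn, path) {
  m <- unclass(conn)
  df <- data.frame(region_id = rownames(m) %||% seq_len(nrow(m)),
                   format(m, digits = 17, trim = TRUE))
  names(df) <- c("region_id", colnames(m) %||% seq_len(ncol(m)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @param atlas optional [parcel_atlas()] used to validate dimensions.
#' @param path file path.
#' @export
read_connectome <- function(path, atlas = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  connectome(m, atlas)
}
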