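#' Suprathreshold cluster extraction
#'
#' Vertices with uncorrected p below the vertex-wise threshold are
#' split by effect sign and grouped into edge-connected components of
#' the mesh graph. Cluster size is the summed vertex area (robust to
#' mesh resolution), and clusters are returned in deterministic order
#' of decreasing size.
#'
#' @param stats a `stat_map` from [fit_vertex_glm()], or any data.frame
#'   with columns `p` and `t` (sign carrier).
#' @param mesh the [sphere_mesh()] the map lives on.
#' @param vertex_p_threshold vertex-wise p threshold in (0, 1);
#'   0.001 is the conventional choice.
#' @return data.frame with one row per cluster: `cluster_id`, `sign`,
#'   `size` (summed vertex area), `n_vertices`, `peak_vertex` (largest
#'   |t|), `peak_t`, `hemisphere`; the member vertex indices are kept
#'   in the `members` attribute (a list). Empty data.frame when nothing
#'   survives.
#' @export
extract_clusters <- function(stats, mesh, vertex_p_threshold = 0.001) {
  if (vertex_p_threshold <= 0 || vertex_p_threshold >= 1) {
    stop("vertex_p_threshold must lie in (0, 1)")
  }
  sel <- which(stats$p < vertex_p_threshold)
  empty <- data.frame(cluster_id = integer(), sign = character(),
                      size = numeric(), n_vertices = integer(),
                      peak_vertex = integer(), peak_t = numeric(),
                      hemisphere = character(),
                      stringsAsFactors = FALSE)
  attr(empty, "members") <- list()
  attr(empty, "vertex_p_threshold") <- vertex_p_threshold
  if (!length(sel)) return(empty)
  sgn <- sign(stats$t)
  comp <- thresholded_components(mesh, sel, sgn)
  if (!length(comp)) return(empty)
  rows <- lapply(comp, function(v) {
    pk <- v[which.max(abs(stats$t[v]))]
    data.frame(
      sign = if (sgn[pk] >= 0) "positive" else "negative",
      size = sum(mesh$vertex_area[v]),
      n_vertices = length(v),
      peak_vertex = pk,
      peak_t = stats$t[pk],
      hemisphere = mesh$hemisphere[pk],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$size, out$peak_vertex)
  out <- out[ord, , drop = FALSE]
  out <- cbind(cluster_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "members") <- comp[ord]
  attr(out, "vertex_p_threshold") <- vertex_p_threshold
  out
}

# connected components among selected vertices, same-sign edges only
thresholded_components <- function(mesh, sel, sgn) {
  inset <- logical(n_vertices(mesh))
  inset[sel] <- TRUE
  e <- mesh$edges
  keep <- inset[e[, 1]] & inset[e[, 2]] & sgn[e[, 1]] == sgn[e[, 2]]
  map <- integer(n_vertices(mesh))
  map[sel] <- seq_along(sel)
  g <- igraph::graph_from_edgelist(
    cbind(map[e[keep, 1]], map[e[keep, 2]]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(sel) - igraph::vcount(g)))
  cmp <- igraph::components(g)$membership
  unname(lapply(split(sel, cmp), sort))
}

#' Monte Carlo null distribution of maximum cluster size
#'
#' Simulates smooth Gaussian null fields on the analysis mesh: each
#' iteration draws an independent standard-normal value per vertex,
#' smooths the field with the analysis FWHM, restandardises it to unit
#' marginal variance (so the vertex threshold keeps its nominal normal
#' tail probability), converts to two-sided normal p-values, extracts
#' clusters at the vertex threshold and records the maximum cluster
#' size (0 when nothing survives).
#'
#' @param mesh the analysis [sphere_mesh()].
#' @param fwhm smoothing FWHM matching the analysed data (mesh units).
#' @param vertex_p_threshold vertex-wise threshold used for the data.
#' @param n_iter number of simulated fields.
#' @param seed RNG seed.
#' @param op optional precomputed [smoothing_operator()] for `fwhm`.
#' @param chunk iterations simulated per block (memory control).
#' @return object of class `null_cluster_distribution`: list with
#'   `max_size` (length `n_iter`), `fwhm`, `vertex_p_threshold`,
#'   `n_iter`, `seed`.
#' @export
simulate_null_clusters <- function(mesh, fwhm, vertex_p_threshold,
                                   n_iter, seed = 1, op = NULL,
                                   chunk = 500L) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (is.null(op)) op <- smoothing_operator(mesh, fwhm)
  nv <- n_vertices(mesh)
  max_size <- numeric(n_iter)
  with_seed(seed, {
    done <- 0L
    while (done < n_iter) {
      nb <- min(chunk, n_iter - done)
      Z <- matrix(stats::rnorm(nb * nv), nb, nv)
      if (op$iterations > 0L) {
        Z <- (Z %*% op$S) / rep(op$marginal_sd, each = nb)
      }
      P <- 2 * stats::pnorm(-abs(Z))
      for (i in seq_len(nb)) {
        cl <- extract_clusters(
          data.frame(p = P[i, ], t = Z[i, ]), mesh,
          vertex_p_threshold)
        max_size[done + i] <- if (nrow(cl)) max(cl$size) else 0
      }
      done <- done + nb
    }
  })
  structure(list(max_size = max_size, fwhm = fwhm,
                 vertex_p_threshold = vertex_p_threshold,
                 n_iter = as.integer(n_iter), seed = seed),
            class = "null_cluster_distribution")
}

#' Cluster-wise corrected p-value
#'
#' Add-one Monte Carlo p-value: `(1 + #\{null maxima >= observed size\})
#' / (1 + n_iter)`. The null's smoothing FWHM and vertex threshold must
#' match the settings the cluster was extracted under.
#'
#' @param size observed cluster size(s) (summed vertex area), or a
#'   cluster table from [extract_clusters()].
#' @param null a `null_cluster_distribution`.
#' @param fwhm,vertex_p_threshold analysis settings for the observed
#'   cluster(s); checked against the null's metadata.
#' @return numeric vector of corrected p-values in (0, 1\].
#' @export
cluster_pvalue <- function(size, null, fwhm = null$fwhm,
                           vertex_p_threshold = null$vertex_p_threshold) {
  stopifnot(inherits(null, "null_cluster_distribution"))
  if (!isTRUE(all.equal(fwhm, null$fwhm)) ||
        !isTRUE(all.equal(vertex_p_threshold,
                          null$vertex_p_threshold))) {
    stop("configuration mismatch: null distribution was simulated ",
         "with fwhm=", null$fwhm, ", threshold=",
         null$vertex_p_threshold)
  }
  if (is.data.frame(size)) size <- size$size
  vapply(size, function(s) {
    (1 + sum(null$max_size >= s)) / (1 + null$n_iter)
  }, numeric(1))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at rate `q`: reject the hypotheses with the
#' smallest p-values up to the largest `i` with `p_(i) <= i * q / m`.
#' Built on `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues vector of p-values in \[0, 1\].
#' @param q target false discovery rate in (0, 1).
#' @return list with `reject` (logical mask in input order),
#'   `threshold` (largest rejected p, 0 if none) and `adjusted`
#'   (BH-adjusted p-values).
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (!length(pvalues)) {
    return(list(reject = logical(), threshold = 0, adjusted = numeric()))
  }
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  reject <- adj <= q
  list(reject = reject,
       threshold = if (any(reject)) max(pvalues[reject]) else 0,
       adjusted = adj)
}
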