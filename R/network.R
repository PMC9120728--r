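#' Normative functional connectome
#'
#' Validates a region x region weight matrix: symmetric within 1e-9,
#' zero diagonal, weights in \[-1, 1\], dimensions matching the atlas
#' region count when an atlas is supplied.
#'
#' @param weights square numeric matrix.
#' @param atlas optional [parcel_atlas()] fixing region order.
#' @return the matrix with class `connectome` (region ids as dimnames
#'   when an atlas is given).
#' @export
connectome <- function(weights, atlas = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("connectome must be square")
  asym <- abs(weights - t(weights))
  if (any(asym > 1e-9)) {
    ij <- sort(which(asym == max(asym), arr.ind = TRUE)[1, ])
    stop("invalid connectome: asymmetric at cell (", ij[1], ", ",
         ij[2], "), |w_ij - w_ji| = ", format(max(asym)))
  }
  if (any(abs(diag(weights)) > 1e-12)) {
    stop("invalid connectome: nonzero diagonal at region ",
         which(abs(diag(weights)) > 1e-12)[1])
  }
  if (any(weights < -1 - 1e-9 | weights > 1 + 1e-9)) {
    stop("invalid connectome: weights outside [-1, 1]")
  }
  if (!is.null(atlas)) {
    if (nrow(weights) != n_regions(atlas)) {
      stop("connectome dimension (", nrow(weights),
           ") does not match atlas region count (", n_regions(atlas), ")")
    }
    dimnames(weights) <- list(atlas$regions$region_id,
                              atlas$regions$region_id)
  }
  class(weights) <- c("connectome", "matrix", "array")
  weights
}

#' Weighted-degree centrality
#'
#' Per-region sum of all weighted connections — the hub measure used to
#' ask whether atrophy maps preferentially fall on densely connected
#' cortex. Negative edges are handled per `mode`: dropped
#' ("positive_only", the default for correlation-based normative
#' connectomes), summed as-is ("signed") or in absolute value
#' ("absolute").
#'
#' @param conn a [connectome()] (or symmetric zero-diagonal matrix).
#' @param mode weight-handling mode.
#' @return numeric vector of centralities with attribute `mode`.
#' @export
weighted_degree <- function(conn,
                            mode = c("positive_only", "signed",
                                     "absolute")) {
  mode <- match.arg(mode)
  if (!inherits(conn, "connectome")) conn <- connectome(conn)
  w <- switch(mode,
    positive_only = pmax(unclass(conn), 0),
    signed = unclass(conn),
    absolute = abs(unclass(conn))
  )
  out <- rowSums(w)
  attr(out, "mode") <- mode
  out
}

#' Pearson spatial similarity of two region-level maps
#'
#' @param map_a,map_b numeric vectors of equal length (>= 3) over the
#'   same region order.
#' @return Pearson correlation coefficient.
#' @export
map_correlation <- function(map_a, map_b) {
  if (length(map_a) != length(map_b)) stop("maps must have equal length")
  if (length(map_a) < 3) stop("need at least 3 regions")
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0) {
    stop("undefined correlation: constant map")
  }
  stats::cor(map_a, map_b)
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Spin rotation of a parcellation
#'
#' Draws one uniform random 3D rotation, applies it to the
#' left-hemisphere centroids and its x-axis mirror to the
#' right-hemisphere centroids, then reassigns each original region the
#' value of the nearest rotated centroid within its hemisphere
#' (assignment with replacement). Rotating both hemispheres with
#' mirrored rotations preserves homotopy, the standard spin-null
#' construction for bilateral atlases.
#'
#' @param atlas a [parcel_atlas()].
#' @param seed RNG seed (NULL uses the current RNG state).
#' @param rotation optional 3x3 rotation matrix overriding the random
#'   draw (e.g. `diag(3)` gives the identity permutation).
#' @return integer permutation `perm`: a spun map is `map[perm]`.
#' @export
spin_rotate <- function(atlas, seed = NULL, rotation = NULL) {
  if (is.null(rotation)) {
    rotation <- with_seed(seed, random_rotation())
  }
  cen <- atlas_centroids(atlas)
  hemi <- atlas$regions$hemisphere
  mirror <- diag(c(-1, 1, 1))
  perm <- integer(nrow(cen))
  for (h in c("left", "right")) {
    idx <- which(hemi == h)
    if (!length(idx)) next
    R <- if (h == "left") rotation else mirror %*% rotation %*% mirror
    rot <- cen[idx, , drop = FALSE] %*% t(R)
    # nearest rotated centroid on the sphere = max dot product
    perm[idx] <- idx[max.col(cen[idx, , drop = FALSE] %*% t(rot),
                             ties.method = "first")]
  }
  perm
}

#' Batch of spin permutations
#'
#' @param atlas a [parcel_atlas()].
#' @param n_perm number of spins.
#' @param seed RNG seed.
#' @return integer matrix (n_perm x n_regions); row `k` permutes a map
#'   as `map[perm[k, ]]`.
#' @export
spin_permutations <- function(atlas, n_perm, seed = 1) {
  cen <- atlas_centroids(atlas)
  hemi <- atlas$regions$hemisphere
  mirror <- diag(c(-1, 1, 1))
  idxL <- which(hemi == "left")
  idxR <- which(hemi == "right")
  cenL <- cen[idxL, , drop = FALSE]
  cenR <- cen[idxR, , drop = FALSE]
  P <- matrix(0L, n_perm, nrow(cen))
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      R <- random_rotation()
      if (length(idxL)) {
        P[k, idxL] <- idxL[max.col(cenL %*% (R %*% t(cenL)),
                                   ties.method = "first")]
      }
      if (length(idxR)) {
        RR <- mirror %*% R %*% mirror
        P[k, idxR] <- idxR[max.col(cenR %*% (RR %*% t(cenR)),
                                   ties.method = "first")]
      }
    }
  })
  P
}

# correlations of each permuted row of `mat` with fixed vector y
row_correlations <- function(mat, y) {
  n <- length(y)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  mm <- rowMeans(mat)
  num <- mat %*% yc        # row-mean term vanishes against centred y
  den <- sqrt(rowSums(mat^2) - n * mm^2) * sy
  as.numeric(num / den)
}

#' Spin permutation test of spatial similarity
#'
#' Observed statistic is the Pearson correlation of the two maps; the
#' null is built by spin-rotating `map_a` (only `map_a`) and
#' recomputing the correlation against the fixed `map_b`. P-value uses
#' the add-one convention; two-sided by default.
#'
#' @param map_a,map_b region-level maps aligned to the atlas.
#' @param atlas a [parcel_atlas()].
#' @param n_perm number of spins.
#' @param seed RNG seed.
#' @param alternative "two.sided", "greater" or "less".
#' @param perms optional precomputed [spin_permutations()] matrix.
#' @return object of class `spin_null`: list with `observed`, `null`
#'   (length `n_perm`), `p`, `n_perm`, `seed`, `alternative`.
#' @export
spin_test <- function(map_a, map_b, atlas, n_perm = 1000, seed = 1,
                      alternative = c("two.sided", "greater", "less"),
                      perms = NULL) {
  alternative <- match.arg(alternative)
  if (n_perm < 1 && is.null(perms)) stop("n_perm must be >= 1")
  observed <- map_correlation(map_a, map_b)
  if (is.null(perms)) perms <- spin_permutations(atlas, n_perm, seed)
  n_perm <- nrow(perms)
  spun <- matrix(map_a[t(perms)], n_perm, length(map_a), byrow = TRUE)
  nullr <- row_correlations(spun, map_b)
  p <- switch(alternative,
    two.sided = (1 + sum(abs(nullr) >= abs(observed))) / (1 + n_perm),
    greater = (1 + sum(nullr >= observed)) / (1 + n_perm),
    less = (1 + sum(nullr <= observed)) / (1 + n_perm)
  )
  structure(list(observed = observed, null = nullr, p = p,
                 n_perm = n_perm, seed = seed,
                 alternative = alternative),
            class = "spin_null")
}

#' @export
print.spin_null <- function(x, ...) {
  cat(sprintf("spin_test: observed r = %.4f, p = %.4g (%s, %d spins)\n",
              x$observed, x$p, x$alternative, x$n_perm))
  invisible(x)
}

#' Disease-epicenter mapping
#'
#' For every region, correlates its connectivity profile (its
#' connectome row, self-connection excluded from both vectors) with the
#' region-level atrophy map, and assesses each correlation with a spin
#' permutation test that rotates the atrophy map (never the
#' connectome). Regions are ranked by correlation magnitude; a region
#' is flagged an epicenter when its spin p-value falls below `alpha`.
#'
#' @param conn a [connectome()].
#' @param atrophy region-level atrophy map (e.g. parcel means of the
#'   severity partial-correlation map) aligned to the atlas.
#' @param atlas a [parcel_atlas()].
#' @param n_perm spins per region (one shared permutation set).
#' @param alpha significance level for the epicenter flag.
#' @param seed RNG seed.
#' @return object of class `epicenter_result`: data.frame with columns
#'   `region_id`, `region_name`, `r`, `p_spin`, `rank`, `significant`.
#' @export
epicenter_map <- function(conn, atrophy, atlas, n_perm = 1000,
                          alpha = 0.01, seed = 1) {
  if (!inherits(conn, "connectome")) conn <- connectome(conn, atlas)
  k <- n_regions(atlas)
  if (length(atrophy) != k) stop("atrophy map length must match atlas")
  if (stats::sd(atrophy) == 0) {
    stop("undefined correlation: constant atrophy map")
  }
  perms <- spin_permutations(atlas, n_perm, seed)
  spun_full <- matrix(atrophy[t(perms)], nrow(perms), k, byrow = TRUE)
  r <- numeric(k)
  p <- numeric(k)
  W <- unclass(conn)
  for (j in seq_len(k)) {
    prof <- W[j, -j]
    r[j] <- map_correlation(prof, atrophy[-j])
    nullr <- row_correlations(spun_full[, -j, drop = FALSE], prof)
    p[j] <- (1 + sum(abs(nullr) >= abs(r[j]))) / (1 + nrow(perms))
  }
  out <- data.frame(region_id = atlas$regions$region_id,
                    region_name = atlas$regions$region_name,
                    r = r, p_spin = p,
                    rank = rank(-abs(r), ties.method = "first"),
                    significant = p < alpha)
  attr(out, "alpha") <- alpha
  attr(out, "n_perm") <- as.integer(nrow(perms))
  attr(out, "seed") <- seed
  class(out) <- c("epicenter_result", "data.frame")
  out
}

#' Similarity of an atrophy map to weighted-degree centrality
#'
#' Convenience composition: compute weighted-degree centrality of the
#' connectome, correlate it with the region-level atrophy/statistic
#' map, and assess the correlation with a spin permutation test (the
#' atrophy map is rotated).
#'
#' @param region_stats region-level statistic map (e.g. parcel means of
#'   the severity partial-correlation map).
#' @param conn a [connectome()].
#' @param atlas a [parcel_atlas()].
#' @param n_perm number of spins.
#' @param seed RNG seed.
#' @param mode weight-handling mode for [weighted_degree()].
#' @return a `spin_null` (see [spin_test()]) with the centrality vector
#'   attached as attribute `centrality`.
#' @export
centrality_similarity <- function(region_stats, conn, atlas,
                                  n_perm = 1000, seed = 1,
                                  mode = "positive_only") {
  wd <- weighted_degree(conn, mode)
  res <- spin_test(region_stats, as.numeric(wd), atlas,
                   n_perm = n_perm, seed = seed)
  attr(res, "centrality") <- as.numeric(wd)
  attr(res, "mode") <- mode
  res
}
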