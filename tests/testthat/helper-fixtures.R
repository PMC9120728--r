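# Shared fixtures (memoised: built once per test run) and independent
# brute-force oracles used to cross-check the package implementations.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fix_cortex <- function(level = 3) {
  memo(paste0("cortex", level), function() make_cortex(level))
}

fix_atlas <- function(level = 3, n = 34) {
  memo(sprintf("atlas%d_%d", level, n),
       function() make_atlas(fix_cortex(level), n, seed = 2))
}

fix_connectome <- function() {
  memo("conn", function() {
    simulate_connectome(simulation_config(seed = 7), fix_atlas())
  })
}

# ---- oracles ---------------------------------------------------------

# breadth-first flood fill over the neighbor lists; independent of the
# igraph-based component extraction in the package
flood_fill_oracle <- function(mesh, sel, sgn) {
  inset <- logical(nrow(mesh$vertices))
  inset[sel] <- TRUE
  visited <- logical(nrow(mesh$vertices))
  comps <- list()
  for (s in sel) {
    if (visited[s]) next
    queue <- s
    visited[s] <- TRUE
    comp <- integer()
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      comp <- c(comp, v)
      for (nb in mesh$neighbors[[v]]) {
        if (inset[nb] && !visited[nb] && sgn[nb] == sgn[v]) {
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# step-up FDR by explicit enumeration of every candidate cutoff
fdr_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kmax <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) kmax <- i
  reject <- logical(m)
  if (kmax > 0) reject[ord[seq_len(kmax)]] <- TRUE
  reject
}

# double-loop weighted degree
weighted_degree_oracle <- function(w, mode) {
  k <- nrow(w)
  out <- numeric(k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      wij <- w[i, j]
      out[i] <- out[i] + switch(mode,
        positive_only = max(wij, 0),
        signed = wij,
        absolute = abs(wij))
    }
  }
  out
}

# random symmetric zero-diagonal matrix in [-1, 1]
random_connectome_matrix <- function(k) {
  w <- matrix(stats::runif(k * k, -1, 1), k, k)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}
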