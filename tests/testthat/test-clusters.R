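fake_stats <- function(p, t) data.frame(p = p, t = t)

test_that("no suprathreshold vertices gives an empty cluster table", {
  m <- fix_cortex(2)
  nv <- nrow(m$vertices)
  cl <- extract_clusters(fake_stats(rep(0.5, nv), rnorm(nv)), m, 0.001)
  expect_identical(nrow(cl), 0L)
  expect_identical(attr(cl, "members"), list())
})

test_that("contiguous suprathreshold vertices form one cluster with summed area", {
  m <- fix_cortex(2)
  nv <- nrow(m$vertices)
  trio <- c(1L, m$neighbors[[1]][1:2])  # vertex 1 plus two of its neighbors
  p <- rep(0.9, nv); p[trio] <- 1e-5
  t <- rep(0.1, nv); t[trio] <- 5
  cl <- extract_clusters(fake_stats(p, t), m, 0.001)
  expect_identical(nrow(cl), 1L)
  expect_equal(cl$size, sum(m$vertex_area[trio]), tolerance = 1e-12)
  expect_identical(cl$n_vertices, 3L)
  expect_identical(sort(attr(cl, "members")[[1]]), sort(trio))
  expect_identical(cl$sign, "positive")
})

test_that("patches separated by a subthreshold ring form distinct clusters", {
  m <- fix_cortex(2)
  nv <- nrow(m$vertices)
  v1 <- 10L
  far <- which.min(m$vertices %*% m$vertices[v1, ])  # antipodal-ish
  patch1 <- c(v1, m$neighbors[[v1]])
  patch2 <- setdiff(c(far, m$neighbors[[far]]), patch1)
  p <- rep(0.9, nv); p[c(patch1, patch2)] <- 1e-5
  t <- rep(0, nv); t[patch1] <- 4; t[patch2] <- -4
  cl <- extract_clusters(fake_stats(p, t), m, 0.001)
  expect_identical(nrow(cl), 2L)
  expect_setequal(cl$sign, c("positive", "negative"))
})

test_that("cluster extraction matches the flood-fill oracle on random maps", {
  m <- fix_cortex(2)
  nv <- nrow(m$vertices)
  set.seed(31)
  for (i in 1:50) {
    z <- rnorm(nv, sd = 1.5)
    p <- 2 * pnorm(-abs(z))
    thr <- sample(c(0.01, 0.05, 0.1), 1)
    cl <- extract_clusters(fake_stats(p, z), m, thr)
    oracle <- flood_fill_oracle(m, which(p < thr), sign(z))
    got <- attr(cl, "members")
    expect_identical(length(got), length(oracle))
    key <- function(l) paste(sapply(l, paste, collapse = ","))
    expect_setequal(key(got), key(oracle))
    # sizes sorted descending
    expect_true(all(diff(cl$size) <= 1e-12))
  }
})

test_that("same-sign adjacency splits touching opposite-sign patches", {
  m <- fix_cortex(2)
  nv <- nrow(m$vertices)
  v <- 30L
  nb <- m$neighbors[[v]]
  p <- rep(0.9, nv); p[c(v, nb)] <- 1e-5
  t <- rep(0, nv); t[v] <- 4; t[nb] <- -4
  cl <- extract_clusters(fake_stats(p, t), m, 0.001)
  expect_identical(sum(cl$sign == "positive"), 1L)
  expect_true(all(cl$n_vertices[cl$sign == "positive"] == 1))
})

test_that("Monte Carlo null: degenerate threshold, determinism, tail calibration", {
  m <- fix_cortex(2)
  # a practically unreachable threshold yields all-zero maxima
  null0 <- simulate_null_clusters(m, 0, 1e-300, 20, seed = 1)
  expect_true(all(null0$max_size == 0))
  # determinism under a fixed seed
  n1 <- simulate_null_clusters(m, 0.8, 0.01, 30, seed = 9)
  n2 <- simulate_null_clusters(m, 0.8, 0.01, 30, seed = 9)
  expect_identical(n1$max_size, n2$max_size)
  # fwhm = 0: suprathreshold fraction matches the normal tail
  nv <- nrow(m$vertices)
  n_iter <- 150
  thr <- 0.01
  set.seed(101)
  cnt <- with(list(), {
    null <- simulate_null_clusters(m, 0, thr, n_iter, seed = 77)
    # recount suprathreshold fraction directly from fresh fields
    Z <- matrix(rnorm(n_iter * nv), n_iter, nv)
    mean(2 * pnorm(-abs(Z)) < thr)
  })
  expect_lt(abs(cnt - thr), 4 * sqrt(thr * (1 - thr) / (n_iter * nv)))
})

test_that("cluster p-values follow the add-one counting convention", {
  null <- structure(list(max_size = as.numeric(seq_len(9999)),
                         fwhm = 0.8, vertex_p_threshold = 0.001,
                         n_iter = 9999L, seed = 1),
                    class = "null_cluster_distribution")
  # larger than every null maximum
  expect_equal(cluster_pvalue(10000, null), 1 / 10000)
  # size zero: every null maximum >= 0
  expect_equal(cluster_pvalue(0, null), 1)
  # observed equal to the null median
  med <- stats::median(null$max_size)
  p_med <- cluster_pvalue(med, null)
  expect_equal(p_med, (1 + sum(null$max_size >= med)) / 10000)
  expect_lt(abs(p_med - 0.5), 0.01)
  # metadata mismatch is a configuration error
  expect_error(cluster_pvalue(10, null, fwhm = 0.4), "mismatch")
  expect_error(cluster_pvalue(10, null, vertex_p_threshold = 0.01),
               "mismatch")
})
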