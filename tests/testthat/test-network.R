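test_that("weighted degree matches direct summation on a toy graph", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[1, 3] <- w[3, 1] <- 0.2
  w[2, 3] <- w[3, 2] <- -0.1
  expect_equal(as.numeric(weighted_degree(w, "positive_only")),
               c(0.7, 0.5, 0.2))
  expect_equal(as.numeric(weighted_degree(w, "signed")),
               c(0.7, 0.4, 0.1))
  expect_equal(as.numeric(weighted_degree(w, "absolute")),
               c(0.7, 0.6, 0.3))
  expect_equal(as.numeric(weighted_degree(matrix(0, 4, 4))), rep(0, 4))
})

test_that("weighted degree equals the brute-force double loop on random connectomes", {
  set.seed(51)
  for (i in 1:40) {
    k <- sample(5:30, 1)
    w <- random_connectome_matrix(k)
    for (mode in c("positive_only", "signed", "absolute")) {
      expect_equal(as.numeric(weighted_degree(w, mode)),
                   weighted_degree_oracle(w, mode), tolerance = 1e-12)
    }
  }
})

test_that("connectome invariants are enforced with the offending cell named", {
  w <- random_connectome_matrix(5)
  w[2, 4] <- w[2, 4] + 1e-6
  expect_error(connectome(w), "asymmetric at cell \\(2, 4\\)")
  w2 <- random_connectome_matrix(5)
  diag(w2)[3] <- 0.2
  expect_error(connectome(w2), "diagonal at region 3")
  w3 <- random_connectome_matrix(5) * 3
  expect_error(connectome(w3), "outside")
  expect_error(connectome(random_connectome_matrix(5), fix_atlas()),
               "does not match")
})

test_that("map correlation handles identity, negation, affine maps and errors", {
  set.seed(52)
  x <- rnorm(20)
  expect_equal(map_correlation(x, x), 1)
  expect_equal(map_correlation(x, -x), -1)
  expect_equal(map_correlation(x, 2.5 * x + 3), 1)
  expect_error(map_correlation(x, rep(1, 20)), "constant")
  expect_error(map_correlation(x, rnorm(19)), "equal length")
  expect_error(map_correlation(x[1:2], x[1:2]), "at least 3")
})

test_that("spin rotations: identity fixed point, isometry, determinism", {
  a <- fix_atlas()
  expect_identical(spin_rotate(a, rotation = diag(3)), 1:68)
  expect_identical(spin_rotate(a, seed = 5), spin_rotate(a, seed = 5))
  cen <- as.matrix(a$regions[, c("cx", "cy", "cz")])
  set.seed(53)
  for (i in 1:20) {
    R <- atrophynet:::random_rotation()
    expect_equal(det(R), 1, tolerance = 1e-9)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
    rot <- cen %*% t(R)
    # rotations preserve all pairwise geodesic distances
    expect_equal(acos(pmin(1, pmax(-1, tcrossprod(rot)))),
                 acos(pmin(1, pmax(-1, tcrossprod(cen)))),
                 tolerance = 1e-9)
  }
  # permutations stay within hemisphere
  P <- spin_permutations(a, 25, seed = 54)
  hemi <- a$regions$hemisphere
  for (k in 1:25) expect_true(all(hemi[P[k, ]] == hemi))
})

test_that("spin test follows the add-one convention and rotates only map_a", {
  a <- fix_atlas()
  set.seed(55)
  map_a <- smooth_region_map(a, seed = 56)
  map_b <- smooth_region_map(a, seed = 57)
  st <- spin_test(map_a, map_b, a, n_perm = 99, seed = 58)
  expect_equal(st$p,
               (1 + sum(abs(st$null) >= abs(st$observed))) / 100)
  expect_gte(st$p, 1 / 100)
  expect_lte(st$p, 1)
  # identical maps: observed r is exactly 1
  st2 <- spin_test(map_a, map_a, a, n_perm = 199, seed = 59)
  expect_equal(st2$observed, 1)
  expect_lt(st2$p, 0.05)
  # null values equal direct recomputation with the same permutations
  P <- spin_permutations(a, 99, seed = 58)
  direct <- apply(P, 1, function(pm) cor(map_a[pm], map_b))
  expect_equal(st$null, direct, tolerance = 1e-12)
})

test_that("spin p-values stabilise as the permutation count grows", {
  a <- fix_atlas()
  conn <- fix_connectome()
  wd <- as.numeric(weighted_degree(conn))
  map <- plant_correlated_map(wd, -0.45, a, seed = 70)
  p5k <- spin_test(map, wd, a, n_perm = 5000, seed = 71)$p
  p10k <- spin_test(map, wd, a, n_perm = 10000, seed = 72)$p
  expect_lt(abs(p5k - p10k), 0.02)
})

test_that("epicenter map: perfect profile match ranks first; errors surface", {
  a <- fix_atlas()
  conn <- fix_connectome()
  atr <- plant_epicenter(conn, 40, 1, a, seed = 60)
  epi <- epicenter_map(conn, atr, a, n_perm = 99, seed = 61)
  expect_identical(epi$rank[40], 1L)
  expect_equal(abs(epi$r[40]), 1, tolerance = 1e-9)
  expect_error(epicenter_map(conn, rep(1, 68), a, n_perm = 9),
               "constant")
})

test_that("epicenter map is equivariant under consistent region relabeling", {
  a <- fix_atlas()
  conn <- fix_connectome()
  atr <- plant_epicenter(conn, 12, 0.8, a, seed = 62)
  epi <- epicenter_map(conn, atr, a, n_perm = 149, seed = 63)
  # permute regions within hemispheres (hemisphere blocks preserved so
  # the atlas layout stays left-then-right)
  set.seed(64)
  pm <- c(sample(1:34), sample(35:68))
  a2 <- parcel_atlas(transform(a$regions[pm, ],
                               region_id = a$regions$region_id))
  conn2 <- connectome(unclass(conn)[pm, pm], a2)
  epi2 <- epicenter_map(conn2, atr[pm], a2, n_perm = 149, seed = 63)
  expect_equal(epi2$r, epi$r[pm], tolerance = 1e-12)
  # same permutation geometry => identical spin p-values
  expect_equal(epi2$p_spin, epi$p_spin[pm], tolerance = 1e-12)
})

test_that("centrality similarity recovers a planted anticorrelation", {
  a <- fix_atlas()
  conn <- fix_connectome()
  wd <- as.numeric(weighted_degree(conn))
  atr <- -1 * (wd - mean(wd)) / sd(wd)
  res <- centrality_similarity(atr, conn, a, n_perm = 99, seed = 65)
  expect_equal(res$observed, -1, tolerance = 1e-12)
  rs <- replicate(30, {
    map <- plant_correlated_map(wd, -0.45, a,
                                seed = sample.int(1e6, 1))
    map_correlation(map, wd)
  })
  expect_lt(abs(mean(rs) - (-0.45)), 0.12)
})
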