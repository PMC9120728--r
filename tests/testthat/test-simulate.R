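test_that("generators are reproducible under a fixed master seed", {
  m <- fix_cortex(2)
  a <- fix_atlas(2)
  cfg <- simulation_config(mesh_level = 2, seed = 99)
  s1 <- simulate_cohort(cfg, m, a)
  s2 <- simulate_cohort(cfg, m, a)
  expect_identical(s1$volumes, s2$volumes)
  expect_identical(s1$cohort, s2$cohort)
  c1 <- simulate_connectome(cfg, a)
  c2 <- simulate_connectome(cfg, a)
  expect_identical(unclass(c1), unclass(c2))
  e1 <- plant_epicenter(c1, 10, 0.7, a, seed = 5)
  e2 <- plant_epicenter(c1, 10, 0.7, a, seed = 5)
  expect_identical(e1, e2)
})

test_that("cohort structure matches the configured study conditions", {
  m <- fix_cortex(2)
  cfg <- simulation_config(mesh_level = 2, seed = 3)
  s <- simulate_cohort(cfg, m)
  co <- s$cohort
  expect_identical(nrow(co), 103L)
  expect_identical(sum(co$group == "case"), 53L)
  expect_identical(sum(is.na(co$severity[co$group == "case"])), 3L)
  expect_true(all(is.na(co$severity[co$group == "control"])))
  sev <- co$severity[!is.na(co$severity)]
  expect_true(all(sev >= 0 & sev <= 54))
  expect_identical(ncol(s$volumes), nrow(m$vertices))
  # planted disc is contiguous and within one hemisphere
  expect_true(length(s$effect_vertices) > 3)
  expect_identical(length(unique(m$hemisphere[s$effect_vertices])), 1L)
})

test_that("pure-noise limit: iid values centered on the baseline", {
  m <- fix_cortex(1)
  cfg <- simulation_config(mesh_level = 1, rho = 0, noise_fwhm = 0,
                           beta_age = 0, beta_sex = 0, beta_etiv = 0,
                           noise_sd = 0.3, seed = 8)
  s <- simulate_cohort(cfg, m)
  expect_equal(mean(s$volumes), cfg$baseline, tolerance = 0.01)
  expect_equal(sd(as.numeric(s$volumes)), 0.3, tolerance = 0.04)
})

test_that("realized partial correlation inside the disc tracks the configured rho", {
  m <- fix_cortex(2)
  rho <- -0.5
  n_rep <- 120
  rs <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    cfg <- simulation_config(mesh_level = 2, rho = rho,
                             seed = 5000 + k)
    s <- simulate_cohort(cfg, m)
    rows <- severity_subset(s$cohort, quiet = TRUE)
    st <- fit_vertex_glm(s$volumes, s$cohort,
                         design_spec("severity", subset = rows))
    rs[k] <- mean(st$r_partial[s$effect_vertices])
  }
  # mean over replicates recovers rho (the effect-scaling algebra);
  # Fisher-z sampling error at n=50 leaves a small attenuation bias
  expect_lt(abs(mean(rs) - rho), 0.05)
})

test_that("rho = 0 plants nothing: p-values uniform at the disc", {
  m <- fix_cortex(2)
  ps <- numeric(80)
  for (k in 1:80) {
    cfg <- simulation_config(mesh_level = 2, rho = 0, seed = 7000 + k)
    s <- simulate_cohort(cfg, m)
    rows <- severity_subset(s$cohort, quiet = TRUE)
    st <- fit_vertex_glm(s$volumes, s$cohort,
                         design_spec("severity", subset = rows))
    ps[k] <- st$p[s$effect_center]
  }
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("connectome construction invariants and distance decay", {
  a <- fix_atlas()
  cfg0 <- simulation_config(conn_noise_sd = 0, decay = 0, n_modules = 1,
                            within_weight = 0.3, seed = 4)
  c0 <- simulate_connectome(cfg0, a)
  off <- unclass(c0)[upper.tri(c0)]
  expect_equal(off, rep(0.3, length(off)), tolerance = 1e-12)
  cfgd <- simulation_config(conn_noise_sd = 0, decay = 1.5,
                            n_modules = 1, seed = 4)
  cd <- simulate_connectome(cfgd, a)
  cen <- as.matrix(a$regions[, c("cx", "cy", "cz")])
  D <- acos(pmin(1, pmax(-1, tcrossprod(cen))))
  iu <- upper.tri(D)
  ord <- order(D[iu])
  w <- unclass(cd)[iu][ord]
  expect_true(all(diff(w) <= 1e-12))  # weight decreasing with distance
  cfg <- simulation_config(seed = 5)
  cc <- simulate_connectome(cfg, a)
  expect_equal(unclass(cc), t(unclass(cc)), tolerance = 1e-12)
  expect_true(all(diag(unclass(cc)) == 0))
})

test_that("planted epicenter limits: noise-free recovery and bounds checks", {
  a <- fix_atlas()
  conn <- fix_connectome()
  atr1 <- plant_epicenter(conn, 25, 1, a, seed = 6)
  prof <- unclass(conn)[25, -25]
  expect_equal(abs(cor(prof, atr1[-25])), 1, tolerance = 1e-9)
  expect_error(plant_epicenter(conn, 0, 0.5, a), "bounds")
  expect_error(plant_epicenter(conn, 25, 1.2, a), "lambda")
  # lambda = 0: planted region not systematically top-ranked
  ranks <- sapply(1:60, function(k) {
    atr <- plant_epicenter(conn, 25, 0, a, seed = 800 + k)
    epi_r <- sapply(1:68, function(j) {
      cor(unclass(conn)[j, -j], atr[-j])
    })
    rank(-abs(epi_r))[25]
  })
  expect_gt(mean(ranks), 10)   # uniform over 1..68 would average 34.5
})
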