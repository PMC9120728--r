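make_test_cohort <- function(n = 40, seed = 1) {
  set.seed(seed)
  cohort_table(data.frame(
    subject_id = sprintf("T%02d", 1:n),
    group = rep(c("case", "control"), length.out = n),
    severity = ifelse(rep(c(TRUE, FALSE), length.out = n),
                      runif(n, 0, 54), NA),
    age = rnorm(n, 44, 10),
    sex = rbinom(n, 1, 0.7),
    etiv = rnorm(n, 1.5e6, 1.5e5)
  ))
}

test_that("volume exactly equal to severity gives partial r = 1 and p ~ 0", {
  co <- make_test_cohort(30)
  rows <- severity_subset(co, quiet = TRUE)
  vol <- matrix(co$severity, nrow(co), 4)
  vol[!rows, ] <- 0
  st <- fit_vertex_glm(vol, co, design_spec("severity", subset = rows))
  expect_equal(st$r_partial, rep(1, 4), tolerance = 1e-8)
  expect_true(all(st$p < 1e-12))
})

test_that("identical group distributions give t = 0 and p = 1", {
  set.seed(4)
  n <- 20
  half <- data.frame(age = rnorm(n, 44, 10), sex = rbinom(n, 1, 0.6),
                     etiv = rnorm(n, 1.5e6, 1e5))
  co <- cohort_table(data.frame(
    subject_id = sprintf("T%02d", 1:(2 * n)),
    group = rep(c("case", "control"), each = n),
    severity = NA_real_,
    rbind(half, half)   # the two groups share identical covariates
  ))
  base <- matrix(rnorm(n * 3), n, 3)
  vol <- rbind(base, base)  # and identical volume maps
  st <- fit_vertex_glm(vol, co, design_spec("group_contrast"))
  expect_equal(st$t, rep(0, 3), tolerance = 1e-10)
  expect_equal(st$p, rep(1, 3), tolerance = 1e-10)
})

test_that("intercept-only nuisance reproduces the closed-form Pearson correlation", {
  co <- make_test_cohort(35)
  rows <- severity_subset(co, quiet = TRUE)
  set.seed(9)
  vol <- matrix(rnorm(35 * 20), 35, 20)
  st <- fit_vertex_glm(vol, co,
                       design_spec("severity", nuisance = character(0),
                                   subset = rows))
  expected <- apply(vol[rows, ], 2,
                    function(y) cor(y, co$severity[rows]))
  expect_equal(st$r_partial, expected, tolerance = 1e-10)
  # and the p-value matches cor.test
  ct <- cor.test(vol[rows, 3], co$severity[rows])
  expect_equal(st$p[3], ct$p.value, tolerance = 1e-10)
})

test_that("partial r is a monotone transform of t with matching sign", {
  co <- make_test_cohort(50)
  rows <- severity_subset(co, quiet = TRUE)
  set.seed(10)
  vol <- matrix(rnorm(50 * 100), 50, 100)
  st <- fit_vertex_glm(vol, co, design_spec("severity", subset = rows))
  df <- attr(st, "df")
  expect_equal(st$r_partial,
               sign(st$t) * sqrt(st$t^2 / (st$t^2 + df)),
               tolerance = 1e-12)
  expect_true(all(sign(st$r_partial) == sign(st$estimate) |
                    st$estimate == 0))
  ord <- order(st$t)
  expect_true(all(diff(st$r_partial[ord]) >= 0))
  expect_identical(attr(st, "df"),
                   sum(rows) - length(attr(st, "columns")))
})

test_that("rank-deficient designs fail naming the collinear columns", {
  co <- make_test_cohort(30)
  co$bdi <- co$age * 2          # exact collinearity with age
  rows <- severity_subset(co, quiet = TRUE)
  vol <- matrix(rnorm(30 * 2), 30, 2)
  expect_error(
    fit_vertex_glm(vol, co,
                   design_spec("severity", extra_nuisance = "bdi",
                               subset = rows)),
    "rank-deficient.*(age|bdi)")
})

test_that("missing covariate values raise an explicit error", {
  co <- make_test_cohort(30)
  co$age[4] <- NA
  vol <- matrix(rnorm(30 * 2), 30, 2)
  expect_error(fit_vertex_glm(vol, co, design_spec("group_contrast")),
               "missing.*age")
  # severity NA rows must be excluded explicitly by the caller
  expect_message(severity_subset(co), "excluded")
})

test_that("planted partial correlation is recovered within the sampling band", {
  # Monte Carlo: cohorts with a true partial correlation of -0.43
  # between severity and volume after covariates
  mesh <- fix_cortex(2)
  n_rep <- 60
  rho <- -0.43
  hits <- 0
  for (k in seq_len(n_rep)) {
    cfg <- simulation_config(mesh_level = 2, rho = rho,
                             n_cases = 53, n_controls = 10,
                             effect_radius = 0.5, seed = 3000 + k)
    sim <- simulate_cohort(cfg, mesh)
    rows <- severity_subset(sim$cohort, quiet = TRUE)
    st <- fit_vertex_glm(sim$volumes, sim$cohort,
                         design_spec("severity", subset = rows))
    rhat <- st$r_partial[sim$effect_center]
    band <- 2 * (1 - rho^2) / sqrt(sum(rows) - 3 - 1)
    hits <- hits + (abs(rhat - rho) < band)
  }
  expect_gte(hits / n_rep, 0.85)   # ~95% coverage expected
})
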