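test_that("stage 1 recovers sigmoid parameters from exact and noisy data", {
  efs <- c(250, 500, 750, 1000, 1500, 2000)
  s <- survival_probability(efs, 800, 200)
  d <- tibble::tibble(
    cell_line = "SW-480", organ = "colon", pulse_duration_us = 100,
    pulse_number = 50, efs_v_cm = efs, replicate = 1,
    viability_pct = 100 * s
  )
  fit <- fit_stage1(d, "SW-480", 100)
  expect_equal(fit$ec_n, 800, tolerance = 1e-6)
  expect_equal(fit$ac_n, 200, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$n_points, 6)

  set.seed(7)
  noisy <- dplyr::mutate(d, viability_pct = 100 * (s + rnorm(6, 0, 0.02)))
  fitn <- fit_stage1(noisy, "SW-480", 100)
  expect_lt(abs(fitn$ec_n - 800) / 800, 0.05)
  expect_lt(abs(fitn$ac_n - 200) / 200, 0.05)
})

test_that("stage 1 rejects degenerate or under-determined designs", {
  base <- tibble::tibble(
    cell_line = "SW-480", organ = "colon", pulse_duration_us = 100,
    pulse_number = 10, replicate = 1
  )
  flat <- dplyr::mutate(tidyr::expand_grid(base, efs_v_cm = c(500, 1000, 1500)),
                        viability_pct = 100)
  expect_error(fit_stage1(flat, "SW-480", 100), class = "ebtsim_fit_failure")
  two <- dplyr::mutate(tidyr::expand_grid(base, efs_v_cm = c(500, 1000)),
                       viability_pct = c(80, 20))
  expect_error(fit_stage1(two, "SW-480", 100),
               class = "ebtsim_insufficient_design")
})

test_that("stage 2 recovers exponential coefficients, including negative rates", {
  ns <- seq(10, 90, by = 10)
  s1 <- tibble::tibble(
    cell_line = "LoVo", organ = "colon", pulse_duration_us = 100,
    pulse_number = ns,
    ec_n = ec_of_n(2000, 0.012, ns),
    ac_n = ac_of_n(600, -0.004, ns),
    r2 = 1, n_points = 6
  )
  fit <- fit_stage2(s1)
  expect_equal(fit$e0, 2000, tolerance = 1e-6)
  expect_equal(fit$k1, 0.012, tolerance = 1e-6)
  expect_equal(fit$a0, 600, tolerance = 1e-6)
  expect_equal(fit$k2, -0.004, tolerance = 1e-6)
  expect_equal(fit$r2_e, 1, tolerance = 1e-12)
  expect_equal(fit$r2_a, 1, tolerance = 1e-12)

  set.seed(11)
  noisy <- dplyr::mutate(s1, ec_n = ec_n * (1 + rnorm(9, 0, 0.05)))
  fitn <- fit_stage2(noisy)
  expect_lt(abs(fitn$e0 - 2000) / 2000, 0.10)
  expect_lt(abs(fitn$k1 - 0.012) / 0.012, 0.25)

  expect_error(fit_stage2(s1[1:2, ]), class = "ebtsim_insufficient_design")
})

test_that("the orchestrated two-step fit round-trips generated datasets", {
  truth <- truth_row("KYSE-410", 100)
  d <- generate_dataset(generator_config(truth, noise_sd = 0, seed = 3))
  fit <- fit_peleg_fermi(d)
  cf <- tidy(fit)
  expect_equal(cf$e0, truth$e0, tolerance = 1e-3)
  expect_equal(cf$k1, truth$k1, tolerance = 1e-3)
  expect_equal(cf$a0, truth$a0, tolerance = 1e-3)
  expect_equal(cf$k2, truth$k2, tolerance = 1e-2)
  g <- glance(fit)
  expect_equal(g$n_fits, 1L)
  expect_equal(g$n_stage1, 9L)
  expect_equal(g$n_failures, 0L)
})

test_that("the two-step fit tolerates a missing pulse number and flags all-dead data", {
  truth <- truth_row("SW-620", 100)
  d <- generate_dataset(generator_config(truth, noise_sd = 0, seed = 5))
  d_missing <- dplyr::filter(d, pulse_number != 50)
  fit <- fit_peleg_fermi(d_missing)
  expect_equal(nrow(fit$stage1), 8)
  expect_equal(tidy(fit)$e0, truth$e0, tolerance = 1e-3)

  dead <- dplyr::mutate(d, viability_pct = 0)
  expect_error(suppressWarnings(fit_peleg_fermi(dead)),
               class = "ebtsim_fit_failure")
})

test_that("the modified model nests the single exponential and fits double ones", {
  ns <- seq(10, 90, by = 10)
  # data on a single exponential: predictions must match it closely
  s1 <- tibble::tibble(
    cell_line = "PANC-1", organ = "pancreas", pulse_duration_us = 25,
    pulse_number = ns,
    ec_n = ec_of_n(1800, 0.01, ns), ac_n = ac_of_n(500, 0.005, ns),
    r2 = 1, n_points = 6
  )
  mfit <- fit_modified_peleg_fermi(s1)
  pred <- ebtsim:::ec_of_n_modified(mfit$e1, mfit$k1, mfit$e2, mfit$k2, ns)
  expect_equal(pred, s1$ec_n, tolerance = 1e-4)

  # exact double exponential: assert on predictions (terms are exchangeable)
  ec_true <- 1500 * exp(-0.02 * ns) + 800 * exp(-0.002 * ns)
  s2 <- dplyr::mutate(s1, ec_n = ec_true)
  mfit2 <- fit_modified_peleg_fermi(s2)
  pred2 <- ebtsim:::ec_of_n_modified(mfit2$e1, mfit2$k1, mfit2$e2, mfit2$k2, ns)
  expect_equal(pred2, ec_true, tolerance = 1e-6)

  expect_error(fit_modified_peleg_fermi(s1[1:3, ]),
               class = "ebtsim_insufficient_design")
})
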