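test_that("electrical-injury maps apply the effective-field threshold", {
  coeffs <- tibble::tibble(e0 = 2000, k1 = 0.012, a0 = 600, k2 = 0.004)
  n <- 50
  ec <- ec_of_n(coeffs$e0, coeffs$k1, n)
  at_ec <- ei_probability(matrix(ec, 2, 2), coeffs, n)
  expect_equal(at_ec, matrix(0.5, 2, 2))  # boundary included
  expect_equal(ei_probability(matrix(0, 2, 2), coeffs, n), matrix(0, 2, 2))
  high <- ei_probability(matrix(10 * ec, 1, 1), coeffs, n)
  expect_lt(abs(high[1, 1] - 1), 1e-6)
  # consistency with the survival surface above threshold
  e_grid <- seq(ec, 4 * ec, length.out = 20)
  p <- ei_probability(matrix(e_grid, ncol = 1), coeffs, n)
  s <- survival_probability(e_grid, ec, ac_of_n(coeffs$a0, coeffs$k2, n))
  expect_equal(as.numeric(p), 1 - s, tolerance = 1e-12)
})

test_that("area ratios count thresholded cells over non-electrode tissue", {
  p <- matrix(0, 10, 10)
  expect_equal(area_ratio(p), 0)
  expect_equal(area_ratio(p + 1), 1)
  p[1:5, ] <- 1  # exactly half the cells
  expect_equal(area_ratio(p), 0.5)
  excl <- matrix(FALSE, 10, 10)
  excl[1:2, ] <- TRUE  # exclude 20 injured cells from both sides
  expect_equal(area_ratio(p, exclude = excl), 30 / 80)
})

test_that("zero-voltage protocols produce zero injury everywhere", {
  dom <- domain_spec(width = 0.02, height = 0.02, spacing = 5e-4,
                     electrode_gap = 8e-3, electrode_radius = 1e-3)
  prot <- pulse_protocol(voltage = 0, n_pulses_ei = 3, n_pulses_ti = 5)
  res <- run_injury_analysis(truth_row("L-02", 100), domain = dom,
                             protocol = prot)
  expect_true(all(res$series$s_ei_ratio == 0))
  expect_true(all(res$series$s_ti_ratio == 0))
  # only metabolic heat remains: a few millikelvin over 5 s
  expect_lt(max(abs(res$series$peak_T_C - 37)), 0.1)
})

test_that("injury analyses produce bounded, monotone series with held EI tail", {
  dom <- domain_spec(width = 0.02, height = 0.02, spacing = 5e-4,
                     electrode_gap = 8e-3, electrode_radius = 1e-3)
  prot <- pulse_protocol(n_pulses_ei = 10, n_pulses_ti = 15)
  res <- run_injury_analysis(truth_row("QBC-939", 100), domain = dom,
                             protocol = prot)
  ser <- tidy(res)
  expect_equal(nrow(ser), 15)
  expect_true(all(ser$s_ei_ratio >= 0 & ser$s_ei_ratio <= 1))
  expect_true(all(ser$s_ti_ratio >= 0 & ser$s_ti_ratio <= 1))
  expect_true(all(diff(ser$s_ei_ratio) >= -1e-12))
  expect_true(all(diff(ser$s_ti_ratio) >= -1e-12))
  expect_true(all(ser$s_ei_ratio[11:15] == ser$s_ei_ratio[10]))
  expect_true(all(res$p_ei >= 0 & res$p_ei <= 1))
  expect_true(all(res$p_ti >= 0 & res$p_ti < 1))
  g <- glance(res)
  expect_equal(g$cell_line, "QBC-939")
  expect_gte(g$peak_T_C, 37)
})

test_that("area ratios are stable under 2x grid refinement on a smooth map", {
  # cell counting on a smooth analytic probability map: refining the grid
  # changes the ratio only through boundary cells
  ratios <- vapply(c(5e-4, 2.5e-4), function(sp) {
    x <- seq(0, 0.04, by = sp)
    r <- sqrt(outer((x - 0.02)^2, (x - 0.02)^2, `+`))
    p <- 1 / (1 + exp((r - 0.01) / 0.002))
    area_ratio(p)
  }, numeric(1))
  expect_lt(abs(ratios[2] - ratios[1]) / ratios[1], 0.02)
})
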