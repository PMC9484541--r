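test_that("the Fermi sigmoid has its half-kill point at Ec and correct tails", {
  expect_identical(survival_probability(800, 800, 200), 0.5)
  expect_lt(survival_probability(1e9, 500, 100), 1e-12)
  expect_equal(survival_probability(500 - 100, 500, 100), 1 / (1 + exp(-1)))
  expect_error(survival_probability(500, 500, 0),
               class = "ebtsim_invalid_slope")
  # strictly decreasing in field strength, always inside (0, 1)
  e <- seq(0, 5000, by = 50)
  s <- survival_probability(e, 800, 200)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s < 1))
})

test_that("Ec(N) and Ac(N) decay exponentially from their N = 0 amplitudes", {
  expect_identical(ec_of_n(1500, 0.01, 0), 1500)
  expect_identical(ac_of_n(600, -0.004, 0), 600)
  # negative rate constants grow, matching the published negative k2 rows
  expect_gt(ac_of_n(600, -0.004, 100), 600)
  expect_error(ec_of_n(1500, 0.01, -1), class = "ebtsim_domain_error")
})

test_that("published coefficient rows reproduce their printed Ec(100)", {
  # spot values from the coefficient database
  expect_equal(ec_of_n(1862.259, 0.014, 100), 459.227, tolerance = 0.5 / 459)
  expect_equal(ec_of_n(5669.169, 0.042, 100), 85.012, tolerance = 0.5 / 85)
  db <- pf_coefficients(complete_only = TRUE)
  thr <- ec_threshold(db, n = 100)
  expect_true(all(abs(thr$ec_n - thr$ec100_printed) <= 0.5))
  # single-line thresholds used by the simulator
  qbc <- truth_row("QBC-939", 100)
  expect_equal(ec_threshold(qbc, 100)$ec_n, 174.474, tolerance = 0.5 / 174)
  l02 <- truth_row("L-02", 100)
  expect_equal(ec_threshold(l02, 100)$ec_n, 401.307, tolerance = 0.5 / 401)
  mia <- truth_row("MIA PaCa-2", 25)
  expect_equal(ec_threshold(mia, 100)$ec_n, 1328.199, tolerance = 0.5 / 1328)
})

test_that("survival surfaces obey the threshold identity and pulse monotonicity", {
  coeffs <- tibble::tibble(e0 = 2000, k1 = 0.012, a0 = 600, k2 = 0.004)
  ns <- c(1, 10, 50, 100)
  surf <- survival_surface(coeffs, efs = seq(100, 3000, by = 100),
                          pulse_numbers = ns)
  # S(Ec(N), N) = 0.5 exactly for every N
  at_ec <- survival_surface(coeffs, efs = ec_of_n(2000, 0.012, ns)[1], ns[1])
  for (np in ns) {
    s <- survival_probability(ec_of_n(2000, 0.012, np),
                              ec_of_n(2000, 0.012, np),
                              ac_of_n(600, 0.004, np))
    expect_identical(s, 0.5)
  }
  # with positive rates, more pulses never increase survival
  wide <- tidyr::pivot_wider(surf, names_from = "pulse_number",
                             values_from = "survival")
  mat <- as.matrix(wide[, -1])
  expect_true(all(diff(t(mat)) <= 0))
  # rows strictly decreasing in field strength
  expect_true(all(apply(mat, 2, diff) < 0))
  # single-point grid
  one <- survival_surface(coeffs, efs = 500, pulse_numbers = 10)
  expect_equal(nrow(one), 1)
})

test_that("power-law fits are exact on exact data and on two points", {
  tp <- c(0.025, 0.05, 0.075, 0.1)
  exact <- fit_power_law(tp, 500 * tp^(-0.4))
  expect_equal(exact$a, 500, tolerance = 1e-9)
  expect_equal(exact$b, -0.4, tolerance = 1e-9)
  two <- fit_power_law(c(0.025, 0.1), c(1000, 500))
  expect_equal(two$b, -0.5, tolerance = 1e-12)
  expect_equal(two$a, 1000 * sqrt(0.025), tolerance = 1e-9)
  expect_equal(two$a, 158.114, tolerance = 1e-5)
  expect_error(fit_power_law(0.1, 500),
               class = "ebtsim_insufficient_design")
  expect_error(fit_power_law(c(0.025, 0.1), c(-5, 500)),
               class = "ebtsim_domain_error")
})

test_that("coefficient tables carry the canonical columns and computed Ec(100)", {
  db <- pf_coefficients(complete_only = TRUE)
  tab <- coefficient_table(db)
  expect_named(tab, c("organ", "cell_line", "pulse_duration_us", "e0", "k1",
                      "r2_e", "a0", "k2", "r2_a", "ec100"))
  expect_equal(tab$ec100, ec_of_n(tab$e0, tab$k1, 100))
  one <- coefficient_table(db[1, ])
  expect_equal(dim(one), c(1L, 10L))
  empty <- coefficient_table(db[0, ])
  expect_equal(nrow(empty), 0)
  # published esophagus range at 100 us
  eso <- tab[tab$organ == "esophagus" & tab$pulse_duration_us == 100, ]
  expect_equal(trunc(range(eso$ec100)), c(459, 684))
})

test_that("coefficient databases round-trip through JSON", {
  db <- pf_coefficients(complete_only = TRUE)[1:5, ]
  path <- withr::local_tempfile(fileext = ".json")
  write_coefficient_db(db, path)
  back <- read_coefficient_db(path)
  expect_equal(back$e0, db$e0)
  expect_equal(back$k2, db$k2)
  expect_equal(back$cell_line, db$cell_line)
  expect_true(all(back$model == "peleg_fermi"))
})
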