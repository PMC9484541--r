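test_that("noiseless generation reproduces the survival model exactly", {
  truth <- truth_row("SW-480", 100)
  d <- generate_dataset(generator_config(truth, noise_sd = 0, replicates = 2,
                                         seed = 1))
  expected <- 100 * survival_probability(
    d$efs_v_cm,
    ec_of_n(truth$e0, truth$k1, d$pulse_number),
    ac_of_n(truth$a0, truth$k2, d$pulse_number)
  )
  expect_equal(d$viability_pct, expected, tolerance = 1e-12)
})

test_that("generation is deterministic in the seed and never negative", {
  truth <- truth_row("Huh-7", 50)
  cfg <- generator_config(truth, noise_sd = 0.1, seed = 99)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- generate_dataset(generator_config(truth, noise_sd = 0.1, seed = 100))
  expect_false(identical(d1$viability_pct, d3$viability_pct))
  expect_true(all(d1$viability_pct >= 0))
})

test_that("mean viability at Ec(N) converges to 0.5 plus the stimulation term", {
  truth <- truth_row("KYSE-150", 100)
  n_p <- 40
  ec <- ec_of_n(truth$e0, truth$k1, n_p)
  reps <- 1e4
  stim <- list(efs_cutoff = 500, boost = 0.1)
  cfg <- generator_config(truth, efs = ec, pulse_numbers = n_p,
                          replicates = reps, noise_sd = 0.03,
                          stimulation = stim, seed = 8)
  d <- generate_dataset(cfg)
  target <- 0.5 + stim$boost * exp(-ec / stim$efs_cutoff)
  se <- 0.03 / sqrt(reps)
  expect_lt(abs(mean(d$viability_pct) / 100 - target), 3 * se)
})

test_that("stimulation raises low-field viability above 100%", {
  truth <- truth_row("KYSE-150", 25)
  cfg <- generator_config(truth, efs = c(250, 3000), pulse_numbers = 10,
                          noise_sd = 0, stimulation = list(efs_cutoff = 500,
                                                           boost = 0.1),
                          seed = 2)
  d <- generate_dataset(cfg)
  low <- d[d$efs_v_cm == 250, ]
  expect_true(all(low$viability_pct > 100))
  # at IRE-scale fields the stimulation term has decayed to nothing
  plain <- generate_dataset(generator_config(truth, efs = c(250, 3000),
                                             pulse_numbers = 10,
                                             noise_sd = 0, seed = 2))
  delta <- d$viability_pct - plain$viability_pct
  expect_lt(max(delta[d$efs_v_cm == 3000]), 0.05)
  expect_gt(min(delta[d$efs_v_cm == 250]), 5)
})

test_that("OD-form generation inverts the normalisation exactly", {
  truth <- truth_row("GES-1", 100)
  cfg <- generator_config(truth, noise_sd = 0.03, replicates = 2, seed = 13)
  od <- generate_od_dataset(cfg, od_control = 1.1, od_blank = 0.1)
  direct <- generate_dataset(cfg)
  expect_equal(od$od_exp, 0.1 + direct$viability_pct / 100,
               tolerance = 1e-12)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(od, path)
  back <- read_viability(path)
  expect_equal(back$viability_pct, direct$viability_pct, tolerance = 1e-9)
  expect_error(generate_od_dataset(cfg, od_control = 0.1, od_blank = 0.1),
               class = "ebtsim_degenerate_control")
})

test_that("default-design datasets support recovery of the generating truth", {
  truth <- truth_row("SW-480", 100)
  d <- generate_dataset(generator_config(truth, seed = 21))
  fit <- tidy(fit_peleg_fermi(d))
  expect_lt(abs(fit$e0 - truth$e0) / truth$e0, 0.10)
  expect_lt(abs(fit$k1 - truth$k1) / truth$k1, 0.10)
})
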