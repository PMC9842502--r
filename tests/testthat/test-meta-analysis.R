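test_that("log response ratio is the log of the ratio and rejects bad means", {
  expect_equal(log_response_ratio(5, 5), 0)
  expect_equal(log_response_ratio(2, 1), log(2))
  # antisymmetric under swapping treatment and control
  expect_equal(log_response_ratio(3.7, 1.2),
               -log_response_ratio(1.2, 3.7))
  expect_error(log_response_ratio(0, 1), "positive")
  expect_error(log_response_ratio(1, -2), "positive")
  expect_error(log_response_ratio(NA, 1), "positive")
})

test_that("percent change transform and its inverse are consistent", {
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(log(1.25)), 25)
  expect_equal(percent_change(log(0.53)), -47)
  # round trip on (-100, Inf)
  pct <- c(-99, -47, -0.5, 0, 25, 300)
  expect_equal(percent_change(log1p(pct / 100)), pct)
})

test_that("degenerate cells collapse to the point estimate", {
  obs <- tibble::tibble(measure = "EEF", outcome = "yield",
                        mean_treatment = c(11, 22, 5.5),
                        mean_control = c(10, 20, 5))
  est <- bootstrap_effect(obs, n_boot = 99, seed = 1)
  expect_equal(est$mean_pct_change, 10)
  expect_equal(est$ci_low, 10)
  expect_equal(est$ci_high, 10)
  expect_true(est$degenerate)
  expect_true(est$significant) # zero outside the zero-width interval

  one <- bootstrap_effect(obs[1, ], n_boot = 99, seed = 1)
  expect_equal(one$mean_pct_change, 10)
  expect_true(one$degenerate)

  down <- tibble::tibble(measure = "EEF", outcome = "NH3",
                         mean_treatment = 0.8, mean_control = 1)
  est <- bootstrap_effect(down, n_boot = 99, seed = 1)
  expect_equal(est$mean_pct_change, -20)
  expect_true(est$degenerate)

  expect_error(bootstrap_effect(obs[0, ], n_boot = 99, seed = 1),
               "no observations")
  mixed <- dplyr::mutate(obs, outcome = c("yield", "yield", "NUE"))
  expect_error(bootstrap_effect(mixed, n_boot = 99, seed = 1),
               "share one measure")
})

test_that("bootstrap point estimate and CI match an independent oracle", {
  cell <- make_cell(n = 200, log_rr = log(0.7), noise_sd = 0.2, seed = 31)
  est <- bootstrap_effect(cell, n_boot = 999, seed = 77)
  # point estimate near the -30% truth
  se_pct <- 0.2 / sqrt(200) * 100 * 0.7 # delta-method on the pct scale
  expect_lt(abs(est$mean_pct_change - (-30)), 3 * se_pct)

  lnr <- log_response_ratio(cell$mean_treatment, cell$mean_control)
  orc <- oracle_bootstrap(lnr, n_boot = 999, seed = 77)
  expect_equal(est$mean_pct_change, orc$mean_pct, tolerance = 1e-12)
  expect_equal(c(est$ci_low, est$ci_high), orc$ci_pct, tolerance = 1e-12)

  est_p <- bootstrap_effect(cell, n_boot = 999, seed = 77,
                            ci_type = "percentile")
  orc_p <- oracle_bootstrap(lnr, n_boot = 999, seed = 77,
                            type = "percentile")
  expect_equal(c(est_p$ci_low, est_p$ci_high), orc_p$ci_pct,
               tolerance = 1e-12)
})

test_that("estimates are invariant to row order and unit rescaling", {
  cell <- make_cell(n = 60, log_rr = log(0.8), noise_sd = 0.25, seed = 5)
  est <- bootstrap_effect(cell, n_boot = 499, seed = 9)
  shuffled <- cell[withr::with_seed(1, sample.int(nrow(cell))), ]
  expect_equal(bootstrap_effect(shuffled, n_boot = 499, seed = 9), est)
  rescaled <- dplyr::mutate(cell,
                            mean_treatment = mean_treatment * 1000,
                            mean_control = mean_control * 1000)
  expect_equal(bootstrap_effect(rescaled, n_boot = 499, seed = 9), est)
})

test_that("effect_table yields one row per populated cell, deterministically", {
  obs <- dplyr::bind_rows(
    make_cell(5, log(0.8), 0.1, 1, "EEF", "NH3"),
    make_cell(5, log(0.8), 0.1, 2, "EEF", "yield"),
    make_cell(5, log(0.8), 0.1, 3, "EEF", "NUE"),
    make_cell(5, log(0.8), 0.1, 4, "tillage", "NH3"),
    make_cell(5, log(0.8), 0.1, 5, "tillage", "yield"),
    make_cell(5, log(0.8), 0.1, 6, "tillage", "NUE")
  )
  eff <- effect_table(obs, n_boot = 199, seed = 3)
  expect_equal(nrow(eff), 6)
  expect_identical(effect_table(obs, n_boot = 199, seed = 3), eff)

  cfg <- synth_config(seed = 12, n_obs_per_cell = 2)
  full <- effect_table(generate_observations(cfg), n_boot = 49, seed = 1)
  expect_equal(nrow(full), 88) # 11 measures x 8 outcomes
})

test_that("non-positive means are excluded with a warning", {
  obs <- make_cell(5, log(0.8), 0.1, 1)
  obs$mean_control[2] <- 0
  expect_warning(v <- validate_observations(obs), "excluded")
  expect_equal(nrow(v), 4)
  expect_equal(nrow(attr(v, "rejected")), 1)
  expect_error(validate_observations(dplyr::mutate(obs, outcome = "xx")),
               "unknown outcome")
})

test_that("efficacies derive from percentage changes with clipping", {
  eff <- tibble::tibble(
    measure = "EEF",
    outcome = c("NH3", "NOx", "N2O", "leaching", "runoff", "yield", "NUE"),
    mean_pct_change = c(-47, 10, -30, -50, -20, 25, 18)
  )
  spec <- efficacy_from_effects(eff)
  expect_equal(spec$eta_NH3, 0.47)
  expect_equal(spec$eta_NOx, 0) # pollution-increasing effect clipped
  expect_equal(spec$eta_leaching, 0.5)
  expect_equal(spec$yield_multiplier, 1.25)
  expect_equal(spec$nue_multiplier, 1.18)
  expect_equal(spec$tier, 1L)
  tr <- attr(spec, "tradeoffs")
  expect_equal(tr$outcome, "NOx")

  # a missing pathway defaults to zero efficacy with a warning
  expect_warning(spec2 <- efficacy_from_effects(eff[-4, ]), "efficacy set to 0")
  expect_equal(spec2$eta_leaching, 0)
})
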