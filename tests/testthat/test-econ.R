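test_that("implementation cost converts kt at USD/kg into USD exactly", {
  expect_equal(implementation_cost(1, 2), 2e6)
  expect_equal(implementation_cost(0, 2), 0)
  expect_error(implementation_cost(-1, 2), "delta_e")
  expect_error(implementation_cost(1, NA_real_), "missing")
})

test_that("ecosystem benefit applies the WTP and PGDP transfer ratios", {
  ec <- toy_econ()
  red_us <- tibble::tibble(region = "USA",
                           pathway = pathway_vocabulary(),
                           delta_e = c(1, 0, 0, 0, 0))
  # reference region: both ratios exactly 1 -> delta_e x unit cost
  expect_equal(ecosystem_benefit(red_us, ec)$eh, 1e6 * 10)

  # non-reference region: wtp ratio 0.5 and pgdp ratio 0.5
  red_t <- dplyr::mutate(red_us, region = "T")
  expect_equal(ecosystem_benefit(red_t, ec)$eh, 1e6 * 10 * 0.5 * 0.5)

  # linear in the reduction
  expect_equal(ecosystem_benefit(dplyr::mutate(red_t, delta_e = delta_e * 2),
                                 ec)$eh,
               2 * ecosystem_benefit(red_t, ec)$eh)

  no_ref <- ec
  no_ref$regions <- no_ref$regions[no_ref$regions$region != "USA", ]
  expect_error(ecosystem_benefit(red_t, no_ref), "reference region")
})

test_that("health benefit sums reductions times unit health costs", {
  ec <- toy_econ()
  red <- tibble::tibble(region = "T", pathway = "NH3", delta_e = 2)
  expect_equal(health_benefit(red, ec)$hh, 2e6 * 20)
  ec0 <- ec
  ec0$damage$hcost <- 0
  expect_equal(health_benefit(red, ec0)$hh, 0)
  expect_equal(health_benefit(dplyr::mutate(red, delta_e = 6), ec)$hh,
               3 * health_benefit(dplyr::mutate(red, delta_e = 2), ec)$hh)
})

test_that("yield benefit is signed", {
  expect_equal(yield_benefit(0, 3), 0)
  expect_equal(yield_benefit(1, 3), 3e6)
  expect_lt(yield_benefit(-1, 3), 0) # monetized cost of a yield loss
})

test_that("climate benefit keeps the sign convention per loss form", {
  ec <- toy_econ()
  n2o <- tibble::tibble(region = "T", pathway = "N2O", delta_e = 1)
  expect_gt(climate_benefit(n2o, ec)$ghg, 0)
  nh3 <- tibble::tibble(region = "T", pathway = "NH3", delta_e = 1)
  expect_lt(climate_benefit(nh3, ec)$ghg, 0) # cooling-aerosol penalty
  zero <- dplyr::mutate(nh3, delta_e = 0)
  expect_equal(climate_benefit(zero, ec)$ghg, 0)
})

test_that("societal benefit is the exact component sum", {
  expect_equal(societal_benefit(196, 130, 152, -2), 476)
  expect_equal(societal_benefit(0, 0, 0, 0), 0)
  expect_equal(societal_benefit(130, 196, -2, 152), 476) # permutation
})

test_that("fertilizer saving and the net-cost identity", {
  expect_equal(fertilizer_saving(0, 0.9), 0)
  expect_equal(fertilizer_saving(1, 0.9), 0.9e6)

  # on a worked fixture: net cost = ic - saving, soc = sum of components
  b <- toy_budget()
  m <- toy_measure()
  ad <- tibble::tibble(region = "T", measure = "EEF", X = 0.5)
  comb <- combine_measures(b, m, ad)
  post <- apply_mitigation(b, comb)
  cba <- cost_benefit(comb$reductions, attr(post, "deltas"), toy_econ())
  expect_equal(cba$net_cost, cba$ic - cba$fertilizer_saving)
  expect_equal(cba$soc, cba$eh + cba$hh + cba$yd + cba$ghg)
  glob <- cba[cba$region == "GLOBAL", ]
  reg <- cba[cba$region != "GLOBAL", ]
  for (f in c("ic", "fertilizer_saving", "net_cost", "soc")) {
    expect_equal(glob[[f]], sum(reg[[f]]), info = f)
  }
  # implementation cost recomputed from first principles
  expect_equal(glob$ic, sum(comb$reductions$delta_e) * 1e6 * 2)
})

test_that("Monte-Carlo propagation is degenerate at zero spread and seeded", {
  cfg <- synth_config(seed = 51, n_regions = 3)
  w <- assessment_world(generate_budgets(cfg), generate_measures(cfg),
                        generate_adoption(cfg), generate_econ_params(cfg),
                        targets = generate_targets(generate_budgets(cfg)))
  res0 <- propagate_uncertainty(w, n_draws = 10, seed = 1, eta_sd = 0,
                                price_rel_sd = 0)
  glob <- res0$summary[res0$summary$region == "GLOBAL", ]
  expect_equal(glob$soc_sd, 0)
  expect_equal(glob$net_cost_sd, 0)
  point <- res0$point[res0$point$region == "GLOBAL", ]
  expect_equal(glob$soc_mean, point$soc)
  expect_equal(glob$ic_mean, point$ic)

  res1 <- propagate_uncertainty(w, n_draws = 25, seed = 9)
  res2 <- propagate_uncertainty(w, n_draws = 25, seed = 9)
  expect_identical(res1$summary, res2$summary)
  expect_error(propagate_uncertainty(w, n_draws = 1, seed = 1), "n_draws")

  # component sum holds in every single draw
  expect_equal(res1$draws$soc,
               res1$draws$eh + res1$draws$hh + res1$draws$yd +
                 res1$draws$ghg)
})

test_that("the error of the Monte-Carlo mean shrinks with the draw count", {
  cfg <- synth_config(seed = 61, n_regions = 2)
  b <- generate_budgets(cfg)
  w <- assessment_world(b, generate_measures(cfg), generate_adoption(cfg),
                        generate_econ_params(cfg),
                        targets = generate_targets(b))
  draws_at <- function(n, seed) {
    propagate_uncertainty(w, n_draws = n, seed = seed)$draws$soc
  }
  d_small <- draws_at(100, 3)
  d_large <- draws_at(400, 4)
  # the draw spread is a stable property of the inputs, so the standard
  # error of the mean scales as 1/sqrt(n_draws)
  expect_lt(abs(stats::sd(d_small) - stats::sd(d_large)) /
              stats::sd(d_large), 0.5)
  se_ratio <- (stats::sd(d_small) / sqrt(100)) /
    (stats::sd(d_large) / sqrt(400))
  expect_gt(se_ratio, 1.4)
  expect_lt(se_ratio, 2.9)
})
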