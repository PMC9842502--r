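test_that("the abatement identity is an exact product with zero baseline at X = 0", {
  act <- tibble::tibble(region = "T", pathway = "NH3", activity = 100,
                        unit = "ktN", emission_factor = 0.1,
                        ef_per = "ktN")
  m <- toy_measure(eta = c(NH3 = 0.47))
  expect_equal(
    emission_reduction(act, m, tibble::tibble(region = "T",
                                              measure = "EEF", X = 0.5))$delta_e,
    2.35)
  expect_equal(
    emission_reduction(act, m, tibble::tibble(region = "T",
                                              measure = "EEF", X = 0))$delta_e,
    0)
  full <- emission_reduction(act, toy_measure(eta = c(NH3 = 1)),
                             tibble::tibble(region = "T", measure = "EEF",
                                            X = 1))
  expect_equal(full$delta_e, 100 * 0.1) # the whole baseline flux

  bad <- dplyr::mutate(act, ef_per = "kha")
  expect_error(emission_reduction(bad, m,
                                  tibble::tibble(region = "T",
                                                 measure = "EEF", X = 1)),
               "unit")
})

test_that("activity/EF decomposition reproduces baseline fluxes", {
  b <- generate_budgets(synth_config(seed = 23, n_regions = 3))
  for (basis in c("input", "fertilizer", "area")) {
    act <- activity_from_budget(b, basis)
    flux <- act$activity * act$emission_factor
    cols <- c(NH3 = "e_nh3", NOx = "e_nox", N2O = "e_n2o",
              leaching = "n_leach", runoff = "n_runoff")
    want <- vapply(seq_len(nrow(act)), function(i) {
      b[[cols[[act$pathway[i]]]]][match(act$region[i], b$region)]
    }, numeric(1))
    expect_equal(flux, want, tolerance = 1e-12, info = basis)
  }
})

test_that("a single non-interacting measure passes through combine_measures", {
  b <- toy_budget()
  m <- toy_measure()
  ad <- tibble::tibble(region = "T", measure = "EEF", X = 0.5)
  comb <- combine_measures(b, m, ad)
  # eta * X on each pathway
  expect_equal(comb$reductions$frac,
               c(0.4, 0.2, 0.3, 0.5, 0.1) * 0.5)
  expect_equal(comb$reductions$delta_e,
               c(15, 2, 3, 12, 8) * c(0.4, 0.2, 0.3, 0.5, 0.1) * 0.5)
  expect_equal(comb$selected$measure, "EEF")
})

test_that("disjoint-pathway measures combine additively", {
  b <- toy_budget()
  m <- dplyr::bind_rows(
    toy_measure("EEF", eta = c(NH3 = 0.4, NOx = 0, N2O = 0,
                               leaching = 0, runoff = 0)),
    toy_measure("buffer_zone", eta = c(NH3 = 0, NOx = 0, N2O = 0,
                                       leaching = 0.6, runoff = 0.3))
  )
  ad <- tibble::tibble(region = "T", measure = c("EEF", "buffer_zone"),
                       X = c(0.5, 1))
  comb <- combine_measures(b, m, ad)
  red <- comb$reductions
  expect_equal(red$delta_e[red$pathway == "NH3"], 15 * 0.4 * 0.5)
  expect_equal(red$delta_e[red$pathway == "leaching"], 12 * 0.6)
  expect_equal(red$delta_e[red$pathway == "runoff"], 8 * 0.3)
  expect_equal(red$delta_e[red$pathway == "N2O"], 0)
})

test_that("combine_measures matches the brute-force oracle with interactions and a target", {
  pw <- pathway_vocabulary()
  b <- toy_budget()
  inter <- interaction_template()
  inter[1, c("measure_a", "measure_b")] <- list("EEF", "fertilizer_rate")
  inter[1, paste0("eta_", pw)] <- as.list(c(0.55, 0.3, 0.4, 0.5, 0.2))

  worlds <- list(
    list(ms = c("EEF", "fertilizer_rate", "tillage"),
         x = c(0.6, 0.8, 0.5), target = 0.58),
    list(ms = c("EEF", "fertilizer_rate", "tillage", "irrigation"),
         x = c(0.9, 0.9, 0.9, 0.9), target = 0.95),
    list(ms = c("EEF", "tillage"), x = c(0.4, 0.4), target = 0.50)
  )
  for (w in worlds) {
    measures <- dplyr::bind_rows(lapply(seq_along(w$ms), function(i) {
      toy_measure(w$ms[i], tier = measure_catalogue()$tier[
        measure_catalogue()$measure == w$ms[i]],
        eta = stats::setNames(c(0.4, 0.2, 0.3, 0.5, 0.1) *
                                (0.6 + 0.2 * i), pw),
        yield_multiplier = 1 + 0.05 * i)
    }))
    ad <- tibble::tibble(region = "T", measure = w$ms, X = w$x)
    tg <- tibble::tibble(region = "T", nue_target = w$target,
                         target_harvest = 70)
    comb <- combine_measures(b, measures, ad, inter, tg)

    # oracle: rank candidates by tier then standalone reduction, take the
    # shortest prefix reaching the target NUE
    x <- as.list(stats::setNames(w$x, w$ms))
    cols <- c(NH3 = "e_nh3", NOx = "e_nox", N2O = "e_n2o",
              leaching = "n_leach", runoff = "n_runoff")
    standalone <- vapply(w$ms, function(m) {
      sum(vapply(pw, function(p) {
        b[[cols[[p]]]] * measures[[paste0("eta_", p)]][
          measures$measure == m] * x[[m]]
      }, numeric(1)))
    }, numeric(1))
    tiers <- measures$tier[match(w$ms, measures$measure)]
    order_ms <- w$ms[order(tiers, -standalone)]
    sel <- character()
    for (m in order_ms) {
      if (oracle_post_nue(b, sel, measures, x, inter, 70) >= w$target) break
      sel <- c(sel, m)
    }
    expect_equal(comb$selected$measure, sel)
    want_frac <- vapply(pw, function(p) {
      oracle_fraction(sel, measures, x, inter, p)
    }, numeric(1))
    expect_equal(comb$reductions$frac, unname(want_frac))
    expect_equal(comb$reductions$delta_e,
                 unname(want_frac) * c(15, 2, 3, 12, 8))
  }
})

test_that("unknown measures in the interaction table are rejected", {
  inter <- interaction_template()
  inter[1, c("measure_a", "measure_b")] <- list("EEF", "nonsense")
  inter[1, paste0("eta_", pathway_vocabulary())] <- as.list(rep(0.5, 5))
  expect_error(
    combine_measures(toy_budget(), toy_measure(),
                     tibble::tibble(region = "T", measure = "EEF", X = 1),
                     inter),
    "unknown measure")
})

test_that("fertilizer reduction follows the identity with both clamp modes", {
  b <- toy_budget() # n_fer 60
  expect_equal(fertilizer_reduction(b, 18, 11, 5), 24)
  expect_equal(fertilizer_reduction(b, 0, 0, 0), 0)

  b$n_fer <- 10
  expect_equal(fertilizer_reduction(b, 18, 11, 5), 10)          # capped
  expect_equal(fertilizer_reduction(b, 18, 11, 5, strict = TRUE), 0)
  # a negative reduction (region should increase input) passes through
  expect_equal(fertilizer_reduction(b, -20, 0, 0), -20)
})

test_that("deposition feedback is proportional with a sensible default fraction", {
  expect_equal(deposition_feedback(10, 0.5), 5)
  expect_equal(deposition_feedback(10, 0), 0)
  expect_error(deposition_feedback(10, 1.5), "fraction")
  b <- toy_budget() # dep 8, gases 20 -> fraction 0.4
  expect_equal(deposition_feedback(10, budgets = b), 4)
})

test_that("manure recycling respects production potential and carrying capacity", {
  b <- toy_budget() # n_man 20; default baseline ratio 0.5 -> production 40
  expect_equal(manure_recycling_adjustment(b, 0.5), 0)
  expect_equal(manure_recycling_adjustment(b, 0.8), 0.8 * 40 - 20)
  expect_equal(manure_recycling_adjustment(b, 1, carrying_capacity = 25), 5)
  expect_equal(manure_recycling_adjustment(b, 0.2), 0) # floored
  expect_equal(manure_recycling_adjustment(b, 0.2, allow_decrease = TRUE),
               0.2 * 40 - 20)
  expect_error(manure_recycling_adjustment(b, 0.5, carrying_capacity = -1),
               "carrying_capacity")
})

test_that("apply_mitigation is the identity under zero adoption", {
  b <- generate_budgets(synth_config(seed = 31, n_regions = 3))
  m <- generate_measures(synth_config(seed = 31))
  ad <- generate_adoption(synth_config(seed = 31, n_regions = 3))
  ad$X <- 0
  comb <- combine_measures(b, m, ad)
  post <- apply_mitigation(b, comb)
  expect_equal(post[names(b)], b, ignore_attr = TRUE)
  d <- attr(post, "deltas")
  expect_equal(d$delta_fer, rep(0, 3))
  expect_equal(d$nr_emission_reduction, rep(0, 3))
})

test_that("full efficacy at full adoption removes all reactive losses", {
  b <- toy_budget()
  m <- toy_measure(eta = stats::setNames(rep(1, 5), pathway_vocabulary()),
                   yield_multiplier = 1)
  ad <- tibble::tibble(region = "T", measure = "EEF", X = 1)
  post <- apply_mitigation(b, combine_measures(b, m, ad))
  expect_equal(post$e_nh3 + post$e_nox + post$e_n2o +
                 post$n_leach + post$n_runoff, 0)
  expect_equal(post$e_n2, 0) # gaseous fraction reduction is 1
})

test_that("the one-region chain matches the hand-computed fixture", {
  b <- toy_budget()
  m <- toy_measure()
  ad <- tibble::tibble(region = "T", measure = "EEF", X = 0.5)
  post <- apply_mitigation(b, combine_measures(b, m, ad))
  d <- attr(post, "deltas")

  # hand-worked: fractions eta*X, gas reduction 3.65 of 20, dep ratio 0.4
  expect_equal(post$e_nh3, 12)
  expect_equal(post$e_nox, 1.8)
  expect_equal(post$e_n2o, 2.55)
  expect_equal(post$n_leach, 9)
  expect_equal(post$n_runoff, 7.6)
  expect_equal(post$e_n2, 10 * (1 - 3.65 / 20))
  expect_equal(post$n_harvest, 52.5)
  expect_equal(d$delta_input, 100 - 93.625)
  expect_equal(d$delta_dep, 0.4 * 3.65)
  expect_equal(d$delta_fer, 6.375 - 1.46)
  expect_equal(post$n_fer, 60 - 4.915)
  # post budget still closes and NUE improved
  expect_equal(total_input(post), total_output(post), tolerance = 1e-12)
  expect_gt(nue(post), nue(b))
})

test_that("post-mitigation budgets keep all invariants on synthetic worlds", {
  cfg <- synth_config(seed = 41, n_regions = 8)
  b <- generate_budgets(cfg)
  m <- generate_measures(cfg)
  ad <- generate_adoption(cfg)
  tg <- generate_targets(b)
  comb <- combine_measures(b, m, ad, targets = tg)
  post <- apply_mitigation(b, comb, targets = tg)
  d <- attr(post, "deltas")

  flux_cols <- setdiff(names(post), c("region", "year"))
  expect_true(all(as.matrix(post[flux_cols]) >= 0))
  # no pathway reduction exceeds its baseline
  expect_true(all(comb$reductions$delta_e <=
                    comb$reductions$baseline + 1e-12))
  # reduction identity where the clamp did not bind
  free <- !d$fer_clamped
  expect_equal(d$delta_fer[free],
               (d$delta_input + d$delta_man - d$delta_dep)[free])
  # NUE does not fall when harvest rises and input falls
  improved <- post$n_harvest >= b$n_harvest &
    total_input(post) <= total_input(b)
  expect_true(all(nue(post)[improved] >= nue(b)[improved] - 1e-12))
})
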