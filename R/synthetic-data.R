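#' Configure the synthetic-data generator
#'
#' Builds a validated configuration for generating the five input table
#' families (field observations, regional nitrogen budgets, measure
#' efficacies, adoption rates and economic parameters) with known ground
#' truth. One root seed fully determines every generated table, so any
#' downstream result can be regenerated bit-identically.
#'
#' @param seed Integer root seed; every generator stage derives its own
#'   stream from it.
#' @param n_studies Number of synthetic source studies the observations are
#'   attributed to.
#' @param n_obs_per_cell Observations generated per measure-by-outcome cell.
#' @param true_effect Tibble with columns `measure`, `outcome`, `log_rr`
#'   giving the true mean log response ratio of each cell. Defaults to
#'   [default_true_effects()].
#' @param obs_noise_sd Standard deviation of the Gaussian noise added to the
#'   log response ratio of each observation. Noise is Gaussian on the log
#'   scale (i.e. lognormal multiplicative on the means) so that generated
#'   means stay strictly positive.
#' @param n_regions Number of world regions; the first region is always
#'   `"USA"`, the willingness-to-pay and per-capita-GDP reference.
#' @param budget_scale Total cropland N input of each region (kt N/yr).
#' @param price_scale Multiplier applied to all unit costs and prices.
#' @param nue_range Length-2 numeric range the regional nitrogen use
#'   efficiencies are drawn from.
#' @param control_median Median of the lognormal distribution the control
#'   means are drawn from (flux or yield units).
#'
#' @return A list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(seed = 1, n_regions = 4)
#' obs <- generate_observations(cfg)
synth_config <- function(seed = 42L,
                         n_studies = 120L,
                         n_obs_per_cell = 17L,
                         true_effect = default_true_effects(),
                         obs_noise_sd = 0.3,
                         n_regions = 8L,
                         budget_scale = 1000,
                         price_scale = 1,
                         nue_range = c(0.2, 0.8),
                         control_median = 50) {
  assert_scalar_number(seed, "seed")
  assert_scalar_number(n_studies, "n_studies", min = 1)
  assert_scalar_number(n_obs_per_cell, "n_obs_per_cell", min = 1)
  assert_scalar_number(obs_noise_sd, "obs_noise_sd", min = 0)
  assert_scalar_number(n_regions, "n_regions", min = 1)
  assert_scalar_number(budget_scale, "budget_scale", min = 0, strict_min = TRUE)
  assert_scalar_number(price_scale, "price_scale", min = 0, strict_min = TRUE)
  assert_scalar_number(control_median, "control_median", min = 0,
                       strict_min = TRUE)
  if (length(nue_range) != 2L || any(nue_range <= 0) || any(nue_range > 1) ||
      nue_range[1] > nue_range[2]) {
    stop("`nue_range` must be an increasing pair within (0, 1]", call. = FALSE)
  }
  stopifnot(is.data.frame(true_effect),
            all(c("measure", "outcome", "log_rr") %in% names(true_effect)))
  bad <- setdiff(true_effect$measure, MEASURES)
  if (length(bad)) stop("unknown measure(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(true_effect$outcome, OUTCOMES)
  if (length(bad)) stop("unknown outcome(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)

  structure(list(
    seed = as.integer(seed),
    n_studies = as.integer(n_studies),
    n_obs_per_cell = as.integer(n_obs_per_cell),
    true_effect = tibble::as_tibble(true_effect),
    obs_noise_sd = obs_noise_sd,
    n_regions = as.integer(n_regions),
    budget_scale = budget_scale,
    price_scale = price_scale,
    nue_range = as.numeric(nue_range),
    control_median = control_median
  ), class = "synth_config")
}

#' Default true effects for the synthetic meta-database
#'
#' Fixed ground-truth log response ratios for every measure-by-outcome cell,
#' chosen inside the ranges field trials typically report: loss pathways
#' reduced by roughly 30-70%, yield increased by up to 30% and NUE by
#' 10-80%. Enhanced-efficiency fertilizers are pinned at a 47% total-loss
#' reduction, +25% yield and +18% NUE.
#'
#' @return Tibble with columns `measure`, `outcome`, `log_rr`.
#' @export
default_true_effects <- function() {
  # per-measure percentage change of total N loss (negative = reduction),
  # yield and NUE; per-pathway deviations around the total-loss effect
  loss_pct <- c(
    EEF = -47, organic_amendment = -30, legume_rotation = -35,
    buffer_zone = -45, fertilizer_rate = -40, fertilizer_type = -30,
    fertilizer_timing = -35, fertilizer_placement = -50,
    new_cultivar = -30, tillage = -30, irrigation = -45
  )
  yield_pct <- c(
    EEF = 25, organic_amendment = 15, legume_rotation = 12,
    buffer_zone = 5, fertilizer_rate = 10, fertilizer_type = 12,
    fertilizer_timing = 15, fertilizer_placement = 20,
    new_cultivar = 30, tillage = 8, irrigation = 18
  )
  nue_pct <- c(
    EEF = 18, organic_amendment = 15, legume_rotation = 20,
    buffer_zone = 10, fertilizer_rate = 40, fertilizer_type = 15,
    fertilizer_timing = 25, fertilizer_placement = 35,
    new_cultivar = 50, tillage = 10, irrigation = 30
  )
  pathway_shift <- c(NH3 = 1.10, NOx = 0.90, N2O = 1.00,
                     leaching = 1.00, runoff = 0.95)

  grid <- tidyr::expand_grid(measure = MEASURES, outcome = OUTCOMES)
  grid$log_rr <- vapply(seq_len(nrow(grid)), function(i) {
    m <- grid$measure[i]
    o <- grid$outcome[i]
    pct <- switch(o,
      yield = yield_pct[[m]],
      NUE = nue_pct[[m]],
      total_N_loss = loss_pct[[m]],
      # pathway: scaled deviation, kept above -95%
      max(loss_pct[[m]] * pathway_shift[[o]], -95)
    )
    log1p(pct / 100)
  }, numeric(1))
  grid
}

region_labels <- function(n_regions) {
  c("USA", sprintf("R%02d", seq_len(max(n_regions - 1L, 0L)) + 1L))
}

#' Generate a synthetic field-observation table
#'
#' Emulates a meta-database of control/treatment contrasts: for each
#' measure-by-outcome cell with a configured true effect, control means are
#' drawn lognormal and treatment means are the control means times
#' `exp(true_effect + noise)`, so every generated mean is strictly positive
#' and the per-cell mean log response ratio converges to the configured
#' truth.
#'
#' @param config A [synth_config()].
#' @return Tibble with columns `study_id`, `measure`, `sub_treatment`,
#'   `outcome`, `mean_treatment`, `mean_control`, `region`.
#' @export
generate_observations <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cells <- config$true_effect
  n <- config$n_obs_per_cell
  regions <- region_labels(config$n_regions)

  withr::with_seed(stage_seed(config$seed, "observations"), {
    out <- purrr::pmap_dfr(cells, function(measure, outcome, log_rr) {
      ctrl <- stats::rlnorm(n, meanlog = log(config$control_median),
                            sdlog = 0.5)
      noise <- if (config$obs_noise_sd > 0) {
        stats::rnorm(n, 0, config$obs_noise_sd)
      } else {
        rep(0, n)
      }
      tibble::tibble(
        study_id = sprintf("S%03d", sample.int(config$n_studies, n,
                                               replace = TRUE)),
        measure = measure,
        sub_treatment = "default",
        outcome = outcome,
        mean_treatment = ctrl * exp(log_rr + noise),
        mean_control = ctrl,
        region = sample(regions, n, replace = TRUE)
      )
    })
  })
  out
}

#' Generate synthetic regional cropland nitrogen budgets
#'
#' Each region receives a total N input equal to `budget_scale`, an NUE
#' drawn uniformly from `nue_range`, and a split of the remaining surplus
#' across the gaseous, leaching and runoff loss pathways. Budgets close
#' exactly by construction: total input equals harvest plus all losses
#' (soil N stock change is fixed at zero by convention).
#'
#' @param config A [synth_config()].
#' @param year Budget year label (default 2015).
#' @return Tibble with one row per region: the five input fluxes, harvest,
#'   four gaseous emissions, leaching, runoff (all kt N/yr) and cropland
#'   `area` (kha).
#' @export
generate_budgets <- function(config, year = 2015L) {
  stopifnot(inherits(config, "synth_config"))
  regions <- region_labels(config$n_regions)
  total <- config$budget_scale

  withr::with_seed(stage_seed(config$seed, "budgets"), {
    purrr::map_dfr(regions, function(r) {
      nue <- stats::runif(1, config$nue_range[1], config$nue_range[2])
      harvest <- nue * total
      loss <- total - harvest
      # loss split: gamma weights keep all shares strictly positive
      w <- stats::rgamma(6, shape = c(3, 1, 1, 2.5, 2.5, 2))
      w <- w / sum(w)
      # input split, fertilizer dominant
      v <- stats::rgamma(5, shape = c(10, 4, 3, 2, 1))
      v <- v / sum(v)
      intensity <- stats::runif(1, 0.05, 0.15) # kt N per kha (50-150 kg/ha)
      tibble::tibble(
        region = r, year = as.integer(year),
        n_fer = v[1] * total, n_man = v[2] * total, n_fix = v[3] * total,
        n_dep = v[4] * total, n_irr = v[5] * total,
        n_harvest = harvest,
        e_nh3 = w[1] * loss, e_n2o = w[2] * loss, e_nox = w[3] * loss,
        e_n2 = w[4] * loss,
        n_leach = w[5] * loss, n_runoff = w[6] * loss,
        area = total / intensity
      )
    })
  })
}

#' Generate synthetic economic parameter tables
#'
#' Produces regional unit abatement costs, US-reference unit ecosystem
#' damage costs per loss form, willingness-to-pay and per-capita GDP (with
#' `"USA"` as the reference region, ratios exactly 1), per-region health
#' damage costs, signed climate damage costs (negative for NH3 and NOx,
#' whose reduction removes a cooling aerosol effect), crop prices and
#' fertilizer prices. All monetary values scale with `price_scale` and are
#' in constant 2017 USD per kg N.
#'
#' @param config A [synth_config()].
#' @return A list of class `econ_params` with elements `regions` (per-region
#'   scalars), `damage` (per region and pathway `hcost`, `ccost`),
#'   `eco_unit_cost` (per pathway, US reference) and `reference_region`.
#' @export
generate_econ_params <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  regions <- region_labels(config$n_regions)
  ps <- config$price_scale

  withr::with_seed(stage_seed(config$seed, "econ"), {
    pgdp_us <- 60000
    wtp_us <- 100
    reg <- tibble::tibble(
      region = regions,
      uc = ps * stats::rlnorm(length(regions), log(2), 0.3),
      wtp = c(wtp_us, wtp_us * stats::runif(length(regions) - 1L, 0.2, 0.9)),
      pgdp = c(pgdp_us,
               pgdp_us * stats::runif(length(regions) - 1L, 0.1, 0.8)),
      crop_price = ps * stats::rlnorm(length(regions), log(3), 0.2),
      fertilizer_price = ps * stats::rlnorm(length(regions), log(1), 0.15)
    )
    # US-reference ecosystem damage cost per kg N by loss form
    eco <- tibble::tibble(
      pathway = PATHWAYS,
      cost = ps * c(10, 12, 4, 8, 8) * stats::rlnorm(5, 0, 0.1)
    )
    dmg <- tidyr::expand_grid(region = regions, pathway = PATHWAYS)
    base_h <- c(NH3 = 20, NOx = 15, N2O = 1, leaching = 2, runoff = 2)
    base_c <- c(NH3 = -2, NOx = -1.5, N2O = 12, leaching = 0, runoff = 0)
    jitter <- stats::rlnorm(nrow(dmg), 0, 0.1)
    dmg$hcost <- ps * base_h[dmg$pathway] * jitter *
      reg$pgdp[match(dmg$region, reg$region)] / pgdp_us
    dmg$ccost <- ps * base_c[dmg$pathway]
  })

  structure(list(
    regions = reg,
    damage = dmg,
    eco_unit_cost = eco,
    reference_region = "USA"
  ), class = "econ_params")
}

#' Generate measure specifications from the configured true effects
#'
#' Converts the generator's ground-truth log response ratios into the
#' per-pathway abatement efficacies, yield multipliers and NUE multipliers
#' that the mitigation stage consumes: a cell with true log ratio
#' `log(0.53)` on a loss pathway yields an efficacy of 0.47. Efficacies are
#' clipped to [0, 1]; pollution-increasing true effects give 0.
#'
#' @param config A [synth_config()].
#' @return Tibble with one row per measure: `measure`, `tier`, `eta_NH3`
#'   ... `eta_runoff`, `yield_multiplier`, `nue_multiplier`.
#' @export
generate_measures <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  te <- config$true_effect
  wide <- tidyr::pivot_wider(te, names_from = "outcome",
                             values_from = "log_rr")
  out <- tibble::tibble(
    measure = wide$measure,
    tier = unname(MEASURE_TIERS[wide$measure])
  )
  for (p in PATHWAYS) {
    lr <- if (p %in% names(wide)) wide[[p]] else rep(NA_real_, nrow(wide))
    out[[paste0("eta_", p)]] <- pmin(pmax(-expm1(ifelse(is.na(lr), 0, lr)),
                                          0), 1)
  }
  out$yield_multiplier <- exp(wide$yield %||% rep(0, nrow(wide)))
  out$nue_multiplier <- exp(wide$NUE %||% rep(0, nrow(wide)))
  out
}

#' Generate synthetic per-region adoption rates
#'
#' @param config A [synth_config()].
#' @param x_range Range the implementation rates are drawn from.
#' @return Tibble with columns `region`, `measure`, `X` (fraction in
#'   \[0, 1\]).
#' @export
generate_adoption <- function(config, x_range = c(0.3, 0.9)) {
  stopifnot(inherits(config, "synth_config"))
  grid <- tidyr::expand_grid(region = region_labels(config$n_regions),
                             measure = MEASURES)
  withr::with_seed(stage_seed(config$seed, "adoption"), {
    grid$X <- stats::runif(nrow(grid), x_range[1], x_range[2])
  })
  grid
}

#' Derive NUE targets and harvest targets from baseline budgets
#'
#' Targets represent what current best technology and management could
#' achieve: the NUE target raises each region's baseline NUE by
#' `nue_uplift` percentage points (capped), and the harvest target scales
#' the baseline harvest by `harvest_uplift`. Deterministic given the
#' budgets.
#'
#' @param budgets Budget table.
#' @param nue_uplift Percentage-point NUE increase (default 13, i.e. a
#'   42% baseline moves to 55%).
#' @param nue_cap Upper bound on the target NUE.
#' @param harvest_uplift Multiplier on baseline harvest (default 1.2, a
#'   20% increase).
#' @return Tibble `region`, `nue_target`, `target_harvest`.
#' @export
generate_targets <- function(budgets, nue_uplift = 0.13, nue_cap = 0.85,
                             harvest_uplift = 1.2) {
  budgets <- validate_budgets(budgets)
  tibble::tibble(
    region = budgets$region,
    nue_target = pmin(nue(budgets) + nue_uplift, nue_cap),
    target_harvest = budgets$n_harvest * harvest_uplift
  )
}

#' Empty interaction table template
#'
#' Measures are combined additively unless a pair appears here with a joint
#' efficacy; field evidence on interacting measure pairs is sparse, so the
#' default is no interactions.
#'
#' @return Zero-row tibble with columns `measure_a`, `measure_b` and
#'   `eta_<pathway>` for each loss pathway.
#' @export
interaction_template <- function() {
  cols <- c(list(measure_a = character(), measure_b = character()),
            stats::setNames(rep(list(numeric()), length(PATHWAYS)),
                            paste0("eta_", PATHWAYS)))
  tibble::as_tibble(cols)
}

#' Write all synthetic tables plus a run manifest
#'
#' Generates the five table families and writes them as CSV under `dir`,
#' together with a `manifest.json` recording the configuration, seed and an
#' md5 hash of every file, which is sufficient to reproduce the run.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_synthetic_tables <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  econ <- generate_econ_params(config)
  budgets <- generate_budgets(config)
  tables <- list(
    observations = generate_observations(config),
    budgets = budgets,
    targets = generate_targets(budgets),
    measures = generate_measures(config),
    adoption = generate_adoption(config),
    econ = econ_params_to_table(econ),
    interactions = interaction_template()
  )
  paths <- purrr::imap(tables, function(tbl, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(tbl, p)
    p
  })

  cfg <- unclass(config)
  cfg$true_effect <- NULL # tabular; hash covers it through observations
  manifest <- list(
    config = cfg,
    files = purrr::map_chr(paths, ~ unname(tools::md5sum(.x)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Flatten econ parameters to a single long table
#'
#' @param econ An `econ_params` list.
#' @return Tibble with one row per region and pathway carrying both the
#'   region-level scalars and the per-pathway unit costs.
#' @export
econ_params_to_table <- function(econ) {
  stopifnot(inherits(econ, "econ_params"))
  tbl <- dplyr::left_join(econ$damage, econ$regions, by = "region")
  tbl <- dplyr::left_join(tbl,
                          dplyr::rename(econ$eco_unit_cost,
                                        eco_unit_cost = "cost"),
                          by = "pathway")
  tbl$reference_region <- econ$reference_region
  tbl
}

#' Rebuild an `econ_params` object from its flat table form
#'
#' @param tbl A table as produced by [econ_params_to_table()].
#' @return An `econ_params` list.
#' @export
econ_params_from_table <- function(tbl) {
  need <- c("region", "pathway", "hcost", "ccost", "uc", "wtp", "pgdp",
            "crop_price", "fertilizer_price", "eco_unit_cost",
            "reference_region")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    stop("econ table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  regions <- dplyr::distinct(tbl, .data$region, .data$uc, .data$wtp,
                             .data$pgdp, .data$crop_price,
                             .data$fertilizer_price)
  structure(list(
    regions = tibble::as_tibble(regions),
    damage = tibble::as_tibble(tbl[c("region", "pathway", "hcost", "ccost")]),
    eco_unit_cost = dplyr::distinct(
      tibble::tibble(pathway = tbl$pathway, cost = tbl$eco_unit_cost)),
    reference_region = tbl$reference_region[1]
  ), class = "econ_params")
}
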