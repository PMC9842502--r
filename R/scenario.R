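SCENARIO_TIER_MAX <- c("BAU" = 0L, "Tier1" = 1L, "Tier1+2" = 2L,
                       "Tier1+2+3" = 3L)

#' Specify a projection scenario
#'
#' A scenario is defined by the cumulative tier package it adopts (BAU
#' adopts nothing), an exogenous harvest-demand trajectory and a horizon.
#' Demand is driven by population and income outside the model and is
#' identical across scenarios; what differs is the measure package and
#' hence the NUE path, input requirement and fertilizer use.
#'
#' @param name One of `"BAU"`, `"Tier1"`, `"Tier1+2"`, `"Tier1+2+3"`.
#' @param demand Tibble `region`, `year`, `harvest` (kt N/yr) with at least
#'   the base-year value per region; intermediate years are linearly
#'   interpolated and the trajectory is held constant beyond the last
#'   given year.
#' @param base_year,horizon_year Projection range (defaults 2015-2050).
#' @param step Year step of the output grid.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("BAU", "Tier1", "Tier1+2", "Tier1+2+3"),
                          demand, base_year = 2015L, horizon_year = 2050L,
                          step = 5L) {
  name <- match.arg(name)
  stopifnot(is.data.frame(demand),
            all(c("region", "year", "harvest") %in% names(demand)))
  if (horizon_year <= base_year) {
    stop("`horizon_year` must exceed `base_year`", call. = FALSE)
  }
  structure(list(
    name = name,
    tier_max = SCENARIO_TIER_MAX[[name]],
    demand = tibble::as_tibble(demand),
    base_year = as.integer(base_year),
    horizon_year = as.integer(horizon_year),
    step = as.integer(step)
  ), class = "scenario_spec")
}

#' Read a scenario specification from a YAML file
#'
#' The file carries `name`, `base_year`, `horizon_year`, `step` and a
#' `demand` list of `{region, year, harvest}` records.
#'
#' @param path Path to the YAML file.
#' @return A [scenario_spec()].
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  demand <- dplyr::bind_rows(lapply(cfg$demand, tibble::as_tibble))
  scenario_spec(cfg$name, demand,
                base_year = cfg$base_year %||% 2015L,
                horizon_year = cfg$horizon_year %||% 2050L,
                step = cfg$step %||% 5L)
}

default_attribute_rules <- function() {
  # declarative caps: when a region attribute takes the given value, the
  # measure's adoption rate is capped; buffer zones occupy marginal
  # cropland and are limited where land is scarce
  tibble::tibble(
    attribute = "land_scarce",
    value = "TRUE",
    measure = "buffer_zone",
    x_cap = 0.2
  )
}

#' Filter measures by tier and regional applicability
#'
#' Keeps measures whose tier does not exceed `tier_max` and applies
#' declarative adoption caps from a rules table keyed on regional
#' attributes (e.g. capping buffer zones where land is scarce).
#'
#' @param measures Measure table with `measure` and `tier`.
#' @param tier_max Highest tier allowed (0 drops everything; BAU).
#' @param region_attributes Optional tibble with a `region` column plus
#'   attribute columns referenced by the rules.
#' @param rules Rules table (`attribute`, `value`, `measure`, `x_cap`);
#'   defaults to capping buffer zones in land-scarce regions. Errors on an
#'   attribute name absent from `region_attributes`.
#' @return Tibble `region`, `measure`, `x_cap` when attributes are given
#'   (one row per region and adoptable measure), otherwise `measure`,
#'   `x_cap`.
#' @export
tier_filter <- function(measures, tier_max, region_attributes = NULL,
                        rules = default_attribute_rules()) {
  stopifnot(all(c("measure", "tier") %in% names(measures)))
  keep <- measures$measure[measures$tier <= tier_max]
  if (is.null(region_attributes)) {
    return(tibble::tibble(measure = keep,
                          x_cap = rep(1, length(keep))))
  }
  stopifnot("region" %in% names(region_attributes))
  out <- tidyr::expand_grid(region = region_attributes$region,
                            measure = keep)
  out$x_cap <- 1
  if (!is.null(rules) && nrow(rules)) {
    unknown <- setdiff(unique(rules$attribute),
                       setdiff(names(region_attributes), "region"))
    if (length(unknown)) {
      stop("unknown region attribute(s) in rules: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (i in seq_len(nrow(rules))) {
      hit_regions <- region_attributes$region[
        as.character(region_attributes[[rules$attribute[i]]]) ==
          rules$value[i]]
      sel <- out$region %in% hit_regions & out$measure == rules$measure[i]
      out$x_cap[sel] <- pmin(out$x_cap[sel], rules$x_cap[i])
    }
  }
  out
}

# standalone mitigation potential (kt N/yr summed over pathways) of a
# measure set in one region, additive with the per-pathway cap at 1
potential_reduction <- function(baseline, measures, x) {
  if (!nrow(measures)) return(0)
  sum(vapply(PATHWAYS, function(p) {
    frac <- sum(vapply(seq_len(nrow(measures)), function(i) {
      measures[[paste0("eta_", p)]][i] * x[[measures$measure[i]]]
    }, numeric(1)))
    baseline[[p]] * min(frac, 1)
  }, numeric(1)))
}

#' Project cropland N trajectories under a tiered scenario
#'
#' For every year on the grid, harvest is set to the exogenous demand and
#' total N input follows from the year's NUE. The NUE moves linearly from
#' the base-year value towards the regional target, scaled by the share of
#' the full mitigation potential that the scenario's tier package can
#' deliver (BAU stays flat); adoption rates ramp linearly from zero to
#' their (tier-filtered, attribute-capped) maxima. Fertilizer use follows
#' the reduction identity (input change plus manure change minus the
#' deposition feedback) against a same-demand baseline in which all fluxes
#' grow with harvest; cropping area is demand over yield, with yield
#' raised by the adopted measures' effects.
#'
#' @param budgets Base-year budget table.
#' @param spec A [scenario_spec()].
#' @param measures Measure table.
#' @param adoption Adoption table giving each measure's maximum rate
#'   `X` per region (reached at the horizon).
#' @param targets Target table (`region`, `nue_target`, `target_harvest`).
#' @param econ Optional `econ_params`; when supplied a per-year
#'   [cost_benefit()] table is attached as attribute `"cba"`.
#' @param region_attributes,rules Passed to [tier_filter()].
#' @param redeposition_fraction Passed to [deposition_feedback()].
#' @return Tibble of trajectory points: `scenario`, `region`, `year`,
#'   `n_input`, `n_fer`, `n_harvest`, `area`, `yield`, `n_surplus`, `nue`.
#'   Errors with the region and year when demand would require NUE > 1.
#' @export
project <- function(budgets, spec, measures, adoption, targets,
                    econ = NULL, region_attributes = NULL,
                    rules = default_attribute_rules(),
                    redeposition_fraction = NULL) {
  budgets <- validate_budgets(budgets)
  stopifnot(inherits(spec, "scenario_spec"))
  years <- unique(c(seq(spec$base_year, spec$horizon_year, by = spec$step),
                    spec$horizon_year))

  caps <- tier_filter(measures, spec$tier_max, region_attributes, rules)
  base_nue <- nue(budgets)
  base_input <- total_input(budgets)

  rows <- list()
  cba_rows <- list()
  for (r in seq_len(nrow(budgets))) {
    b <- budgets[r, ]
    region <- b$region
    tgt <- targets[targets$region == region, ]
    if (!nrow(tgt)) stop("no target for region ", region, call. = FALSE)
    dem <- spec$demand[spec$demand$region == region, ]
    if (!nrow(dem)) stop("no demand for region ", region, call. = FALSE)
    demand_at <- function(y) {
      if (nrow(dem) == 1L) return(dem$harvest[1])
      stats::approx(dem$year, dem$harvest, xout = y, rule = 2)$y
    }

    # maximum adoption per measure in this region, after tier/attribute caps
    x_max <- stats::setNames(adoption$X[adoption$region == region],
                             adoption$measure[adoption$region == region])
    reg_caps <- if ("region" %in% names(caps)) {
      caps[caps$region == region, ]
    } else caps
    sel <- intersect(reg_caps$measure, names(x_max))
    x_max <- pmin(x_max[sel], reg_caps$x_cap[match(sel, reg_caps$measure)])
    msel <- measures[measures$measure %in% sel, ]

    baseline <- vapply(PATHWAYS, function(p) b[[PATHWAY_COLS[[p]]]],
                       numeric(1))
    pot_sel <- potential_reduction(baseline, msel, as.list(x_max))
    x_full <- stats::setNames(adoption$X[adoption$region == region],
                              adoption$measure[adoption$region == region])
    pot_all <- potential_reduction(baseline,
                                   measures[measures$measure %in%
                                              names(x_full), ],
                                   as.list(x_full))
    achieved <- if (pot_all > 0) pot_sel / pot_all else 0

    nue0 <- base_nue[r]
    loss_cols <- c(BUDGET_LOSS_COLS)
    loss_base <- vapply(loss_cols, function(cl) b[[cl]], numeric(1))
    loss_total0 <- sum(loss_base)
    loss_share <- if (loss_total0 > 0) {
      loss_base / loss_total0
    } else rep(0, length(loss_base))
    in_share_cols <- BUDGET_INPUT_COLS
    base_yield <- if (b$area > 0) b$n_harvest / b$area else NA_real_

    for (y in years) {
      f <- (y - spec$base_year) / (spec$horizon_year - spec$base_year)
      h <- demand_at(y)
      growth <- if (b$n_harvest > 0) h / b$n_harvest else 1

      nue_t <- nue0 + f * achieved * (tgt$nue_target[1] - nue0)
      nue_t <- min(nue_t, 1)
      if (h > 0 && nue_t <= 0) {
        stop("non-positive NUE for region ", region, " in ", y,
             call. = FALSE)
      }
      input_t <- if (h > 0) h / nue_t else base_input[r] * growth
      if (input_t < h - 1e-9) {
        stop("demand in region ", region, " year ", y,
             " would require NUE > 1", call. = FALSE)
      }

      # same-demand baseline: base-year budget scaled with harvest
      bau_loss <- loss_base * growth
      bau_inputs <- vapply(in_share_cols, function(cl) b[[cl]] * growth,
                           numeric(1))
      loss_t <- (input_t - h) * loss_share
      names(loss_t) <- loss_cols

      gas_red <- sum(bau_loss[c("e_nh3", "e_nox", "e_n2o")]) -
        sum(loss_t[c("e_nh3", "e_nox", "e_n2o")])
      frac_r <- if (is.null(redeposition_fraction)) {
        gb <- sum(loss_base[c("e_nh3", "e_nox", "e_n2o")])
        if (gb > 0) min(b$n_dep / gb, 1) else 0
      } else redeposition_fraction
      delta_dep <- max(gas_red, 0) * frac_r
      delta_input <- sum(bau_inputs) - input_t
      delta_fer <- min(delta_input - delta_dep, bau_inputs[["n_fer"]])
      fer_t <- max(bau_inputs[["n_fer"]] - delta_fer, 0)

      hm <- 1
      for (i in seq_len(nrow(msel))) {
        hm <- hm * (1 + (msel$yield_multiplier[i] - 1) *
                      x_max[[msel$measure[i]]] * f)
      }
      yield_t <- base_yield * hm
      area_t <- if (is.finite(yield_t) && yield_t > 0) h / yield_t else
        b$area

      rows[[length(rows) + 1L]] <- tibble::tibble(
        scenario = spec$name, region = region, year = as.integer(y),
        n_input = input_t, n_fer = fer_t, n_harvest = h, area = area_t,
        yield = yield_t, n_surplus = input_t - h, nue = nue_t
      )

      if (!is.null(econ)) {
        de <- pmax(bau_loss[PATHWAY_COLS] - loss_t[PATHWAY_COLS], 0)
        cba_rows[[length(cba_rows) + 1L]] <- tibble::tibble(
          scenario = spec$name, region = region, year = as.integer(y),
          pathway = PATHWAYS, delta_e = unname(de),
          delta_fer = delta_fer
        )
      }
    }
  }

  out <- dplyr::bind_rows(rows)
  if (!is.null(econ) && length(cba_rows)) {
    red <- dplyr::bind_rows(cba_rows)
    cba <- purrr::map_dfr(unique(red$year), function(y) {
      ry <- red[red$year == y, ]
      deltas <- dplyr::distinct(ry, .data$region, .data$delta_fer)
      deltas$delta_harvest <- 0 # demand is met identically across scenarios
      tbl <- cost_benefit(ry[c("region", "pathway", "delta_e")],
                          deltas, econ)
      tbl$year <- as.integer(y)
      tbl$scenario <- spec$name
      tbl
    })
    attr(out, "cba") <- cba
  }
  out
}
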