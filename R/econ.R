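KT_TO_KG <- 1e6 # kt N -> kg N; unit costs are USD per kg N

#' Implementation cost of an emission reduction
#'
#' Abated mass times the integrated unit abatement cost:
#' `IC = delta_e * UC`. Unit costs are USD per kg N abated and reductions
#' kt N, so 1 kt abated at 2 USD/kg costs 2 million USD.
#'
#' @param delta_e Emission reduction, kt N (vectorized).
#' @param uc Unit abatement cost, USD per kg N.
#' @return Cost in USD.
#' @export
implementation_cost <- function(delta_e, uc) {
  if (any(delta_e < 0)) stop("`delta_e` must be >= 0", call. = FALSE)
  if (any(!is.finite(uc))) stop("missing unit abatement cost", call. = FALSE)
  delta_e * KT_TO_KG * uc
}

check_reductions <- function(reductions) {
  stopifnot(all(c("region", "pathway", "delta_e") %in% names(reductions)))
  bad <- setdiff(unique(reductions$pathway), PATHWAYS)
  if (length(bad)) {
    stop("unknown pathway(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(reductions)
}

econ_ratios <- function(econ) {
  stopifnot(inherits(econ, "econ_params"))
  reg <- econ$regions
  ref <- reg[reg$region == econ$reference_region, ]
  if (nrow(ref) != 1L) {
    stop("reference region '", econ$reference_region,
         "' absent from econ parameters", call. = FALSE)
  }
  tibble::tibble(
    region = reg$region,
    wtp_ratio = reg$wtp / ref$wtp,
    pgdp_ratio = reg$pgdp / ref$pgdp
  )
}

#' Ecosystem benefit of emission reductions
#'
#' Benefit-transfer monetization: each loss form's reduction is valued at
#' the US-reference unit ecosystem damage cost, scaled to the region by the
#' willingness-to-pay ratio and the per-capita GDP ratio:
#' `EH = sum_j delta_e_j * cost_US_j * (WTP_i/WTP_US) * (PGDP_i/PGDP_US)`.
#'
#' @param reductions Tibble `region`, `pathway`, `delta_e` (kt N).
#' @param econ An `econ_params` object; must contain the reference region.
#' @return Tibble `region`, `eh` (USD).
#' @export
ecosystem_benefit <- function(reductions, econ) {
  check_reductions(reductions)
  ratios <- econ_ratios(econ)
  tbl <- dplyr::left_join(reductions, econ$eco_unit_cost, by = "pathway")
  tbl <- dplyr::left_join(tbl, ratios, by = "region")
  tbl$value <- tbl$delta_e * KT_TO_KG * tbl$cost * tbl$wtp_ratio *
    tbl$pgdp_ratio
  dplyr::summarise(dplyr::group_by(tbl, .data$region),
                   eh = sum(.data$value), .groups = "drop")
}

#' Health benefit of emission reductions
#'
#' Avoided premature-mortality damage: `HH = sum_j delta_e_j * HCost_j`,
#' with region-specific unit health damage costs (USD per kg N).
#'
#' @inheritParams ecosystem_benefit
#' @return Tibble `region`, `hh` (USD).
#' @export
health_benefit <- function(reductions, econ) {
  check_reductions(reductions)
  tbl <- dplyr::left_join(reductions, econ$damage,
                          by = c("region", "pathway"))
  if (anyNA(tbl$hcost)) {
    stop("missing health damage cost for some region/pathway",
         call. = FALSE)
  }
  tbl$value <- tbl$delta_e * KT_TO_KG * tbl$hcost
  dplyr::summarise(dplyr::group_by(tbl, .data$region),
                   hh = sum(.data$value), .groups = "drop")
}

#' Yield benefit of a harvest change
#'
#' `YD = delta_harvest * crop_price`, signed: a yield loss monetizes as a
#' negative benefit (a cost).
#'
#' @param delta_harvest Change in harvested N, kt N (may be negative).
#' @param crop_price Integrated crop price, USD per kg harvested N.
#' @return Benefit in USD (vectorized).
#' @export
yield_benefit <- function(delta_harvest, crop_price) {
  delta_harvest * KT_TO_KG * crop_price
}

#' Climate benefit of emission reductions (signed)
#'
#' `GHG = sum_j delta_e_j * CCost_j`. Unit climate costs are signed: N2O
#' abatement benefits the climate, while reducing NH3 and NOx removes a
#' cooling aerosol effect, so their unit costs are negative and the total
#' climate "benefit" can be a damage.
#'
#' @inheritParams ecosystem_benefit
#' @return Tibble `region`, `ghg` (USD, signed).
#' @export
climate_benefit <- function(reductions, econ) {
  check_reductions(reductions)
  tbl <- dplyr::left_join(reductions, econ$damage,
                          by = c("region", "pathway"))
  if (anyNA(tbl$ccost)) {
    stop("missing climate cost for some region/pathway", call. = FALSE)
  }
  tbl$value <- tbl$delta_e * KT_TO_KG * tbl$ccost
  dplyr::summarise(dplyr::group_by(tbl, .data$region),
                   ghg = sum(.data$value), .groups = "drop")
}

#' Total societal benefit
#'
#' Exact sum of the four components: ecosystem, health, yield and climate.
#'
#' @param eh,hh,yd,ghg Benefit components (USD, vectorized).
#' @return `eh + hh + yd + ghg`.
#' @export
#' @examples
#' societal_benefit(196e9, 130e9, 152e9, -2e9) # 476e9
societal_benefit <- function(eh, hh, yd, ghg) {
  eh + hh + yd + ghg
}

#' Fertilizer saving from reduced fertilizer use
#'
#' `delta_fer * fertilizer_price`. Signed: regions that should increase
#' fertilizer use get a negative saving (an added purchase).
#'
#' @param delta_fer Fertilizer reduction, kt N.
#' @param fertilizer_price USD per kg N.
#' @return Saving in USD (vectorized).
#' @export
fertilizer_saving <- function(delta_fer, fertilizer_price) {
  delta_fer * KT_TO_KG * fertilizer_price
}

#' Full cost-benefit table for a mitigation outcome
#'
#' Combines the monetization operations into one result per region plus a
#' `GLOBAL` row: implementation cost (`ic`), fertilizer saving, net cost
#' (`ic - fertilizer_saving`), the four benefit components, total societal
#' benefit (`soc`, exactly their sum) and benefit-to-cost ratios (net-cost
#' denominator where the net cost is positive; the gross-denominator
#' variant is also reported).
#'
#' @param reductions Tibble `region`, `pathway`, `delta_e` (kt N).
#' @param deltas Per-region deltas as attached by [apply_mitigation()]
#'   (needs `delta_harvest`, `delta_fer`).
#' @param econ An `econ_params` object.
#' @return Tibble of class `cost_benefit` with one row per region and a
#'   final `GLOBAL` row.
#' @export
cost_benefit <- function(reductions, deltas, econ) {
  check_reductions(reductions)
  stopifnot(all(c("region", "delta_harvest", "delta_fer") %in%
                  names(deltas)))

  tot_red <- dplyr::summarise(dplyr::group_by(reductions, .data$region),
                              delta_e = sum(.data$delta_e),
                              .groups = "drop")
  reg <- econ$regions
  idx <- match(tot_red$region, reg$region)
  if (anyNA(idx)) {
    stop("econ parameters missing for region(s) ",
         paste(tot_red$region[is.na(idx)], collapse = ", "), call. = FALSE)
  }

  res <- tibble::tibble(
    region = tot_red$region,
    ic = implementation_cost(tot_red$delta_e, reg$uc[idx])
  )
  res <- dplyr::left_join(res, ecosystem_benefit(reductions, econ),
                          by = "region")
  res <- dplyr::left_join(res, health_benefit(reductions, econ),
                          by = "region")
  res <- dplyr::left_join(res, climate_benefit(reductions, econ),
                          by = "region")
  didx <- match(res$region, deltas$region)
  res$yd <- yield_benefit(deltas$delta_harvest[didx],
                          reg$crop_price[match(res$region, reg$region)])
  res$fertilizer_saving <- fertilizer_saving(
    deltas$delta_fer[didx],
    reg$fertilizer_price[match(res$region, reg$region)])
  res$soc <- societal_benefit(res$eh, res$hh, res$yd, res$ghg)
  res$net_cost <- res$ic - res$fertilizer_saving

  glob <- dplyr::summarise(res, dplyr::across(dplyr::where(is.numeric),
                                              sum))
  glob$region <- "GLOBAL"
  res <- dplyr::bind_rows(res, glob)
  res$bcr_net <- ifelse(res$net_cost > 0, res$soc / res$net_cost, NA_real_)
  res$bcr_gross <- ifelse(res$ic > 0, res$soc / res$ic, NA_real_)
  class(res) <- c("cost_benefit", class(res))
  res[c("region", "ic", "fertilizer_saving", "net_cost", "eh", "hh", "yd",
        "ghg", "soc", "bcr_net", "bcr_gross")]
}

#' Bundle the inputs of a full assessment
#'
#' Convenience container holding everything needed to run the mitigation
#' and cost-benefit chain on one world: baseline budgets, measure
#' efficacies, adoption rates, optional interactions and NUE targets, and
#' economic parameters.
#'
#' @param budgets,measures,adoption,econ See the respective generators.
#' @param interactions,targets Optional.
#' @param redeposition_fraction Passed to [apply_mitigation()].
#' @param delta_man Manure input change per region (kt N/yr).
#' @param strict Literal fertilizer clamp.
#' @return A list of class `assessment_world`.
#' @export
assessment_world <- function(budgets, measures, adoption, econ,
                             interactions = NULL, targets = NULL,
                             redeposition_fraction = NULL, delta_man = 0,
                             strict = FALSE) {
  structure(list(
    budgets = validate_budgets(budgets), measures = measures,
    adoption = adoption, econ = econ, interactions = interactions,
    targets = targets, redeposition_fraction = redeposition_fraction,
    delta_man = delta_man, strict = strict
  ), class = "assessment_world")
}

#' Run the mitigation and cost-benefit chain once
#'
#' @param world An [assessment_world()].
#' @return List: `combined` (the measure combination), `post_budgets`
#'   (with the `"deltas"` attribute) and `cba` (the [cost_benefit()]
#'   table).
#' @export
evaluate_world <- function(world) {
  stopifnot(inherits(world, "assessment_world"))
  combined <- combine_measures(world$budgets, world$measures,
                               world$adoption, world$interactions,
                               world$targets)
  post <- apply_mitigation(world$budgets, combined, world$targets,
                           world$redeposition_fraction, world$delta_man,
                           world$strict)
  deltas <- attr(post, "deltas")
  list(
    combined = combined,
    post_budgets = post,
    cba = cost_benefit(combined$reductions, deltas, world$econ)
  )
}

perturb_measures <- function(measures, eta_sd, rng) {
  out <- measures
  for (p in paste0("eta_", PATHWAYS)) {
    # noise on the log response ratio underlying the efficacy keeps the
    # perturbed efficacy inside [0, 1) from above
    lr <- log1p(-out[[p]])
    out[[p]] <- pmin(pmax(-expm1(lr + rng(nrow(out)) * eta_sd), 0), 1)
  }
  out$yield_multiplier <- exp(log(out$yield_multiplier) +
                                rng(nrow(out)) * eta_sd)
  out
}

perturb_econ <- function(econ, price_rel_sd, rng) {
  reg <- econ$regions
  n <- nrow(reg)
  # positive prices: normal relative noise truncated at zero
  for (col in c("uc", "crop_price", "fertilizer_price")) {
    reg[[col]] <- pmax(reg[[col]] * (1 + rng(n) * price_rel_sd), 0)
  }
  dmg <- econ$damage
  dmg$hcost <- pmax(dmg$hcost * (1 + rng(nrow(dmg)) * price_rel_sd), 0)
  # climate costs are signed; scale without truncation
  dmg$ccost <- dmg$ccost * (1 + rng(nrow(dmg)) * price_rel_sd)
  eco <- econ$eco_unit_cost
  eco$cost <- pmax(eco$cost * (1 + rng(nrow(eco)) * price_rel_sd), 0)
  structure(list(regions = reg, damage = dmg, eco_unit_cost = eco,
                 reference_region = econ$reference_region),
            class = "econ_params")
}

#' Monte-Carlo uncertainty propagation through the full chain
#'
#' Re-runs the mitigation and cost-benefit chain `n_draws` times with
#' perturbed inputs and reports the mean and standard deviation of every
#' monetary field. Efficacies are perturbed by Gaussian noise on their
#' underlying log response ratio (keeping them in \[0, 1\]); positive
#' prices by relative Gaussian noise truncated at zero; signed climate
#' costs by untruncated relative noise. The component-sum identity
#' `soc = eh + hh + yd + ghg` holds in every draw by construction.
#'
#' @param world An [assessment_world()].
#' @param n_draws Number of Monte-Carlo draws (>= 2).
#' @param seed Seed for the draw stream.
#' @param eta_sd Log-ratio noise SD on efficacies and yield multipliers.
#' @param price_rel_sd Relative noise SD on unit costs and prices.
#' @return List: `summary` (per region and field: mean, sd), `draws`
#'   (global values per draw) and `point` (unperturbed [cost_benefit()]
#'   table).
#' @export
propagate_uncertainty <- function(world, n_draws = 1000L, seed,
                                  eta_sd = 0.05, price_rel_sd = 0.1) {
  stopifnot(inherits(world, "assessment_world"))
  if (n_draws < 2) stop("`n_draws` must be >= 2", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)

  point <- evaluate_world(world)$cba

  draws <- withr::with_seed(stage_seed(seed, "draws"), {
    purrr::map(seq_len(n_draws), function(d) {
      w <- world
      w$measures <- perturb_measures(world$measures, eta_sd, stats::rnorm)
      w$econ <- perturb_econ(world$econ, price_rel_sd, stats::rnorm)
      evaluate_world(w)$cba
    })
  })

  all_draws <- dplyr::bind_rows(draws, .id = "draw")
  fields <- c("ic", "fertilizer_saving", "net_cost", "eh", "hh", "yd",
              "ghg", "soc")
  summary <- dplyr::summarise(
    dplyr::group_by(all_draws, .data$region),
    dplyr::across(dplyr::all_of(fields),
                  list(mean = mean, sd = stats::sd)),
    .groups = "drop"
  )
  list(
    summary = summary,
    draws = tibble::as_tibble(all_draws[all_draws$region == "GLOBAL",
                                        c("draw", fields)]),
    point = point
  )
}
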