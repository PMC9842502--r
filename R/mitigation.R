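#' Decompose baseline budgets into activity and emission factors
#'
#' Abatement is computed on an activity-times-emission-factor basis. When
#' no explicit emission-factor table is supplied, the factors are derived
#' from the baseline budget itself (`EF = baseline pathway flux /
#' activity`), which guarantees that `A * EF` reproduces the baseline flux
#' exactly.
#'
#' @param budgets Validated budget table.
#' @param activity Which activity basis to use: total N `"input"`,
#'   `"fertilizer"` use or cropping `"area"`.
#' @return Tibble with columns `region`, `pathway`, `activity`, `unit`,
#'   `emission_factor`, `ef_per` (the activity unit the factor is per).
#' @export
activity_from_budget <- function(budgets,
                                 activity = c("input", "fertilizer",
                                              "area")) {
  activity <- match.arg(activity)
  budgets <- validate_budgets(budgets)
  a <- switch(activity,
    input = total_input(budgets),
    fertilizer = budgets$n_fer,
    area = budgets$area
  )
  unit <- if (activity == "area") "kha" else "ktN"
  grid <- tidyr::expand_grid(region = budgets$region, pathway = PATHWAYS)
  idx <- match(grid$region, budgets$region)
  flux <- vapply(seq_len(nrow(grid)), function(i) {
    budgets[[PATHWAY_COLS[[grid$pathway[i]]]]][idx[i]]
  }, numeric(1))
  grid$activity <- a[idx]
  grid$unit <- unit
  grid$emission_factor <- ifelse(grid$activity > 0, flux / grid$activity, 0)
  grid$ef_per <- unit
  grid
}

#' Emission reduction from one measure (activity x EF x efficacy x rate)
#'
#' The abatement identity: `delta_e = A * EF * eta * X`, per region and
#' loss pathway. Zero adoption (`X = 0`) is the baseline and yields zero
#' reduction; full efficacy at full adoption removes the entire baseline
#' flux `A * EF`.
#'
#' @param activity Activity/emission-factor table from
#'   [activity_from_budget()] (or user-supplied with the same columns).
#' @param measure One row of a measure table carrying `measure` and the
#'   `eta_<pathway>` efficacies.
#' @param adoption Adoption table with columns `region`, `measure`, `X`.
#' @return Tibble `region`, `measure`, `pathway`, `delta_e` (kt N/yr).
#' @export
emission_reduction <- function(activity, measure, adoption) {
  stopifnot(all(c("region", "pathway", "activity", "emission_factor") %in%
                  names(activity)))
  if (!is.null(activity$unit) && !is.null(activity$ef_per) &&
      any(activity$unit != activity$ef_per)) {
    stop("emission factor unit does not match activity unit", call. = FALSE)
  }
  m <- measure$measure[1]
  eta <- vapply(PATHWAYS, function(p) {
    col <- paste0("eta_", p)
    if (col %in% names(measure)) measure[[col]][1] else 0
  }, numeric(1))
  if (any(eta < 0 | eta > 1)) {
    stop("efficacies must lie in [0, 1]", call. = FALSE)
  }
  x <- adoption$X[adoption$measure == m]
  names(x) <- adoption$region[adoption$measure == m]
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    stop("implementation rates must lie in [0, 1]", call. = FALSE)
  }
  xr <- x[activity$region]
  xr[is.na(xr)] <- 0
  tibble::tibble(
    region = activity$region,
    measure = m,
    pathway = activity$pathway,
    delta_e = unname(activity$activity * activity$emission_factor *
                       eta[activity$pathway] * xr)
  )
}

# effective abated fraction of each pathway for a set of measures in one
# region: individual terms eta * X summed, except that an interacting pair
# with both members present contributes its joint efficacy at the larger
# of the two adoption rates instead of the two individual terms
combined_fraction <- function(measure_rows, x, interactions, pathway) {
  col <- paste0("eta_", pathway)
  sel <- measure_rows$measure
  paired <- character()
  frac <- 0
  if (!is.null(interactions) && nrow(interactions)) {
    for (i in seq_len(nrow(interactions))) {
      a <- interactions$measure_a[i]
      b <- interactions$measure_b[i]
      if (a %in% sel && b %in% sel) {
        joint <- interactions[[col]][i]
        frac <- frac + joint * max(x[[a]], x[[b]])
        paired <- c(paired, a, b)
      }
    }
  }
  solo <- setdiff(sel, paired)
  for (m in solo) {
    eta <- measure_rows[[col]][measure_rows$measure == m]
    frac <- frac + eta * x[[m]]
  }
  min(frac, 1)
}

# harvest multiplier of a measure set: each measure's yield effect applied
# on its adopted fraction, combined multiplicatively
harvest_multiplier <- function(measure_rows, x) {
  mult <- 1
  for (i in seq_len(nrow(measure_rows))) {
    m <- measure_rows$measure[i]
    mult <- mult * (1 + (measure_rows$yield_multiplier[i] - 1) * x[[m]])
  }
  mult
}

# post-mitigation NUE of one region under a measure set (closure
# convention: input = harvest + all losses, N2 scaled with the gaseous Nr
# reduction fraction)
region_post_nue <- function(budget_row, measure_rows, x, interactions,
                            target_harvest = NULL) {
  baseline <- vapply(PATHWAYS,
                     function(p) budget_row[[PATHWAY_COLS[[p]]]],
                     numeric(1))
  frac <- vapply(PATHWAYS, function(p) {
    combined_fraction(measure_rows, x, interactions, p)
  }, numeric(1))
  losses <- baseline * (1 - frac)
  gas_base <- sum(baseline[c("NH3", "NOx", "N2O")])
  gas_frac <- if (gas_base > 0) {
    sum((baseline * frac)[c("NH3", "NOx", "N2O")]) / gas_base
  } else 0
  n2 <- budget_row$e_n2 * (1 - gas_frac)
  harvest <- budget_row$n_harvest * harvest_multiplier(measure_rows, x)
  if (!is.null(target_harvest)) harvest <- min(harvest, target_harvest)
  input <- harvest + sum(losses) + n2
  if (input <= 0) return(1)
  harvest / input
}

#' Combine mitigation measures region by region
#'
#' Builds the most appropriate measure set for each region. Candidate
#' measures (adoption rate > 0) are ranked by ascending tier and then by
#' descending total emission reduction, and added in that order; once a
#' region's post-mitigation NUE reaches its target, no further measures are
#' added. Non-interacting measures combine additively; a measure pair
#' listed in the interaction table contributes its jointly measured
#' efficacy (at the larger of the two adoption rates) instead of the sum of
#' its individual effects. The abated fraction of each pathway is capped at
#' 1, so no reduction can exceed its baseline flux.
#'
#' @param budgets Validated budget table.
#' @param measures Measure table (`measure`, `tier`, `eta_<pathway>`,
#'   `yield_multiplier`, `nue_multiplier`).
#' @param adoption Adoption table (`region`, `measure`, `X`).
#' @param interactions Optional joint-efficacy table (`measure_a`,
#'   `measure_b`, `eta_<pathway>`); default none (pure additivity).
#' @param targets Optional target table (`region`, `nue_target`,
#'   `target_harvest`); enables the NUE-target truncation and the harvest
#'   cap.
#' @return List of class `combined_reduction`: `reductions` (per region and
#'   pathway: `baseline`, `frac`, `delta_e`), `selected` (measures used per
#'   region, in priority order) and `harvest_mult` (per region harvest
#'   multiplier from the selected set).
#' @export
combine_measures <- function(budgets, measures, adoption,
                             interactions = NULL, targets = NULL) {
  budgets <- validate_budgets(budgets)
  stopifnot(all(c("measure", "tier") %in% names(measures)))
  if (!is.null(interactions) && nrow(interactions)) {
    unknown <- setdiff(c(interactions$measure_a, interactions$measure_b),
                       MEASURES)
    if (length(unknown)) {
      stop("interaction table references unknown measure(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }

  red <- list()
  sel_out <- list()
  hm <- numeric(nrow(budgets))

  for (r in seq_len(nrow(budgets))) {
    b <- budgets[r, ]
    region <- b$region
    x_all <- adoption$X[adoption$region == region]
    names(x_all) <- adoption$measure[adoption$region == region]
    cand <- measures[measures$measure %in% names(x_all)[x_all > 0], ]
    x <- as.list(x_all)

    baseline <- vapply(PATHWAYS, function(p) b[[PATHWAY_COLS[[p]]]],
                       numeric(1))
    # priority: ascending tier, then descending standalone reduction
    if (nrow(cand)) {
      tot_red <- vapply(seq_len(nrow(cand)), function(i) {
        sum(vapply(PATHWAYS, function(p) {
          baseline[[p]] * cand[[paste0("eta_", p)]][i] *
            x[[cand$measure[i]]]
        }, numeric(1)))
      }, numeric(1))
      cand <- cand[order(cand$tier, -tot_red), ]
    }

    tgt <- if (!is.null(targets)) {
      targets[targets$region == region, ]
    } else NULL
    nue_target <- if (!is.null(tgt) && nrow(tgt)) tgt$nue_target[1] else NULL
    t_harv <- if (!is.null(tgt) && nrow(tgt)) tgt$target_harvest[1] else NULL

    chosen <- cand[0, ]
    if (nrow(cand)) {
      for (i in seq_len(nrow(cand))) {
        if (!is.null(nue_target) &&
            region_post_nue(b, chosen, x, interactions, t_harv) >=
              nue_target) {
          break
        }
        chosen <- rbind(chosen, cand[i, ])
      }
    }

    frac <- vapply(PATHWAYS, function(p) {
      combined_fraction(chosen, x, interactions, p)
    }, numeric(1))
    red[[r]] <- tibble::tibble(
      region = region, pathway = PATHWAYS,
      baseline = unname(baseline), frac = unname(frac),
      delta_e = unname(baseline * frac)
    )
    hm[r] <- harvest_multiplier(chosen, x)
    sel_out[[r]] <- if (nrow(chosen)) {
      tibble::tibble(region = region, measure = chosen$measure,
                     tier = chosen$tier, rank = seq_len(nrow(chosen)))
    } else {
      tibble::tibble(region = character(), measure = character(),
                     tier = integer(), rank = integer())
    }
  }

  structure(list(
    reductions = dplyr::bind_rows(red),
    selected = dplyr::bind_rows(sel_out),
    harvest_mult = tibble::tibble(region = budgets$region,
                                  multiplier = hm)
  ), class = "combined_reduction")
}

#' Fertilizer reduction implied by input, manure and deposition changes
#'
#' `delta_fer = delta_input + delta_man - delta_dep`, then constrained so
#' that post-mitigation fertilizer use stays non-negative. The default
#' reading caps the reduction at the baseline fertilizer use (fertilizer
#' floored at zero); `strict = TRUE` instead zeroes any reduction exceeding
#' the baseline (the literal clamp), discarding that region's fertilizer
#' saving.
#'
#' @param budgets Validated budget table.
#' @param delta_input,delta_man,delta_dep Numeric vectors (kt N/yr) aligned
#'   with `budgets` rows: reduction of total N input, increase of manure
#'   recycling, reduction of atmospheric deposition.
#' @param strict Use the literal clamp.
#' @return Numeric vector of fertilizer reductions (kt N/yr); may be
#'   negative for regions that should increase input.
#' @export
fertilizer_reduction <- function(budgets, delta_input, delta_man,
                                 delta_dep, strict = FALSE) {
  budgets <- validate_budgets(budgets)
  d <- delta_input + delta_man - delta_dep
  if (strict) {
    ifelse(d > budgets$n_fer, 0, d)
  } else {
    pmin(d, budgets$n_fer)
  }
}

#' Deposition change proportional to the emission reduction
#'
#' Atmospheric N deposition onto cropland falls in proportion to the
#' reduction of reactive gaseous emissions. When no fraction is given, each
#' region's baseline deposition-to-gaseous-emission ratio is used (capped
#' at 1).
#'
#' @param emission_reduction Reduction of reactive gaseous N emissions
#'   (NH3 + NOx + N2O), kt N/yr, per region.
#' @param fraction Redeposition fraction(s) in \[0, 1\], or `NULL` to derive
#'   from `budgets`.
#' @param budgets Budget table, required when `fraction` is `NULL`.
#' @return Deposition reduction, kt N/yr.
#' @export
deposition_feedback <- function(emission_reduction, fraction = NULL,
                                budgets = NULL) {
  if (is.null(fraction)) {
    if (is.null(budgets)) {
      stop("supply `fraction` or `budgets`", call. = FALSE)
    }
    budgets <- validate_budgets(budgets)
    gas <- rowSums(as.matrix(budgets[c("e_nh3", "e_nox", "e_n2o")]))
    fraction <- ifelse(gas > 0, pmin(budgets$n_dep / gas, 1), 0)
  }
  if (any(fraction < 0 | fraction > 1)) {
    stop("redeposition fraction must lie in [0, 1]", call. = FALSE)
  }
  emission_reduction * fraction
}

#' Manure recycling adjustment
#'
#' Additional manure N recycled to cropland when the recycling ratio is
#' raised towards a target, bounded by the cropland's maximum manure
#' carrying capacity and by the manure production potential.
#'
#' @param budgets Validated budget table.
#' @param recycling_ratio_target Target recycling ratio in \[0, 1\].
#' @param manure_production Manure production potential per region
#'   (kt N/yr); defaults to baseline manure input divided by
#'   `baseline_ratio`.
#' @param carrying_capacity Maximum manure N the cropland can absorb
#'   (kt N/yr); default unbounded.
#' @param baseline_ratio Assumed baseline recycling ratio used when
#'   `manure_production` is not supplied.
#' @param allow_decrease Permit negative adjustments (target below the
#'   baseline ratio); default floors the change at zero.
#' @return Manure input change per region, kt N/yr.
#' @export
manure_recycling_adjustment <- function(budgets, recycling_ratio_target,
                                        manure_production = NULL,
                                        carrying_capacity = Inf,
                                        baseline_ratio = 0.5,
                                        allow_decrease = FALSE) {
  budgets <- validate_budgets(budgets)
  if (any(recycling_ratio_target < 0 | recycling_ratio_target > 1)) {
    stop("`recycling_ratio_target` must lie in [0, 1]", call. = FALSE)
  }
  if (any(carrying_capacity < 0)) {
    stop("`carrying_capacity` must be >= 0", call. = FALSE)
  }
  if (is.null(manure_production)) {
    manure_production <- budgets$n_man / baseline_ratio
  }
  target_man <- pmin(recycling_ratio_target * manure_production,
                     carrying_capacity)
  d <- target_man - budgets$n_man
  if (!allow_decrease) d <- pmax(d, 0)
  d
}

#' Apply a combined reduction to the baseline budgets
#'
#' Produces post-mitigation budgets: pathway fluxes are reduced by the
#' combined `delta_e`; N2 emission is scaled down with the gaseous-Nr
#' reduction fraction and its saving is tracked separately (it is not an
#' environmental improvement); harvest is scaled by the selected measures'
#' yield effect (capped at the target harvest); total input follows from
#' the closure convention; deposition falls via [deposition_feedback()];
#' manure changes by `delta_man`; and fertilizer absorbs the remaining
#' input change (the fertilizer-reduction identity), clamped at zero.
#'
#' @param budgets Validated baseline budget table.
#' @param combined A `combined_reduction` from [combine_measures()].
#' @param targets Optional target table (caps harvest at
#'   `target_harvest`).
#' @param redeposition_fraction Passed to [deposition_feedback()]; `NULL`
#'   derives per-region fractions from the baseline.
#' @param delta_man Manure input change per region (kt N/yr), e.g. from
#'   [manure_recycling_adjustment()]; default 0.
#' @param strict Literal fertilizer clamp (see [fertilizer_reduction()]).
#' @return Post-mitigation budget tibble with attribute `"deltas"`: per
#'   region `delta_input`, `delta_man`, `delta_dep`, `delta_fer`,
#'   `delta_n2`, `delta_harvest`, `nr_emission_reduction` and
#'   `fer_clamped`.
#' @export
apply_mitigation <- function(budgets, combined, targets = NULL,
                             redeposition_fraction = NULL, delta_man = 0,
                             strict = FALSE) {
  budgets <- validate_budgets(budgets)
  stopifnot(inherits(combined, "combined_reduction"))
  red <- combined$reductions
  post <- budgets
  delta_man <- rep_len(delta_man, nrow(budgets))

  # reduce the five reactive pathways
  for (p in PATHWAYS) {
    col <- PATHWAY_COLS[[p]]
    d <- red$delta_e[red$pathway == p][match(budgets$region,
                                             red$region[red$pathway == p])]
    d[is.na(d)] <- 0
    if (any(d > budgets[[col]] * (1 + 1e-9))) {
      stop("reduction exceeds baseline flux for pathway ", p,
           call. = FALSE)
    }
    post[[col]] <- pmax(budgets[[col]] - d, 0)
  }

  gas_base <- rowSums(as.matrix(budgets[c("e_nh3", "e_nox", "e_n2o")]))
  gas_post <- rowSums(as.matrix(post[c("e_nh3", "e_nox", "e_n2o")]))
  gas_red <- gas_base - gas_post
  gas_frac <- ifelse(gas_base > 0, gas_red / gas_base, 0)

  # N2 scales with the gaseous-Nr reduction; a fertilizer saving, not an
  # environmental improvement
  delta_n2 <- budgets$e_n2 * gas_frac
  post$e_n2 <- budgets$e_n2 - delta_n2

  hm <- combined$harvest_mult$multiplier[match(budgets$region,
                                               combined$harvest_mult$region)]
  hm[is.na(hm)] <- 1
  new_harvest <- budgets$n_harvest * hm
  if (!is.null(targets)) {
    th <- targets$target_harvest[match(budgets$region, targets$region)]
    new_harvest <- ifelse(!is.na(th), pmin(new_harvest, th), new_harvest)
  }
  post$n_harvest <- new_harvest

  new_input <- total_output(post) # closure convention
  delta_input <- total_input(budgets) - new_input

  delta_dep <- deposition_feedback(gas_red, redeposition_fraction, budgets)
  delta_dep <- pmin(delta_dep, budgets$n_dep)
  post$n_dep <- budgets$n_dep - delta_dep
  post$n_man <- budgets$n_man + delta_man

  delta_fer <- fertilizer_reduction(budgets, delta_input, delta_man,
                                    delta_dep, strict = strict)
  fer_clamped <- (delta_input + delta_man - delta_dep) > budgets$n_fer
  post$n_fer <- budgets$n_fer - delta_fer

  nr_red <- gas_red +
    (budgets$n_leach - post$n_leach) + (budgets$n_runoff - post$n_runoff)

  attr(post, "deltas") <- tibble::tibble(
    region = budgets$region,
    delta_input = delta_input,
    delta_man = delta_man,
    delta_dep = delta_dep,
    delta_fer = delta_fer,
    delta_n2 = delta_n2,
    delta_harvest = new_harvest - budgets$n_harvest,
    nr_emission_reduction = nr_red,
    fer_clamped = fer_clamped
  )
  post
}
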