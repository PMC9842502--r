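#' Log response ratio of a treatment/control contrast
#'
#' The effect metric of the meta-analysis: `ln(mean_treatment /
#' mean_control)`. Antisymmetric under swapping the two means. Both means
#' must be strictly positive; ratios of fluxes, yields or efficiencies are
#' undefined otherwise.
#'
#' @param mean_treatment,mean_control Positive numeric vectors (recycled).
#' @return Numeric vector of log response ratios.
#' @export
#' @examples
#' log_response_ratio(2, 1) # log(2)
log_response_ratio <- function(mean_treatment, mean_control) {
  if (any(!is.finite(mean_treatment)) || any(!is.finite(mean_control)) ||
      any(mean_treatment <= 0) || any(mean_control <= 0)) {
    stop("means must be finite and strictly positive", call. = FALSE)
  }
  log(mean_treatment / mean_control)
}

#' Percentage change implied by a log response ratio
#'
#' Transforms the log-scale effect to the reported scale:
#' `(r - 1) * 100` where `r = exp(ln_r)`. A log ratio of `log(0.53)`
#' reports as -47%.
#'
#' @param ln_r Numeric vector of log response ratios.
#' @return Percentage change; always greater than -100.
#' @export
percent_change <- function(ln_r) {
  expm1(ln_r) * 100
}

#' Validate a field-observation table
#'
#' Checks the schema and closed vocabularies and excludes records whose
#' reported means are non-positive (logged via a warning naming the rows),
#' since the log response ratio is undefined for them.
#'
#' @param observations Data frame with at least `measure`, `outcome`,
#'   `mean_treatment`, `mean_control`.
#' @return The validated tibble; excluded rows are attached as the
#'   `"rejected"` attribute.
#' @export
validate_observations <- function(observations) {
  need <- c("measure", "outcome", "mean_treatment", "mean_control")
  missing <- setdiff(need, names(observations))
  if (length(missing)) {
    stop("observations lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_m <- setdiff(unique(observations$measure), MEASURES)
  if (length(bad_m)) {
    stop("unknown measure label(s): ", paste(bad_m, collapse = ", "),
         call. = FALSE)
  }
  bad_o <- setdiff(unique(observations$outcome), OUTCOMES)
  if (length(bad_o)) {
    stop("unknown outcome label(s): ", paste(bad_o, collapse = ", "),
         call. = FALSE)
  }
  ok <- is.finite(observations$mean_treatment) &
    is.finite(observations$mean_control) &
    observations$mean_treatment > 0 & observations$mean_control > 0
  out <- tibble::as_tibble(observations[ok, , drop = FALSE])
  rejected <- tibble::as_tibble(observations[!ok, , drop = FALSE])
  if (nrow(rejected)) {
    warning(nrow(rejected), " observation(s) with non-positive means ",
            "excluded (rows ", paste(utils::head(which(!ok), 5),
                                     collapse = ", "),
            if (nrow(rejected) > 5) ", ..." else "", ")", call. = FALSE)
  }
  attr(out, "rejected") <- rejected
  out
}

# resampled cell means on the log scale; the RNG stream is exactly
# `sample.int(n, n * n_boot, replace = TRUE)` after `set.seed(seed)`,
# which independent re-implementations can reproduce; values are sorted
# first so the result is invariant to observation order
boot_means <- function(ln_r, n_boot, seed) {
  ln_r <- sort(ln_r)
  n <- length(ln_r)
  set.seed(seed)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  colMeans(matrix(ln_r[idx], nrow = n))
}

bc_interval <- function(bm, observed, level) {
  alpha <- (1 - level) / 2
  n_boot <- length(bm)
  # bias-correction factor with a continuity split on ties, clamped away
  # from 0/1 so qnorm stays finite
  p <- (sum(bm < observed) + 0.5 * sum(bm == observed)) / n_boot
  p <- min(max(p, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
  z0 <- stats::qnorm(p)
  probs <- stats::pnorm(2 * z0 + stats::qnorm(c(alpha, 1 - alpha)))
  unname(stats::quantile(bm, probs))
}

#' Bootstrap the mean effect of one measure-by-outcome cell
#'
#' Computes the unweighted mean log response ratio of the cell and a
#' bootstrap confidence interval from `n_boot` resamples (with replacement,
#' resampling individual observations), both reported on the percentage
#' scale. Effects are unweighted because field studies often omit variances
#' and replication counts. The default interval is the bias-corrected
#' percentile bootstrap; a plain percentile interval is available. An
#' effect is flagged significant when the interval excludes zero.
#'
#' @param observations Observations of a single measure-by-outcome cell.
#' @param n_boot Number of bootstrap iterations (default 4999).
#' @param seed Integer seed; the resample stream is fully determined by it.
#' @param ci_level Confidence level (default 0.95).
#' @param ci_type `"bc"` (bias-corrected percentile, default) or
#'   `"percentile"`.
#' @return One-row tibble: `measure`, `outcome`, `n_obs`,
#'   `mean_pct_change`, `ci_low`, `ci_high`, `n_boot`, `seed`,
#'   `significant`, `degenerate`. With a single observation (or zero
#'   spread) the interval collapses to the point estimate and `degenerate`
#'   is set.
#' @export
bootstrap_effect <- function(observations, n_boot = 4999L, seed,
                             ci_level = 0.95,
                             ci_type = c("bc", "percentile")) {
  ci_type <- match.arg(ci_type)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (nrow(observations) == 0L) {
    stop("no observations in cell", call. = FALSE)
  }
  if (length(unique(observations$measure)) > 1L ||
      length(unique(observations$outcome)) > 1L) {
    stop("all observations must share one measure and one outcome",
         call. = FALSE)
  }
  ln_r <- log_response_ratio(observations$mean_treatment,
                             observations$mean_control)
  point_ln <- mean(ln_r)
  n <- length(ln_r)

  degenerate <- n == 1L || stats::sd(ln_r) == 0
  if (degenerate) {
    ci_ln <- c(point_ln, point_ln)
  } else {
    bm <- boot_means(ln_r, n_boot, seed)
    ci_ln <- if (ci_type == "bc") {
      bc_interval(bm, point_ln, ci_level)
    } else {
      alpha <- (1 - ci_level) / 2
      unname(stats::quantile(bm, c(alpha, 1 - alpha)))
    }
  }

  ci <- percent_change(ci_ln)
  est <- percent_change(point_ln)
  tibble::tibble(
    measure = observations$measure[1],
    outcome = observations$outcome[1],
    n_obs = n,
    mean_pct_change = est,
    ci_low = ci[1],
    ci_high = ci[2],
    n_boot = as.integer(n_boot),
    seed = as.integer(seed),
    significant = !(ci[1] <= 0 && ci[2] >= 0),
    degenerate = degenerate
  )
}

#' Effect estimates for every populated measure-by-outcome cell
#'
#' Runs [bootstrap_effect()] on each non-empty cell of the observation
#' table. Cells are processed in a fixed order (measures, then outcomes, in
#' vocabulary order) with per-cell seeds derived deterministically from the
#' root seed, so the full table is bit-identical across runs.
#'
#' @param observations A validated observation table (see
#'   [validate_observations()]).
#' @param n_boot,ci_level,ci_type Passed to [bootstrap_effect()].
#' @param seed Root seed for the whole table.
#' @return Tibble of effect estimates, one row per populated cell.
#' @export
effect_table <- function(observations, n_boot = 4999L, seed,
                         ci_level = 0.95, ci_type = c("bc", "percentile")) {
  ci_type <- match.arg(ci_type)
  observations <- validate_observations(observations)
  cells <- dplyr::distinct(observations, .data$measure, .data$outcome)
  cells <- cells[order(match(cells$measure, MEASURES),
                       match(cells$outcome, OUTCOMES)), ]
  base <- stage_seed(seed, "meta")
  purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    cell <- observations[observations$measure == cells$measure[i] &
                           observations$outcome == cells$outcome[i], ]
    bootstrap_effect(cell, n_boot = n_boot,
                     seed = (base + i) %% 2147483647L,
                     ci_level = ci_level, ci_type = ci_type)
  })
}

#' Calibration of the bootstrap interval and significance rule
#'
#' Simulates many synthetic measure-by-outcome cells with a known true log
#' response ratio and Gaussian log-scale noise, runs [bootstrap_effect()]
#' on each, and reports how often the confidence interval covers the truth
#' and how often the zero-overlap rule declares significance. With a true
#' effect of zero the significance rate is the empirical type-I error of
#' the rule.
#'
#' @param n_datasets Number of simulated cells.
#' @param n_obs Observations per cell.
#' @param true_log_rr True mean log response ratio.
#' @param noise_sd Log-scale noise standard deviation.
#' @param n_boot Bootstrap iterations per cell.
#' @param seed Root seed for data generation and all resample streams.
#' @param ci_type Interval variant, as in [bootstrap_effect()].
#' @return List: `coverage` (fraction of intervals containing the true
#'   percentage change), `significance_rate`, `true_pct` and the per-cell
#'   `estimates` table.
#' @export
bootstrap_calibration <- function(n_datasets = 500L, n_obs = 50L,
                                  true_log_rr = log(0.7), noise_sd = 0.2,
                                  n_boot = 999L, seed,
                                  ci_type = c("bc", "percentile")) {
  ci_type <- match.arg(ci_type)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  withr::with_seed(stage_seed(seed, "meta"), {
    data <- matrix(stats::rnorm(n_datasets * n_obs, true_log_rr, noise_sd),
                   nrow = n_obs)
    cell_seeds <- sample.int(2147483646L, n_datasets)
  })
  ests <- purrr::map_dfr(seq_len(n_datasets), function(i) {
    obs <- tibble::tibble(
      measure = "EEF", outcome = "total_N_loss",
      mean_treatment = exp(data[, i]), mean_control = 1
    )
    bootstrap_effect(obs, n_boot = n_boot, seed = cell_seeds[i],
                     ci_type = ci_type)
  })
  true_pct <- percent_change(true_log_rr)
  list(
    coverage = mean(ests$ci_low <= true_pct & true_pct <= ests$ci_high),
    significance_rate = mean(ests$significant),
    true_pct = true_pct,
    estimates = ests
  )
}

#' Derive measure specifications from meta-analysis effects
#'
#' Maps each measure's mean percentage changes to the inputs of the
#' mitigation stage: for every loss pathway, the abatement efficacy is
#' `eta = -mean_pct_change / 100`, clipped to \[0, 1\] (a -47% change on
#' total N loss gives 0.47); pollution-increasing effects are clipped to 0
#' and surfaced in the `"tradeoffs"` attribute rather than producing
#' negative efficacy. Yield and NUE changes are carried as multiplicative
#' factors. A measure missing a pathway estimate gets efficacy 0 with a
#' warning.
#'
#' @param effects Effect table from [effect_table()].
#' @return Tibble with columns `measure`, `tier`, `eta_<pathway>`,
#'   `yield_multiplier`, `nue_multiplier`; pollution-increasing cells are
#'   attached as attribute `"tradeoffs"`.
#' @export
efficacy_from_effects <- function(effects) {
  stopifnot(all(c("measure", "outcome", "mean_pct_change") %in%
                  names(effects)))
  measures <- unique(effects$measure)
  measures <- measures[order(match(measures, MEASURES))]

  tradeoffs <- effects[effects$outcome %in% LOSS_OUTCOMES &
                         effects$mean_pct_change > 0, ]
  missing_cells <- character()

  out <- purrr::map_dfr(measures, function(m) {
    sub <- effects[effects$measure == m, ]
    row <- tibble::tibble(measure = m, tier = unname(MEASURE_TIERS[m]))
    for (p in PATHWAYS) {
      pc <- sub$mean_pct_change[sub$outcome == p]
      if (length(pc) == 0L) {
        missing_cells <<- c(missing_cells, paste(m, p, sep = ":"))
        pc <- 0
      }
      row[[paste0("eta_", p)]] <- min(max(-pc[1] / 100, 0), 1)
    }
    ymult <- sub$mean_pct_change[sub$outcome == "yield"]
    nmult <- sub$mean_pct_change[sub$outcome == "NUE"]
    row$yield_multiplier <- 1 + (if (length(ymult)) ymult[1] else 0) / 100
    row$nue_multiplier <- 1 + (if (length(nmult)) nmult[1] else 0) / 100
    row
  })
  if (length(missing_cells)) {
    warning("no effect estimate for ", length(missing_cells),
            " measure:pathway cell(s); efficacy set to 0 (",
            paste(utils::head(missing_cells, 5), collapse = ", "),
            if (length(missing_cells) > 5) ", ..." else "", ")",
            call. = FALSE)
  }
  attr(out, "tradeoffs") <- tibble::as_tibble(tradeoffs)
  out
}
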