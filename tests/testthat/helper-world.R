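# Shared fixtures, all built in code.

# one-region budget with round numbers for hand-checked chains:
# input 100 = fer 60 + man 20 + fix 10 + dep 8 + irr 2
# output 100 = harvest 50 + gases (15 + 3 + 2 + 10) + leach 12 + runoff 8
toy_budget <- function() {
  tibble::tibble(
    region = "T", year = 2015L,
    n_fer = 60, n_man = 20, n_fix = 10, n_dep = 8, n_irr = 2,
    n_harvest = 50,
    e_nh3 = 15, e_n2o = 3, e_nox = 2, e_n2 = 10,
    n_leach = 12, n_runoff = 8,
    area = 1000
  )
}

toy_measure <- function(measure = "EEF", tier = 1L,
                        eta = c(NH3 = 0.4, NOx = 0.2, N2O = 0.3,
                                leaching = 0.5, runoff = 0.1),
                        yield_multiplier = 1.1, nue_multiplier = 1.1) {
  row <- tibble::tibble(measure = measure, tier = tier)
  for (p in names(eta)) row[[paste0("eta_", p)]] <- eta[[p]]
  row$yield_multiplier <- yield_multiplier
  row$nue_multiplier <- nue_multiplier
  row
}

toy_econ <- function(regions = c("T", "USA")) {
  pathways <- pathway_vocabulary()
  reg <- tibble::tibble(
    region = regions,
    uc = 2, wtp = ifelse(regions == "USA", 100, 50),
    pgdp = ifelse(regions == "USA", 60000, 30000),
    crop_price = 3, fertilizer_price = 1
  )
  dmg <- tidyr::expand_grid(region = regions, pathway = pathways)
  dmg$hcost <- c(NH3 = 20, NOx = 15, N2O = 1, leaching = 2,
                 runoff = 2)[dmg$pathway]
  dmg$ccost <- c(NH3 = -2, NOx = -1.5, N2O = 12, leaching = 0,
                 runoff = 0)[dmg$pathway]
  structure(list(
    regions = reg, damage = dmg,
    eco_unit_cost = tibble::tibble(pathway = pathways,
                                   cost = c(10, 12, 4, 8, 8)),
    reference_region = "USA"
  ), class = "econ_params")
}

# observations of a single cell with a known log response ratio and noise
make_cell <- function(n, log_rr, noise_sd, seed,
                      measure = "EEF", outcome = "total_N_loss") {
  withr::with_seed(seed, {
    ctrl <- stats::rlnorm(n, log(50), 0.5)
    noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else rep(0, n)
    tibble::tibble(
      study_id = sprintf("S%02d", seq_len(n)),
      measure = measure, sub_treatment = "default", outcome = outcome,
      mean_treatment = ctrl * exp(log_rr + noise),
      mean_control = ctrl, region = "T"
    )
  })
}

# independent re-implementation of the combination rules, used as the
# brute-force oracle: fraction abated on pathway p by measure set `sel`
oracle_fraction <- function(sel, measures, x, inter, p) {
  col <- paste0("eta_", p)
  used <- character()
  f <- 0
  if (!is.null(inter) && nrow(inter)) {
    for (i in seq_len(nrow(inter))) {
      a <- inter$measure_a[i]; b <- inter$measure_b[i]
      if (a %in% sel && b %in% sel) {
        f <- f + inter[[col]][i] * max(x[[a]], x[[b]])
        used <- c(used, a, b)
      }
    }
  }
  for (m in setdiff(sel, used)) {
    f <- f + measures[[col]][measures$measure == m] * x[[m]]
  }
  min(f, 1)
}

oracle_post_nue <- function(b, sel, measures, x, inter, target_harvest) {
  pw <- pathway_vocabulary()
  cols <- c(NH3 = "e_nh3", NOx = "e_nox", N2O = "e_n2o",
            leaching = "n_leach", runoff = "n_runoff")
  base <- vapply(pw, function(p) b[[cols[[p]]]], numeric(1))
  frac <- vapply(pw, function(p) oracle_fraction(sel, measures, x, inter, p),
                 numeric(1))
  gas <- c("NH3", "NOx", "N2O")
  gfrac <- if (sum(base[gas]) > 0) sum((base * frac)[gas]) / sum(base[gas])
    else 0
  hm <- 1
  for (m in sel) {
    hm <- hm * (1 + (measures$yield_multiplier[measures$measure == m] - 1) *
                  x[[m]])
  }
  h <- min(b$n_harvest * hm, target_harvest)
  h / (h + sum(base * (1 - frac)) + b$e_n2 * (1 - gfrac))
}

# independent re-implementation of the resample stream and both interval
# variants, used as the bootstrap oracle
oracle_bootstrap <- function(ln_r, n_boot, seed, level = 0.95,
                             type = "bc") {
  ln_r <- sort(ln_r)
  n <- length(ln_r)
  set.seed(seed)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  bm <- colMeans(matrix(ln_r[idx], nrow = n))
  alpha <- (1 - level) / 2
  if (type == "percentile") {
    ci <- unname(stats::quantile(bm, c(alpha, 1 - alpha)))
  } else {
    obs <- mean(ln_r)
    p <- (sum(bm < obs) + 0.5 * sum(bm == obs)) / n_boot
    p <- min(max(p, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
    z0 <- stats::qnorm(p)
    ci <- unname(stats::quantile(bm,
                                 stats::pnorm(2 * z0 +
                                                stats::qnorm(c(alpha,
                                                               1 - alpha)))))
  }
  list(mean_pct = expm1(mean(ln_r)) * 100, ci_pct = expm1(ci) * 100)
}
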