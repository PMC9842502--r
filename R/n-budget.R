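#' Cropland nitrogen budget accounting
#'
#' A regional cropland N budget is a row per region and year with five
#' input fluxes (fertilizer `n_fer`, manure `n_man`, biological fixation
#' `n_fix`, atmospheric deposition `n_dep`, irrigation `n_irr`), harvested
#' crop N (`n_harvest`), four gaseous emissions (`e_nh3`, `e_n2o`, `e_nox`,
#' `e_n2`), leaching (`n_leach`), runoff (`n_runoff`) and cropland `area`.
#' All fluxes are kt N/yr; areas are kha. Soil N stock change carries no
#' term: input-output closure is a convention of the synthetic generator
#' and is only flagged, never enforced, on user budgets.
#'
#' @name n_budget
NULL

BUDGET_INPUT_COLS <- c("n_fer", "n_man", "n_fix", "n_dep", "n_irr")
BUDGET_GAS_COLS <- c("e_nh3", "e_n2o", "e_nox", "e_n2")
BUDGET_LOSS_COLS <- c(BUDGET_GAS_COLS, "n_leach", "n_runoff")
BUDGET_FLUX_COLS <- c(BUDGET_INPUT_COLS, "n_harvest", BUDGET_LOSS_COLS)

# maps loss pathway labels to budget columns (N2 deliberately absent:
# it is not a reactive loss)
PATHWAY_COLS <- c(NH3 = "e_nh3", NOx = "e_nox", N2O = "e_n2o",
                  leaching = "n_leach", runoff = "n_runoff")

#' Validate a budget table
#'
#' @param budgets Data frame of regional budgets.
#' @return The budgets as a tibble; errors on missing columns or negative
#'   fluxes.
#' @export
validate_budgets <- function(budgets) {
  need <- c("region", BUDGET_FLUX_COLS)
  missing <- setdiff(need, names(budgets))
  if (length(missing)) {
    stop("budgets lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in BUDGET_FLUX_COLS) {
    if (any(!is.finite(budgets[[col]]) | budgets[[col]] < 0)) {
      bad <- which(!is.finite(budgets[[col]]) | budgets[[col]] < 0)
      stop("negative or non-finite `", col, "` in region(s) ",
           paste(budgets$region[utils::head(bad, 5)], collapse = ", "),
           call. = FALSE)
    }
  }
  tibble::as_tibble(budgets)
}

#' Total N input to cropland
#'
#' Sum of the five input fluxes: fertilizer, manure, fixation, deposition
#' and irrigation.
#'
#' @param budgets Validated budget table.
#' @return Numeric vector, kt N/yr, one value per row.
#' @export
#' @examples
#' b <- generate_budgets(synth_config(seed = 1, n_regions = 2))
#' total_input(b)
total_input <- function(budgets) {
  budgets <- validate_budgets(budgets)
  rowSums(as.matrix(budgets[BUDGET_INPUT_COLS]))
}

#' Total N output from cropland
#'
#' Harvested N plus all gaseous emissions (NH3, N2O, NOx, N2), leaching and
#' runoff.
#'
#' @inheritParams total_input
#' @return Numeric vector, kt N/yr.
#' @export
total_output <- function(budgets) {
  budgets <- validate_budgets(budgets)
  rowSums(as.matrix(budgets[c("n_harvest", BUDGET_LOSS_COLS)]))
}

#' Nitrogen use efficiency
#'
#' Harvested crop N divided by total N input.
#'
#' @inheritParams total_input
#' @return Numeric vector of fractions; errors when any region has zero
#'   total input.
#' @export
nue <- function(budgets) {
  inp <- total_input(budgets)
  if (any(inp <= 0)) {
    stop("zero total N input in region(s) ",
         paste(budgets$region[inp <= 0], collapse = ", "),
         "; NUE undefined", call. = FALSE)
  }
  budgets$n_harvest / inp
}

#' Target N input implied by a harvest target and target NUE
#'
#' @param targets Data frame with columns `region`, `target_harvest`
#'   (kt N/yr) and `nue_target` (fraction in (0, 1]).
#' @return Numeric vector: `target_harvest / nue_target` per region.
#' @export
target_input <- function(targets) {
  stopifnot(all(c("region", "nue_target", "target_harvest") %in%
                  names(targets)))
  if (any(targets$nue_target <= 0 | targets$nue_target > 1)) {
    stop("`nue_target` must lie in (0, 1]", call. = FALSE)
  }
  if (any(targets$target_harvest < 0)) {
    stop("`target_harvest` must be >= 0", call. = FALSE)
  }
  targets$target_harvest / targets$nue_target
}

#' N input surplus relative to the target input
#'
#' Signed difference between the current and target total N input. Positive
#' values flag overuse ("too much" regions); negative values flag regions
#' that should increase N input to meet their harvest target ("too little"
#' regions).
#'
#' @param budgets Validated budget table.
#' @param targets Target table (see [target_input()]); matched by `region`.
#' @return Numeric vector, kt N/yr, aligned with `budgets` rows.
#' @export
input_surplus <- function(budgets, targets) {
  ti <- target_input(targets)
  idx <- match(budgets$region, targets$region)
  if (anyNA(idx)) {
    stop("no target for region(s) ",
         paste(budgets$region[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  total_input(budgets) - ti[idx]
}

#' Per-region budget summary
#'
#' @param budgets Validated budget table.
#' @param targets Optional target table; adds target input and surplus.
#' @param closure_tol Relative tolerance beyond which a budget is flagged
#'   as non-closed (input != output); non-closure is a warning-level flag,
#'   not an error.
#' @return Tibble with `region`, `input`, `output`, `nue`, `closed` and,
#'   when targets are given, `target_input` and `surplus`.
#' @export
budget_summary <- function(budgets, targets = NULL, closure_tol = 1e-6) {
  budgets <- validate_budgets(budgets)
  inp <- total_input(budgets)
  out <- total_output(budgets)
  res <- tibble::tibble(
    region = budgets$region,
    input = inp,
    output = out,
    nue = nue(budgets),
    closed = abs(inp - out) <= closure_tol * pmax(inp, 1)
  )
  if (!is.null(targets)) {
    res$target_input <- target_input(targets)[match(res$region,
                                                    targets$region)]
    res$surplus <- res$input - res$target_input
  }
  res
}
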