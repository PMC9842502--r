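#' Controlled vocabularies for measures, outcomes and loss pathways
#'
#' The analysis recognises 11 field management measures grouped into three
#' tiers of increasing implementation difficulty, eight outcome variables
#' measured in field trials, and five reactive-nitrogen loss pathways.
#' These vocabularies are closed: every observation, efficacy entry and
#' adoption record must use them.
#'
#' @name vocabularies
#' @keywords internal
NULL

# the 11 measures with their tier assignment (1 = cheap/easy additive
# measures, 2 = 4R nutrient stewardship, 3 = knowledge/capital intensive)
MEASURE_TIERS <- c(
  EEF                  = 1L,
  organic_amendment    = 1L,
  legume_rotation      = 1L,
  buffer_zone          = 1L,
  fertilizer_rate      = 2L,
  fertilizer_type      = 2L,
  fertilizer_timing    = 2L,
  fertilizer_placement = 2L,
  new_cultivar         = 3L,
  tillage              = 3L,
  irrigation           = 3L
)

MEASURES <- names(MEASURE_TIERS)

# Nr loss pathways monetized per unit mass; N2 is tracked separately because
# its reduction is not an environmental improvement
PATHWAYS <- c("NH3", "NOx", "N2O", "leaching", "runoff")

OUTCOMES <- c(PATHWAYS, "total_N_loss", "yield", "NUE")

LOSS_OUTCOMES <- c(PATHWAYS, "total_N_loss")

#' List the recognised mitigation measures
#'
#' @return A tibble with columns `measure` and `tier`.
#' @export
#' @examples
#' measure_catalogue()
measure_catalogue <- function() {
  tibble::tibble(measure = MEASURES, tier = unname(MEASURE_TIERS))
}

#' List the recognised outcome variables
#'
#' @return Character vector of outcome labels: the five Nr loss pathways
#'   (`NH3`, `NOx`, `N2O`, `leaching`, `runoff`), `total_N_loss`, `yield`
#'   and `NUE`.
#' @export
outcome_vocabulary <- function() OUTCOMES

#' List the reactive-nitrogen loss pathways
#'
#' @return Character vector of the five monetized loss forms.
#' @export
pathway_vocabulary <- function() PATHWAYS

# derive a per-stage RNG seed from one root seed so that every stage of a
# run is reproducible from a single integer (kept below 2^31 - 1)
stage_seed <- function(seed, stage) {
  stages <- c(
    observations = 11L, budgets = 23L, econ = 37L, measures = 41L,
    adoption = 43L, meta = 53L, cba = 59L, scenario = 61L, draws = 67L
  )
  if (!stage %in% names(stages)) {
    stop("unknown stage '", stage, "'", call. = FALSE)
  }
  as.integer((as.numeric(seed) * 1009 + stages[[stage]]) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a finite number", call. = FALSE)
  }
  if (strict_min && x <= min) {
    stop("`", name, "` must be > ", min, call. = FALSE)
  }
  if (!strict_min && x < min) {
    stop("`", name, "` must be >= ", min, call. = FALSE)
  }
  invisible(x)
}
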