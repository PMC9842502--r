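#' Configure a pipeline run
#'
#' One object carries everything a run needs: the root seed (every stage
#' derives its own stream from it), iteration counts, the input table
#' paths and the output directory. Every run writes a manifest capturing
#' the configuration and the md5 hash of each input, which is sufficient
#' to reproduce it.
#'
#' @param seed Root seed.
#' @param n_boot Bootstrap iterations for the meta-analysis stage.
#' @param n_draws Monte-Carlo draws for the uncertainty stage.
#' @param input_dir Directory holding the input CSV tables (and where the
#'   `synth` stage writes them).
#' @param out_dir Output directory.
#' @param strict Literal fertilizer clamp mode.
#' @param synth Optional [synth_config()] used by the `synth` stage;
#'   defaults to `synth_config(seed = seed)`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed, n_boot = 4999L, n_draws = 1000L,
                       input_dir, out_dir, strict = FALSE, synth = NULL) {
  assert_scalar_number(seed, "seed")
  structure(list(
    seed = as.integer(seed),
    n_boot = as.integer(n_boot),
    n_draws = as.integer(n_draws),
    input_dir = input_dir,
    out_dir = out_dir,
    strict = isTRUE(strict),
    synth = synth %||% synth_config(seed = seed)
  ), class = "run_config")
}

table_path <- function(dir, name) file.path(dir, paste0(name, ".csv"))

read_table <- function(path) {
  if (!file.exists(path)) {
    stop("input table not found: ", path, call. = FALSE)
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Validate the input tables of a run
#'
#' Checks each table's schema, closed vocabularies and invariants.
#' Problems are classified as errors (schema violations, vocabulary
#' breaches, negative fluxes, non-positive means) or warnings (a user
#' budget that does not close input = output, which is legitimate for real
#' data).
#'
#' @param paths Named character vector or list of file paths; recognised
#'   names are `observations`, `budgets`, `targets`, `measures`,
#'   `adoption`, `econ`, `interactions`.
#' @return Tibble `table`, `level` (`"error"`/`"warning"`), `message`;
#'   zero rows means everything passed.
#' @export
validate_tables <- function(paths) {
  report <- list()
  note <- function(table, level, message) {
    report[[length(report) + 1L]] <<- tibble::tibble(
      table = table, level = level, message = message)
  }
  get <- function(name) {
    p <- paths[[name]]
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) {
      note(name, "error", paste("file not found:", p))
      return(NULL)
    }
    tryCatch(read_table(p), error = function(e) {
      note(name, "error", conditionMessage(e))
      NULL
    })
  }

  obs <- get("observations")
  if (!is.null(obs)) {
    tryCatch(
      withCallingHandlers(
        validate_observations(obs),
        warning = function(w) {
          note("observations", "error", conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) note("observations", "error",
                               conditionMessage(e)))
  }

  bud <- get("budgets")
  if (!is.null(bud)) {
    tryCatch({
      b <- validate_budgets(bud)
      s <- budget_summary(b)
      if (any(!s$closed)) {
        note("budgets", "warning",
             paste("budget not closed (input != output) for region(s):",
                   paste(s$region[!s$closed], collapse = ", ")))
      }
    }, error = function(e) note("budgets", "error", conditionMessage(e)))
  }

  tgt <- get("targets")
  if (!is.null(tgt)) {
    tryCatch(target_input(tgt),
             error = function(e) note("targets", "error",
                                      conditionMessage(e)))
  }

  mea <- get("measures")
  if (!is.null(mea)) {
    need <- c("measure", "tier", paste0("eta_", PATHWAYS))
    missing <- setdiff(need, names(mea))
    if (length(missing)) {
      note("measures", "error",
           paste("missing column(s):", paste(missing, collapse = ", ")))
    } else {
      bad <- setdiff(mea$measure, MEASURES)
      if (length(bad)) {
        note("measures", "error",
             paste("unknown measure label(s):", paste(bad, collapse = ", ")))
      }
      etas <- as.matrix(mea[paste0("eta_", PATHWAYS)])
      if (any(etas < 0 | etas > 1)) {
        note("measures", "error", "efficacies outside [0, 1]")
      }
    }
  }

  ado <- get("adoption")
  if (!is.null(ado)) {
    if (!all(c("region", "measure", "X") %in% names(ado))) {
      note("adoption", "error", "needs columns region, measure, X")
    } else if (any(ado$X < 0 | ado$X > 1)) {
      note("adoption", "error", "implementation rates outside [0, 1]")
    }
  }

  eco <- get("econ")
  if (!is.null(eco)) {
    tryCatch(econ_params_from_table(eco),
             error = function(e) note("econ", "error", conditionMessage(e)))
  }

  if (length(report)) dplyr::bind_rows(report) else {
    tibble::tibble(table = character(), level = character(),
                   message = character())
  }
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, reading the input
#' tables from `config$input_dir`, writing every intermediate table as CSV
#' under `config$out_dir` and finishing with a `manifest.json` (config plus
#' input-file hashes). With identical config and inputs the outputs are
#' bit-identical.
#'
#' Stages: `synth` generates all input tables; `meta` estimates the effect
#' table and derives measure efficacies from it (later stages then use
#' those estimates instead of `measures.csv`); `budget` summarises the
#' regional budgets; `mitigate` combines measures and applies them;
#' `cba` monetizes the outcome and propagates uncertainty; `scenario`
#' projects the four tier scenarios to 2050.
#'
#' @param config A [run_config()].
#' @param stages Subset of
#'   `c("synth", "meta", "budget", "mitigate", "cba", "scenario")`.
#' @return Invisibly, a named list with the in-memory results of each
#'   stage.
#' @export
run_pipeline <- function(config,
                         stages = c("synth", "meta", "budget", "mitigate",
                                    "cba", "scenario")) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("synth", "meta", "budget", "mitigate", "cba", "scenario")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  out <- list()
  emit <- function(tbl, name) {
    readr::write_csv(tbl, table_path(config$out_dir, name))
    tbl
  }

  if ("synth" %in% stages) {
    write_synthetic_tables(config$synth, config$input_dir)
  }

  in_tbl <- function(name) read_table(table_path(config$input_dir, name))
  report <- validate_tables(stats::setNames(
    as.list(table_path(config$input_dir,
                       c("observations", "budgets", "targets", "measures",
                         "adoption", "econ"))),
    c("observations", "budgets", "targets", "measures", "adoption",
      "econ")))
  if (any(report$level == "error")) {
    stop("input validation failed:\n",
         paste(report$table[report$level == "error"],
               report$message[report$level == "error"],
               sep = ": ", collapse = "\n"), call. = FALSE)
  }

  budgets <- in_tbl("budgets")
  targets <- in_tbl("targets")
  adoption <- in_tbl("adoption")
  econ <- econ_params_from_table(in_tbl("econ"))
  interactions <- tryCatch(in_tbl("interactions"), error = function(e) NULL)
  measures <- in_tbl("measures")

  if ("meta" %in% stages) {
    obs <- validate_observations(in_tbl("observations"))
    effects <- effect_table(obs, n_boot = config$n_boot,
                            seed = config$seed)
    out$effects <- emit(effects, "effects")
    measures <- efficacy_from_effects(effects)
    out$measures_estimated <- emit(measures, "measures_estimated")
  }

  if ("budget" %in% stages) {
    out$budget_summary <- emit(budget_summary(budgets, targets),
                               "budget_summary")
  }

  world <- assessment_world(budgets, measures, adoption, econ,
                            interactions = interactions, targets = targets,
                            strict = config$strict)

  if (any(c("mitigate", "cba") %in% stages)) {
    run <- evaluate_world(world)
    if ("mitigate" %in% stages) {
      out$reductions <- emit(run$combined$reductions, "reductions")
      deltas <- attr(run$post_budgets, "deltas")
      out$post_budgets <- emit(run$post_budgets, "post_budgets")
      out$deltas <- emit(deltas, "deltas")
    }
    if ("cba" %in% stages) {
      out$cba <- emit(run$cba, "cba")
      unc <- propagate_uncertainty(world, n_draws = config$n_draws,
                                   seed = config$seed)
      out$cba_uncertainty <- emit(unc$summary, "cba_uncertainty")
    }
  }

  if ("scenario" %in% stages) {
    # demand: linear growth of required harvest N to 1.3x by the horizon
    demand <- dplyr::bind_rows(
      tibble::tibble(region = budgets$region, year = 2015L,
                     harvest = budgets$n_harvest),
      tibble::tibble(region = budgets$region, year = 2050L,
                     harvest = budgets$n_harvest * 1.3)
    )
    traj <- purrr::map_dfr(names(SCENARIO_TIER_MAX), function(nm) {
      project(budgets, scenario_spec(nm, demand), measures, adoption,
              targets, econ = econ)
    })
    out$trajectories <- emit(traj, "trajectories")
  }

  in_files <- list.files(config$input_dir, pattern = "\\.csv$",
                         full.names = TRUE)
  manifest <- list(
    config = list(seed = config$seed, n_boot = config$n_boot,
                  n_draws = config$n_draws, strict = config$strict,
                  stages = stages),
    inputs = as.list(tools::md5sum(in_files))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}
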