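# End-to-end orchestration: simulate (optional) -> categorise -> prep ->
# six ST-GPR fits -> rake -> aggregate -> summarise -> decompose, with one
# config, deterministic seeding, a run manifest and tabular outputs.

#' Default run configuration
#'
#' @param out_dir Output directory.
#' @param seed Root seed; all stage sub-streams derive from it.
#' @param n_draws Posterior (and envelope) draws.
#' @param simulate Generate the synthetic world (TRUE) or read inputs from
#'   `input_dir` (expects the files written by [emit_fixtures()]).
#' @param input_dir Directory of input CSVs when `simulate = FALSE`.
#' @param sim Named list of overrides passed to [sim_config()].
#' @param categorize Named list: `rulebook_path` (NULL for the default) and
#'   `csec_min_count`.
#' @param prep Named list: `offset`, `variance_inflation`.
#' @param stgpr Named list of overrides passed to [stgpr_config()].
#' @param years Modelled years.
#' @param decompose_years Length-2 years for the change decomposition.
#' @param table_year Year of the formatted report table.
#' @return Nested configuration list.
#' @export
default_run_config <- function(out_dir = tempfile("facmix_run_"),
                               seed = 1L, n_draws = 100,
                               simulate = TRUE, input_dir = NULL,
                               sim = list(), categorize = list(),
                               prep = list(), stgpr = list(),
                               years = 1995:2023,
                               decompose_years = c(1995, 2023),
                               table_year = 2023) {
  list(
    out_dir = out_dir, seed = as.integer(seed), n_draws = as.integer(n_draws),
    simulate = simulate, input_dir = input_dir,
    sim = sim,
    categorize = utils::modifyList(
      list(rulebook_path = NULL, csec_min_count = 25), categorize
    ),
    prep = utils::modifyList(
      list(offset = 1e-4, variance_inflation = 1), prep
    ),
    stgpr = stgpr,
    years = years, decompose_years = decompose_years, table_year = table_year
  )
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the defaults of
#' [default_run_config()]; everything else keeps its default.
#'
#' @param path Path to a YAML file.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(raw)) {
    if (nm %in% c("sim", "categorize", "prep", "stgpr") && is.list(raw[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], raw[[nm]])
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  if (!is.null(raw$years) && length(raw$years) == 2) {
    cfg$years <- raw$years[1]:raw$years[2]
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_draws <- as.integer(cfg$n_draws)
  cfg
}

read_world_inputs <- function(dir) {
  need <- c(
    hierarchy = "hierarchy.csv", births = "births.csv",
    covariates = "covariates.csv", envelope = "envelope.csv",
    microdata = "microdata.csv"
  )
  paths <- file.path(dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "missing input file(s) in '", dir, "': ", paste(missing, collapse = ", ")
    ))
  }
  world <- list(
    hierarchy = readr::read_csv(paths[1], show_col_types = FALSE),
    births = readr::read_csv(paths[2], show_col_types = FALSE),
    covariates = tidyr::pivot_wider(
      readr::read_csv(paths[3], show_col_types = FALSE),
      names_from = "name", values_from = "value"
    ),
    envelope = readr::read_csv(paths[4], show_col_types = FALSE),
    microdata = readr::read_csv(paths[5], show_col_types = FALSE)
  )
  truth_path <- file.path(dir, "truth.csv")
  if (file.exists(truth_path)) {
    world$truth <- readr::read_csv(truth_path, show_col_types = FALSE)
  }
  world
}

#' Run the full estimation pipeline
#'
#' Executes every stage on one configuration and writes all outputs (input
#' fixtures when simulating, option assignments, prepared data, indicator
#' draws, composition summaries at country and aggregate level, the
#' formatted report table, the change decomposition, and a JSON manifest
#' with the config hash, seed, per-stage row counts and collected
#' warnings). Re-running with the same config reproduces identical outputs.
#'
#' @param config See [default_run_config()] / [read_run_config()].
#' @return The manifest, invisibly (list; also written as
#'   `manifest.json`).
#' @export
run_all <- function(config = default_run_config()) {
  warnings_log <- character(0)
  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    stages = list()
  )
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  years <- config$years

  # --- inputs -------------------------------------------------------------
  if (isTRUE(config$simulate)) {
    sim_args <- utils::modifyList(
      list(seed = config$seed, n_draws = config$n_draws, years = years),
      config$sim
    )
    world <- collect(simulate_world(do.call(sim_config, sim_args)))
    emit_fixtures(world, file.path(config$out_dir, "inputs"))
  } else {
    if (is.null(config$input_dir)) {
      rlang::abort("config$input_dir must be set when simulate = FALSE")
    }
    world <- collect(read_world_inputs(config$input_dir))
  }
  if (length(draw_cols(world$envelope)) < config$n_draws) {
    rlang::abort("envelope has fewer draws than n_draws")
  }
  manifest$stages$inputs <- list(
    microdata_rows = nrow(world$microdata),
    locations = nrow(world$hierarchy)
  )

  # --- categorize ---------------------------------------------------------
  rulebook <- if (is.null(config$categorize$rulebook_path)) {
    default_rulebook()
  } else {
    read_rulebook(config$categorize$rulebook_path)
  }
  catalogue <- world$microdata |>
    dplyr::group_by(.data$source_id, .data$location_id,
      label = .data$response_label
    ) |>
    dplyr::summarise(
      weighted_count = sum(.data$weight),
      csec_count = sum(.data$weight * .data$csec),
      .groups = "drop"
    )
  assignments <- collect(classify_options(
    catalogue, rulebook,
    csec_min_count = config$categorize$csec_min_count
  ))
  readr::write_csv(assignments, file.path(config$out_dir, "assignments.csv"))
  manifest$stages$categorize <- list(options = nrow(assignments))

  # --- prep ---------------------------------------------------------------
  micro <- world$microdata |>
    dplyr::inner_join(
      dplyr::select(
        assignments, "source_id", "location_id", "label",
        "facility_status", "level", "modelling_sector"
      ),
      by = c(
        "source_id", "location_id", "response_label" = "label"
      )
    )
  prepared <- collect(tabulate_proportions(
    micro,
    offset = config$prep$offset,
    variance_inflation = config$prep$variance_inflation
  ))
  readr::write_csv(prepared, file.path(config$out_dir, "prepared.csv"))
  manifest$stages$prep <- list(data_points = nrow(prepared))

  # --- stgpr: six indicators ---------------------------------------------
  stgpr_args <- utils::modifyList(
    list(
      n_draws = config$n_draws, offset = config$prep$offset,
      seed = config$seed
    ),
    config$stgpr
  )
  fits <- list()
  for (ind in INDICATORS) {
    flag <- if (ind %in% SECTOR_INDICATORS) {
      prepared$in_level_sector_models
    } else {
      prepared$in_level_models
    }
    idata <- prepared[prepared$indicator == ind & flag, ]
    cfg_i <- do.call(stgpr_config, utils::modifyList(
      stgpr_args, list(seed = substream_seed(config$seed, "stgpr", ind))
    ))
    fits[[ind]] <- collect(fit_stgpr(
      idata, world$covariates, world$hierarchy, cfg_i,
      years = years
    ))
    readr::write_csv(
      fits[[ind]]$draws,
      file.path(config$out_dir, paste0("draws_", ind, ".csv"))
    )
  }
  manifest$stages$stgpr <- list(
    indicators = length(fits),
    grid_rows = nrow(fits[[1]]$draws)
  )

  # --- rake + aggregate + summarise ---------------------------------------
  template <- align_draws(fits[[1]]$draws)
  meta <- dplyr::select(template, "location_id", "year")
  env <- align_draws(world$envelope, template)
  env_m <- draw_matrix(env)[, seq_len(config$n_draws), drop = FALSE]
  get_m <- function(ind) {
    draw_matrix(align_draws(fits[[ind]]$draws, template))
  }
  composition <- collect(build_composition(
    level_draws = list(hosp = get_m("hosp"), low = get_m("low")),
    sector_draws = list(
      pub_hosp = get_m("pub_hosp"), priv_hosp = get_m("priv_hosp"),
      pub_low = get_m("pub_low"), priv_low = get_m("priv_low")
    ),
    envelope = env_m, meta = meta
  ))
  aggregates <- collect(
    aggregate_regions(composition, world$hierarchy, world$births)
  )
  summary_tbl <- dplyr::bind_rows(
    summarize_composition(composition),
    summarize_composition(aggregates)
  )
  readr::write_csv(summary_tbl, file.path(config$out_dir, "summary.csv"))
  manifest$stages$rake <- list(summary_rows = nrow(summary_tbl))

  # --- report + decomposition ---------------------------------------------
  tbl <- make_table(summary_tbl, config$table_year, world$hierarchy)
  readr::write_csv(
    tbl, file.path(config$out_dir, paste0("table_", config$table_year, ".csv"))
  )
  change <- collect(decompose_change(
    aggregates, "global",
    config$decompose_years[1], config$decompose_years[2]
  ))
  change_tbl <- dplyr::bind_rows(
    dplyr::mutate(change$pp_change, measure = "pp_change"),
    dplyr::mutate(change$share_of_change, measure = "share_of_change")
  )
  readr::write_csv(
    change_tbl, file.path(config$out_dir, "change_decomposition.csv")
  )
  manifest$stages$report <- list(
    table_rows = nrow(tbl), excluded_draws = change$n_excluded
  )

  manifest$warnings <- unique(warnings_log)
  jsonlite::write_json(
    manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}

#' Format the report table for one year
#'
#' One row per country, region and the global aggregate; one column per
#' category, formatted `"mean (lower-upper)"` in percent with one decimal.
#' Full-precision values stay in `summary.csv`.
#'
#' @param summary_tbl Output of [summarize_composition()] (stacked levels).
#' @param year Report year.
#' @param hierarchy Hierarchy tibble (defines the row set and order).
#' @return Wide tibble, one formatted column per category.
#' @export
make_table <- function(summary_tbl, year, hierarchy) {
  rows <- c(
    "global",
    sort(unique(hierarchy$region_id)),
    sort(unique(hierarchy$location_id))
  )
  sub <- summary_tbl[summary_tbl$year == year & summary_tbl$location_id %in% rows, ]
  if (nrow(sub) == 0) {
    rlang::abort(paste0("no summaries available for year ", year))
  }
  sub$cell <- sprintf(
    "%.1f (%.1f-%.1f)", 100 * sub$mean, 100 * sub$lower, 100 * sub$upper
  )
  wide <- tidyr::pivot_wider(
    dplyr::select(sub, "location_id", "category", "cell"),
    names_from = "category", values_from = "cell"
  )
  wide <- wide[match(rows, wide$location_id), c("location_id", CATEGORIES)]
  wide
}
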