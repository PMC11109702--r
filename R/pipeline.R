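# Pipeline orchestration: simulate -> panel -> moves -> family ->
# descriptives -> model, with CSV/JSON outputs, a resolved-config snapshot
# and a manifest of row counts and checksums for reproducibility audits.

#' Pipeline configuration
#'
#' Defaults reproduce the analysis constants: 4 km short/long cutoff, 250 m
#' proximity radius, 5 m minimum move, survey validity 12 months forward /
#' 6 months back.
#'
#' @param seed Integer seed used for the simulation and the move tie-break.
#' @param out_dir Output directory.
#' @param sim Either a [sim_config()] or a list of arguments for one
#'   (without `seed`).
#' @param cutoff_km,radius_m,min_move_m,survey_back_months,survey_fwd_months
#'   Analysis constants.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("simulate", "panel", "moves", "family", "describe", "model")`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, out_dir = tempfile("hdssmove_run_"),
                            sim = list(), cutoff_km = 4, radius_m = 250,
                            min_move_m = 5, survey_back_months = 6,
                            survey_fwd_months = 12,
                            stages = c("simulate", "panel", "moves",
                                       "family", "describe")) {
  if (missing(seed)) config_error("seed", "a seed is mandatory")
  all_stages <- c("simulate", "panel", "moves", "family", "describe",
                  "model")
  if (!all(stages %in% all_stages))
    config_error("stages", paste("unknown stage:",
                                 setdiff(stages, all_stages)[1]))
  sim_cfg <- if (inherits(sim, "sim_config")) sim else
    do.call(sim_config, c(list(seed = seed), sim))
  structure(list(seed = as.integer(seed), out_dir = out_dir, sim = sim_cfg,
                 cutoff_km = cutoff_km, radius_m = radius_m,
                 min_move_m = min_move_m,
                 survey_back_months = survey_back_months,
                 survey_fwd_months = survey_fwd_months, stages = stages),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [pipeline_config()] arguments, with
#'   `sim` as a nested mapping.
#' @param seed Seed override (takes precedence over the file).
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  if (is.null(y$seed)) config_error("seed", "a seed is mandatory")
  if (!is.null(y$sim$period)) y$sim$period <- as.Date(unlist(y$sim$period))
  if (!is.null(y$sim$area_bounds)) y$sim$area_bounds <- unlist(y$sim$area_bounds)
  do.call(pipeline_config, y)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order, writes each stage's
#' outputs under `config$out_dir`, and returns a manifest with one row per
#' file (row count where tabular, md5 checksum) plus the exclusion ledger.
#' Identical config and seed yield identical manifest checksums.
#'
#' @param config A [pipeline_config()].
#' @return List with `manifest` (data frame), `exclusions`, and the in-memory
#'   stage outputs (`register`, `panel`, `moves`, `family_context`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  excl <- list()
  res <- list()

  snap <- config[setdiff(names(config), "sim")]
  snap$sim <- config$sim[setdiff(names(config$sim), "gazetteer")]
  snap$sim$period <- as.character(snap$sim$period)
  snap <- rapply(snap, unclass, how = "replace")
  yaml::write_yaml(snap, file.path(config$out_dir, "resolved_config.yaml"))
  files <- c(files, "resolved_config.yaml")

  run <- function(stage) stage %in% config$stages
  wr <- function(df, name) {
    utils::write.csv(df, file.path(config$out_dir, name), row.names = FALSE,
                     na = "")
    files <<- c(files, name)
  }

  if (run("simulate")) {
    res$register <- simulate_register(config$sim)
    write_register(res$register, config$out_dir)
    files <- c(files, register_files())
  } else {
    res$register <- read_register(config$out_dir,
                                  gazetteer = config$sim$gazetteer)
  }
  reg <- res$register

  if (run("panel") || run("moves") || run("family") || run("describe") ||
        run("model")) {
    res$panel <- build_panel(reg,
                             survey_back_months = config$survey_back_months,
                             survey_fwd_months = config$survey_fwd_months)
    wr(res$panel, "panel.csv")
  }
  if (run("moves") || run("describe") || run("model")) {
    raw <- detect_moves(res$panel, reg$episodes, reg, seed = config$seed,
                        min_move_m = config$min_move_m)
    res$moves <- classify_moves(raw, res$panel, reg,
                                cutoff_km = config$cutoff_km)
    excl$moves <- c(dropped_under_min = attr(raw, "n_dropped_short"),
                    tie_broken = attr(raw, "n_tie_broken"),
                    unresolved_distance = attr(res$moves, "n_unresolved"))
    wr(res$moves, "moves.csv")
    res$cutoff <- derive_distance_cutoff(reg, cutoff_km = config$cutoff_km)
    jsonlite::write_json(unclass(res$cutoff),
                         file.path(config$out_dir,
                                   "cutoff_diagnostics.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    files <- c(files, "cutoff_diagnostics.json")
  }
  if (run("family") || run("describe") || run("model")) {
    res$family_context <- build_family_context(reg, res$panel,
                                               radius_m = config$radius_m)
    wr(res$family_context, "family_context.csv")
  }
  if (run("describe")) {
    res$risk <- move_risk_by_age(res$panel, res$moves)
    wr(res$risk, "risk_curves.csv")
    res$flows <- build_flow_table(res$moves, res$panel, res$family_context)
    if (!is.null(res$flows$table)) wr(res$flows$table, "flow_tables.csv")
    for (nm in names(res$flows$sankey)) {
      fn <- sprintf("sankey_%s.json", nm)
      jsonlite::write_json(res$flows$sankey[[nm]],
                           file.path(config$out_dir, fn),
                           auto_unbox = TRUE, digits = NA)
      files <- c(files, fn)
    }
    res$accompaniment <- parent_accompaniment(res$moves, res$panel)
    if (!is.null(res$accompaniment))
      wr(res$accompaniment, "parent_accompaniment.csv")
  }
  if (run("model")) {
    res$fits <- list()
    for (sx in c("female", "male")) {
      for (stg in c("child", "adolescent")) {
        nm <- paste(sx, stg, sep = "_")
        md <- try(build_model_dataset(res$panel, res$moves,
                                      res$family_context, sx, stg),
                  silent = TRUE)
        if (inherits(md, "try-error")) next
        excl[[paste0("model_", nm)]] <- attr(md, "exclusions")
        fit <- try(fit_multinomial_multilevel(
          md, covariates = intersect(default_covariates(stg), names(md)),
          nAGQ = 0L), silent = TRUE)
        if (inherits(fit, "try-error")) next
        res$fits[[nm]] <- fit
        fn <- sprintf("fit_%s.json", nm)
        jsonlite::write_json(fit_to_list(fit),
                             file.path(config$out_dir, fn),
                             auto_unbox = TRUE, digits = NA, na = "null")
        files <- c(files, fn)
      }
    }
  }

  paths <- file.path(config$out_dir, files)
  manifest <- data.frame(
    file = files,
    rows = vapply(paths, function(f)
      if (grepl("[.]csv$", f)) length(readLines(f)) - 1L else NA_integer_,
      integer(1)),
    md5 = unname(tools::md5sum(paths)),
    stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  res$manifest <- manifest
  res$exclusions <- excl
  res
}

fit_to_list <- function(fit) {
  out <- unclass(fit)
  out$fits <- lapply(out$fits, function(f) {
    f$coefficients <- as.list(f$coefficients)
    f
  })
  out
}

register_files <- function() {
  c("persons.csv", "households.csv", "household_geo.csv", "episodes.csv",
    "surveys.csv", "marriages.csv", "gazetteer.csv")
}

#' Write a register to CSV files
#'
#' RFC-4180 CSV with ISO-8601 dates and WGS84 decimal degrees.
#'
#' @param register An `hdss_register`.
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_register <- function(register, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(persons = register$persons, households = register$households,
               household_geo = register$household_geo,
               episodes = register$episodes, surveys = register$surveys,
               marriages = register$marriages,
               gazetteer = register$gazetteer)
  paths <- file.path(dir, paste0(names(tabs), ".csv"))
  for (i in seq_along(tabs))
    utils::write.csv(tabs[[i]], paths[i], row.names = FALSE, na = "")
  invisible(paths)
}

#' Read a register from CSV files
#'
#' @param dir Directory holding the files written by [write_register()].
#' @param gazetteer Optional gazetteer override.
#' @return An `hdss_register` (without a simulation config).
#' @export
read_register <- function(dir, gazetteer = NULL) {
  rd <- function(name, dates = character(0), logicals = character(0)) {
    df <- utils::read.csv(file.path(dir, paste0(name, ".csv")),
                          stringsAsFactors = FALSE, na.strings = "")
    for (cc in intersect(dates, names(df))) df[[cc]] <- as.Date(df[[cc]])
    for (cc in intersect(logicals, names(df)))
      df[[cc]] <- as.logical(df[[cc]])
    df
  }
  reg <- list(
    persons = rd("persons", dates = c("birth_date", "death_date"),
                 logicals = "secondary_edu"),
    households = rd("households"),
    household_geo = rd("household_geo", dates = c("valid_from", "valid_to")),
    episodes = rd("episodes", dates = c("start_date", "end_date")),
    surveys = rd("surveys", dates = "survey_date",
                 logicals = c("in_primary", "mother_secondary_edu",
                              "father_secondary_edu")),
    marriages = rd("marriages", dates = c("start_date", "end_date"),
                   logicals = "polygynous"),
    gazetteer = gazetteer %||% rd("gazetteer"),
    config = NULL)
  class(reg) <- "hdss_register"
  reg
}
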