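#' Run the full flight-altitude pipeline
#'
#' One call from raw input to report bundle: read or simulate the logger
#' data, extract flight episodes, compute altitude-variation metrics,
#' detect exploratory events, ascents and descents, and - when the strata
#' allow it - fit the season-by-region comparisons. All outputs are written
#' as plain CSV/JSON plus a manifest with the configuration and file
#' checksums, so a rerun on the same inputs is byte-identical.
#'
#' @param input a [logger_dataset()], a [scenario_spec()] (simulated on the
#'   fly), or a path to a logger CSV.
#' @param out_dir output directory, created if needed.
#' @param config a [pipeline_config()].
#' @param responses metric columns to run group comparisons on.
#' @return Invisibly, a list with every table and the manifest. Files
#'   written: `episodes.csv`, `metrics.csv`, `events.csv`, `descents.csv`,
#'   `ascents.csv`, `comparisons.json`, `manifest.json` (and
#'   `simulated.csv` when the input was a scenario).
#' @export
run_pipeline <- function(input, out_dir, config = pipeline_config(),
                         responses = c("level_fraction", "mean_vz",
                                       "tortuosity")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  sim_path <- NULL
  if (inherits(input, "scenario_spec")) {
    sim <- generate_dataset(input, seed = input$seed %||% config$rng_seed %||% 1L)
    dataset <- sim$dataset
    truth <- sim$truth
    sim_path <- file.path(out_dir, "simulated.csv")
    write_logger_csv(dataset, sim_path)
  } else if (is.character(input)) {
    dataset <- read_logger_csv(input)
  } else if (inherits(input, "logger_dataset")) {
    dataset <- input
  } else stopf("input must be a logger_dataset, scenario_spec or CSV path")

  # diagnostics raised by the stages end up in the manifest, not the console
  log <- character(0)
  quietly <- function(expr) withCallingHandlers(expr, warning = function(w) {
    log <<- c(log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  episodes <- extract_flight_episodes(dataset, config)
  metrics <- quietly(flight_metrics(episodes, config))
  events <- quietly(rbind(detect_terminated_exploratory(episodes, config),
                          detect_midflight_exploratory(episodes, config)))
  descents <- extract_descents(episodes, config)
  ascents <- ascent_table(episodes, config)

  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    if (is.null(df)) df <- data.frame()
    for (cn in names(df)) if (inherits(df[[cn]], "POSIXct"))
      df[[cn]] <- format_utc(df[[cn]])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    path
  }
  paths <- c(
    wr(episode_table(episodes), "episodes.csv"),
    wr(metrics, "metrics.csv"),
    wr(events, "events.csv"),
    wr(descents, "descents.csv"),
    wr(ascents, "ascents.csv"))

  comparisons <- list()
  if (!is.null(metrics)) {
    full <- metrics[metrics$variant == "full" & metrics$class == "migratory", ]
    for (resp in responses) {
      cmp <- quietly(tryCatch(compare_groups(full, resp, config),
                              error = function(e) conditionMessage(e)))
      comparisons[[resp]] <- if (is.character(cmp)) list(skipped = cmp) else {
        list(model = cmp$model, table = cmp$table)
      }
    }
  }
  cmp_path <- file.path(out_dir, "comparisons.json")
  jsonlite::write_json(comparisons, cmp_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, cmp_path)

  manifest <- list(
    package = "nightflight",
    version = as.character(utils::packageVersion("nightflight")),
    config = unclass(config),
    seed = if (inherits(input, "scenario_spec")) input$seed else config$rng_seed,
    input = if (is.character(input)) basename(input)
            else class(input)[1],
    n_episodes = length(episodes),
    log = as.list(log),
    files = lapply(stats::setNames(paths, basename(paths)),
                   function(p) unname(tools::md5sum(p))))
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(dataset = dataset, truth = truth, episodes = episodes,
                 metrics = metrics, events = events, descents = descents,
                 ascents = ascents, comparisons = comparisons,
                 manifest = manifest))
}
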