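#' Pipeline run configuration
#'
#' One configuration object drives the whole analysis chain:
#' simulate -> behavior -> selectivity -> decoding -> temporal.  Every
#' stochastic stage carries an explicit seed derived from `seed`.  The
#' default stage parameters are scaled for a quick demonstration run;
#' canonical study-scale parameters can be passed through `task`,
#' `population`, `protocol` and the stage lists.
#'
#' @param out_dir output directory for stage results and the report.
#' @param task a [task_config()].
#' @param population a [make_population()] table.
#' @param stages character vector of stage names to run (subset of
#'   `c("behavior", "selectivity", "decoding", "temporal")`; simulation
#'   always runs unless `data_dir` is given).
#' @param data_dir optional existing dataset directory (read with
#'   [read_dataset()]) instead of simulating.
#' @param protocol a [decoding_protocol()] used by the decoding stage.
#' @param temporal list of parameters for the temporal stage
#'   (`n_resamples`, `n_shuffles`, optionally `min_per_level`).
#' @param seed root seed.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(out_dir,
                            task = task_config(),
                            population = make_population(),
                            stages = c("behavior", "selectivity",
                                       "decoding", "temporal"),
                            data_dir = NULL,
                            protocol = decoding_protocol(resamples = 20L),
                            temporal = list(n_resamples = 5L,
                                            n_shuffles = 5L),
                            seed = 1L) {
  stages <- match.arg(stages, c("behavior", "selectivity", "decoding",
                                "temporal"), several.ok = TRUE)
  structure(list(out_dir = out_dir, task = task, population = population,
                 stages = stages, data_dir = data_dir, protocol = protocol,
                 temporal = temporal, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order on a simulated (or
#' loaded) dataset, writes each stage's summary as JSON into the run
#' directory together with provenance (seed, package version), and renders
#' a markdown report.  A stage failure halts downstream stages and is
#' recorded in the report.  Reruns with the same configuration and seed
#' produce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_result` with per-stage outputs and `report`
#'   (path to the markdown report).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  errors <- list()

  if (is.null(config$data_dir)) {
    sim <- generate_experiment(config$task, config$population)
    ds <- sim$dataset
    results$truth <- sim$truth
    write_dataset(ds, file.path(config$out_dir, "dataset"))
  } else {
    ds <- read_dataset(config$data_dir)
  }
  results$dataset <- ds

  safe <- function(name, expr) {
    if (length(errors)) return(NULL)   # halt downstream stages
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  if ("behavior" %in% config$stages) {
    results$behavior <- safe("behavior", behavior_summary(ds))
    if (!is.null(results$behavior))
      jsonlite::write_json(list(
        sessions = results$behavior$sessions,
        chance = results$behavior$chance),
        file.path(config$out_dir, "behavior.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if ("selectivity" %in% config$stages) {
    results$selectivity <- safe("selectivity", selectivity_analysis(ds))
    if (!is.null(results$selectivity))
      jsonlite::write_json(results$selectivity$neurons,
                           file.path(config$out_dir, "selectivity.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if ("decoding" %in% config$stages) {
    results$decoding <- safe("decoding", {
      eligible <- eligible_neurons(ds, config$protocol$trials_per_class)
      neurons <- eligible
      note <- NULL
      if (!is.null(results$selectivity)) {
        sel <- results$selectivity$neurons
        neurons <- intersect(eligible, sel$neuron_id[sel$selective])
        if (length(neurons) < 2) {
          neurons <- eligible
          note <- "too few selective neurons; decoding used all eligible neurons"
        }
      } else {
        note <- "selectivity stage disabled; decoding used all eligible neurons"
      }
      d <- decode_numerosity(ds, neurons = neurons,
                             protocol = config$protocol)
      d$note <- note
      d
    })
    if (!is.null(results$decoding))
      jsonlite::write_json(list(
        accuracy = results$decoding$accuracy,
        sem = results$decoding$sem,
        confusion = results$decoding$confusion,
        note = results$decoding$note),
        file.path(config$out_dir, "decoding.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if ("temporal" %in% config$stages) {
    results$temporal <- safe("temporal", {
      ph <- ds$meta$phase
      scheme <- bin_scheme(-100,
                           ph$instruction_ms + ph$planning_ms + 100,
                           width_ms = 200, step_ms = 100)
      mpl <- config$temporal$min_per_level
      pev_timecourse(ds, scheme = scheme,
                     n_resamples = config$temporal$n_resamples,
                     n_shuffles = config$temporal$n_shuffles,
                     min_per_level = if (is.null(mpl)) 10L else mpl,
                     seed = config$seed)
    })
    if (!is.null(results$temporal))
      jsonlite::write_json(list(
        time_ms = results$temporal$time_ms,
        pev = results$temporal$pev,
        null_p95 = results$temporal$null_p95),
        file.path(config$out_dir, "temporal.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  prov <- list(seed = config$seed,
               package_version = as.character(
                 utils::packageVersion("numopop")),
               stages = config$stages,
               errors = errors)
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  report <- make_report(results, file.path(config$out_dir, "report.md"),
                        errors = errors)
  structure(c(results, list(report = report, errors = errors)),
            class = "run_result")
}

#' Render a markdown report of pipeline results
#'
#' @param results named list of stage outputs (any subset of `behavior`,
#'   `selectivity`, `decoding`, `temporal`).
#' @param path output file.
#' @param errors named list of stage error messages.
#' @return `path`, invisibly.
#' @export
make_report <- function(results, path, errors = list()) {
  ln <- c("# Numerosity population analysis report", "")
  if (!is.null(results$dataset)) {
    ds <- results$dataset
    ln <- c(ln, "## Dataset",
            paste0("- sessions: ", length(unique(ds$trials$session_id))),
            paste0("- trials: ", nrow(ds$trials), " (",
                   sum(ds$trials$outcome == "correct"), " correct, ",
                   sum(ds$trials$outcome == "error"), " error, ",
                   sum(ds$trials$outcome == "aborted"), " aborted)"),
            paste0("- neurons: ", nrow(ds$neurons)), "")
  }
  if (!is.null(results$behavior)) {
    b <- results$behavior
    ln <- c(ln, "## Behavior",
            sprintf("- overall percent correct: %.1f%%",
                    mean(b$sessions$percent_correct)),
            sprintf("- sessions included (>= 40%%): %d / %d",
                    sum(b$sessions$included), nrow(b$sessions)),
            sprintf("- chance level: %.1f%%", b$chance), "")
  }
  if (!is.null(results$selectivity)) {
    s <- results$selectivity$neurons
    ln <- c(ln, "## Selectivity",
            sprintf("- neurons included: %d / %d", sum(s$included),
                    nrow(s)),
            sprintf("- exclusively number-selective: %d (%.1f%%)",
                    sum(s$selective), 100 * mean(s$selective)), "")
  }
  if (!is.null(results$decoding)) {
    d <- results$decoding
    ln <- c(ln, "## Decoding",
            sprintf("- planning-period accuracy: %.1f +/- %.1f%% (chance %.1f%%)",
                    d$accuracy, d$sem, d$chance))
    if (!is.null(d$note)) ln <- c(ln, paste0("- note: ", d$note))
    ln <- c(ln, "")
  }
  if (!is.null(results$temporal)) {
    t_ <- results$temporal
    ln <- c(ln, "## Time-resolved PEV",
            sprintf("- peak number PEV: %.2f%% at %d ms",
                    max(t_$pev["number", ]),
                    round(t_$time_ms[which.max(t_$pev["number", ])])), "")
  }
  if (length(errors)) {
    ln <- c(ln, "## Stage errors",
            vapply(names(errors), function(n)
              paste0("- ", n, ": ", errors[[n]]), character(1)), "")
  }
  writeLines(ln, path)
  invisible(path)
}
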