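#' Run an analysis command and write its outputs
#'
#' High-level driver tying the pipeline stages together. Each command writes
#' CSV outputs plus a `manifest.json` (command, config digest, seed, package
#' version, timestamp, output files) into `out_dir`. All randomness flows
#' from the single `seed`, so a rerun with identical inputs reproduces
#' identical CSVs.
#'
#' Commands: `evaluate` (cost-utility table), `owsa` (one-way tornado),
#' `psa` (probabilistic draws), `ceac` (PSA summaries: CE plane,
#' probability cost-effective, acceptability curve), `threshold` (maximum TE
#' unit cost), `scenario` (ICERs by screening age), `bia` (budget impact),
#' `synth` (writes the synthetic life table and a config template).
#'
#' @param command One of the commands above.
#' @param config Path to a YAML config, a parsed list, or `NULL` for
#'   defaults.
#' @param out_dir Output directory, created if needed.
#' @param population Optional population override (`"mets"`/`"obesity"`).
#' @param age Optional start-age override.
#' @param strategy Strategy id for `owsa`/`threshold`/`bia`
#'   (default `"fib4_te"`; `bia` runs all screening strategies when `NULL`).
#' @param n Number of PSA draws (for `psa`/`ceac`).
#' @param seed Seed override.
#' @param wtp Willingness-to-pay override, THB per QALY.
#' @param verbose Print progress messages?
#' @return Invisibly, the manifest list.
#' @export
run_command <- function(command = c("evaluate", "owsa", "psa", "ceac",
                                    "threshold", "scenario", "bia", "synth"),
                        config = NULL, out_dir = ".",
                        population = NULL, age = NULL, strategy = NULL,
                        n = NULL, seed = NULL, wtp = NULL, verbose = FALSE) {
  command <- match.arg(command)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  config_digest <- NA_character_
  cfg <- config
  if (is.character(config)) {
    config_digest <- unname(tools::md5sum(config))
    cfg <- config
  }
  params <- if (is.null(cfg)) default_parameters(population %||% "mets")
            else load_parameters(cfg)
  if (!is.null(population) && params$population != population)
    params <- default_parameters(population, start_age = params$start_age,
                                 max_age = params$max_age)
  if (!is.null(age)) params$start_age <- age
  if (!is.null(seed)) params$seed <- seed
  if (!is.null(wtp)) params$econ$wtp <- wtp
  validate_parameters(params)

  say <- function(...) if (verbose) message(...)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
    say("wrote ", path)
  }

  strategy <- strategy %||% if (command %in% c("owsa", "threshold")) "fib4_te"
  screeners <- setdiff(names(params$strategies), "no_screen")

  if (command == "evaluate") {
    ce <- cost_effectiveness(params)
    emit(as.data.frame(ce), "cost_effectiveness.csv")
  } else if (command == "owsa") {
    ow <- one_way_sweep(params, strategy)
    emit(as.data.frame(ow), paste0("owsa_", strategy, ".csv"))
  } else if (command == "psa") {
    draws <- run_psa(params, n = n %||% params$psa$n,
                     seed = params$seed)
    emit(as.data.frame(draws), "psa_draws.csv")
  } else if (command == "ceac") {
    draws <- run_psa(params, n = n %||% params$psa$n,
                     seed = params$seed)
    sm <- psa_summaries(draws)
    emit(sm$ce_plane, "ce_plane.csv")
    emit(sm$prob_ce, "prob_cost_effective.csv")
    emit(sm$ceac, "ceac.csv")
  } else if (command == "threshold") {
    th <- threshold_te_cost(strategy, params)
    emit(data.frame(strategy = strategy, verdict = th$verdict,
                    critical_cost_thb = th$critical_cost,
                    icer_at_current = th$icer_at_current,
                    icer_at_zero = th$icer_at_zero),
         paste0("threshold_", strategy, ".csv"))
  } else if (command == "scenario") {
    emit(scenario_sweep(params), "scenario_ages.csv")
  } else if (command == "bia") {
    ids <- if (is.null(strategy)) screeners else strategy
    for (id in ids)
      emit(as.data.frame(compute_budget(params, id)),
           paste0("bia_", id, ".csv"))
  } else if (command == "synth") {
    lt <- synth_life_table()
    write_life_table(lt, file.path(out_dir, "life_table_synthetic.tsv"))
    files <- c(files, "life_table_synthetic.tsv")
    write_parameters(params, file.path(out_dir, "config_template.yaml"))
    files <- c(files, "config_template.yaml")
  }

  manifest <- list(
    command = command,
    config_digest = config_digest,
    seed = params$seed,
    population = params$population,
    start_age = params$start_age,
    package_version = as.character(packageVersion("fibscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
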