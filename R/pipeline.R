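#' Pipeline configuration
#'
#' Assembles the options of the full decision-analysis chain. With the
#' defaults the pipeline runs on the bundled published tables, completes
#' the eight unpublished yields from the synthetic published-layout scenario
#' surface (clearly recorded in the manifest), and uses the documented
#' surrogate/optimizer defaults.
#'
#' @param data `"builtin"` to use the bundled tables, or a named list of
#'   CSV paths (`design`, `phenology`, `indicators`, `responses`).
#' @param fill_missing_yields `"scenario"` to complete missing yields from
#'   `scenario`'s surface (synthetic values, flagged), or `"error"` to
#'   abort on missing yields.
#' @param scenario a [trial_scenario()] used for yield completion.
#' @param surrogate a [surrogate_config()].
#' @param ga a [ga_params()].
#' @param weights length-3 selection weights.
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(data = "builtin",
                            fill_missing_yields = c("scenario", "error"),
                            scenario = trial_scenario(),
                            surrogate = surrogate_config(restarts = 5,
                                                         split_mode = "loo"),
                            ga = ga_params(), weights = c(1, 1, 1),
                            seed = 1L) {
  fill_missing_yields <- match.arg(fill_missing_yields)
  structure(list(data = data, fill_missing_yields = fill_missing_yields,
                 scenario = scenario, surrogate = surrogate, ga = ga,
                 weights = weights, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `seed`, `weights`, `fill_missing_yields`,
#' `data` (mapping of table paths), `surrogate` (fields of
#' [surrogate_config()]), `ga` (fields of [ga_params()]), `scenario`
#' (fields of [trial_scenario()]).
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$data)) args$data <- y$data
  if (!is.null(y$fill_missing_yields)) {
    args$fill_missing_yields <- y$fill_missing_yields
  }
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$weights)) args$weights <- as.numeric(y$weights)
  if (!is.null(y$surrogate)) {
    args$surrogate <- do.call(surrogate_config, y$surrogate)
  }
  if (!is.null(y$ga)) args$ga <- do.call(ga_params, y$ga)
  if (!is.null(y$scenario)) args$scenario <- do.call(trial_scenario, y$scenario)
  do.call(pipeline_config, args)
}

load_pipeline_data <- function(config) {
  if (identical(config$data, "builtin")) {
    return(list(ds = published_trial_dataset(),
                inputs = vapply(c("design_table2.csv", "phenology_table3.csv",
                                  "quality_table4.csv", "yields_text.csv"),
                                function(f) system.file("extdata", f,
                                                        package = "melonopt"),
                                character(1))))
  }
  p <- config$data
  design <- load_trial_table(p$design, "design")
  ds <- design
  if (!is.null(p$phenology)) {
    ph <- load_trial_table(p$phenology, "phenology")
    ds$phenology <- ph$phenology
  }
  if (!is.null(p$indicators)) {
    ind <- load_trial_table(p$indicators, "indicators")
    ds$indicators <- ind$indicators
    ds$indicator_sd <- ind$indicator_sd
  }
  if (!is.null(p$responses)) {
    rs <- load_trial_table(p$responses, "responses")
    ds$responses <- rs$responses
  }
  if (is.null(ds$responses) && !is.null(ds$phenology)) {
    dur <- compute_phenology_durations(ds$phenology)
    ds$responses <- data.frame(label = dur$label,
                               duration = dur$total_growth_days,
                               yield = NA_real_, ci = NA_real_)
  }
  list(ds = ds, inputs = unlist(p))
}

#' Run the full decision-analysis pipeline
#'
#' Executes the chain: load and validate the trial tables; entropy-weight
#' TOPSIS on the quality indicators (Ci merged into the responses); train
#' the neural surrogate on (spacing, pruning) -> (duration, yield, Ci);
#' evolve the NSGA-II Pareto front over the feasible grid; weighted-sum
#' selection of one recommended configuration. All artifacts plus a run
#' manifest (seeds, input digests, stage timings, output paths) are
#' written under `out_dir`; result files contain no timestamps, so a rerun
#' with the same config and seed is byte-identical.
#'
#' @param config a [pipeline_config()], or a YAML path understood by
#'   [read_pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return object of class `run_manifest`; the stage results are attached
#'   as the attribute `"results"`.
#' @export
run_full_pipeline <- function(config = pipeline_config(),
                              out_dir = tempfile("melonopt_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = paste0("melonopt ",
                  as.character(utils::packageVersion("melonopt"))),
    seed = config$seed,
    stage_seeds = list(),
    inputs = list(), timings = list(), outputs = list(),
    notes = character(0)
  )
  results <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      manifest_path <- file.path(out_dir, "manifest.json")
      writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                  digits = NA, force = TRUE), manifest_path)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (manifest so far: ", manifest_path, ")", call. = FALSE)
    })
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    manifest$outputs[[name]] <<- path
    path
  }

  loaded <- stage("load", {
    l <- load_pipeline_data(config)
    rep <- validate_dataset(l$ds)
    if (!rep$ok) {
      stop("input dataset failed validation:\n",
           paste(rep$issues$message[rep$issues$severity == "error"],
                 collapse = "\n"))
    }
    l
  })
  ds <- loaded$ds
  manifest$inputs <- as.list(vapply(loaded$inputs, function(p)
    unname(tools::md5sum(p)), character(1)))

  topsis <- stage("topsis", run_topsis(ds))
  results$topsis <- topsis
  ds$responses$ci <- topsis$closeness[match(ds$responses$label,
                                            names(topsis$closeness))]
  emit("topsis.json", function(p) topsis_result_json(topsis, p))

  ds <- stage("merge_responses", {
    if (anyNA(ds$responses$yield)) {
      if (config$fill_missing_yields == "error") {
        stop("missing yields for: ",
             paste(ds$responses$label[is.na(ds$responses$yield)],
                   collapse = ", "))
      }
      filled <- scenario_surface(config$scenario, ds$treatments$spacing,
                                 ds$treatments$pruning_code)
      miss <- is.na(ds$responses$yield)
      ds$responses$yield[miss] <- filled$yield[miss]
      manifest$notes <- c(manifest$notes, paste0(
        "yields for ", paste(ds$responses$label[miss], collapse = ", "),
        " are synthetic (scenario surface), not measured"))
    }
    ds
  })
  emit("responses.csv", function(p) write_trial_table(ds, p, "responses"))

  fit <- stage("train", {
    cfg <- config$surrogate
    cfg$seed <- as.integer(derive_seed(config$seed, 1) %% 2^31)
    manifest$stage_seeds$train <- cfg$seed
    train_surrogate(ds, cfg)
  })
  results$fit <- fit
  emit("model.json", function(p) write_surrogate(fit$model, p))

  front <- stage("optimize", {
    ga <- config$ga
    ga$seed <- as.integer(derive_seed(config$seed, 2) %% 2^31)
    manifest$stage_seeds$optimize <- ga$seed
    evolve(fit$model, ga)
  })
  results$front <- front
  emit("front.json", function(p) {
    writeLines(jsonlite::toJSON(front$solutions, dataframe = "rows",
                                auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), p)
  })

  decision <- stage("select", weighted_sum_select(front, config$weights))
  results$decision <- decision
  emit("decision.json", function(p) decision_result_json(decision, p))

  manifest$outputs$manifest.json <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, force = TRUE),
             file.path(out_dir, "manifest.json"))
  out <- structure(manifest, class = "run_manifest")
  attr(out, "results") <- results
  out
}

#' Render a human-readable pipeline report
#'
#' Prints the TOPSIS scoring table, the Pareto front listing, and the
#' selected configuration with its three predicted objectives. Every
#' number shown is reproducible from the manifest's seeds and inputs.
#'
#' @param manifest a `run_manifest` from [run_full_pipeline()].
#' @param ... unused.
#' @return the report text, invisibly (also printed).
#' @export
report <- function(manifest, ...) {
  stopifnot(inherits(manifest, "run_manifest"))
  results <- attr(manifest, "results")
  if (is.null(results)) stop("manifest carries no attached results")
  lines <- utils::capture.output({
    cat("==", manifest$tool, "run (seed", manifest$seed, ") ==\n\n")
    cat("-- Comprehensive quality (entropy-weight TOPSIS) --\n")
    print(results$topsis)
    cat("\n-- Pareto front (duration min, yield max, Ci max) --\n")
    print(results$front)
    cat("\n-- Recommendation --\n")
    print(results$decision)
    if (length(manifest$notes)) {
      cat("\nnotes:\n")
      for (n in manifest$notes) cat(" -", n, "\n")
    }
  })
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run manifest (", x$tool, ", seed ", x$seed, ")\n", sep = "")
  cat("  stages:", paste(names(x$timings), collapse = " -> "), "\n")
  cat("  outputs:", paste(names(x$outputs), collapse = ", "), "\n")
  invisible(x)
}
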