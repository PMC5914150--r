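#' Read a run configuration file (YAML or JSON)
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A named list (see [run_pipeline()] for the recognized fields).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

config_defaults <- function(cfg) {
  def <- list(tau = 0, metrics = c("degree", "clustering", "betweenness"),
              modes = c("ga", "manual"), alpha = 0.05,
              normalized_betweenness = FALSE, ga = list(), grid = NULL,
              fitness_grid = NULL, input = list(mode = "simulate"))
  for (nm in names(def)) if (is.null(cfg[[nm]])) cfg[[nm]] <- def[[nm]]
  cfg
}

as_grid <- function(g, default) {
  if (is.null(g)) return(default)
  if (inherits(g, "hyper_grid")) return(g)
  hyper_grid(cost = g$cost, gamma = g$gamma)
}

load_pipeline_matrices <- function(input, seed) {
  mode <- input$mode %||% "simulate"
  if (mode == "simulate") {
    sc <- do.call(synth_config, input$synth %||% list())
    if (sc$mode != "network")
      stop("pipeline input mode 'simulate' requires a network-mode cohort")
    cohort <- simulate_cohort(sc, seed = seed)
    return(list(cms = cohort_connectivity(cohort), planted = cohort$planted,
                atlas = cohort$atlas))
  }
  atlas <- read_atlas(input$atlas)
  files <- as.data.frame(input$files)
  need <- c("path", "subject", "condition")
  if (!all(need %in% colnames(files)))
    stop("input$files needs columns ", paste(need, collapse = ", "))
  cms <- lapply(seq_len(nrow(files)), function(i) {
    f <- files[i, ]
    tryCatch(
      if (mode == "timeseries")
        fisher_connectivity(read_roi_timeseries(f$path, atlas, f$subject,
                                                f$condition))
      else read_connectivity(f$path, atlas, f$subject, f$condition),
      error = function(e) stop("while loading ", f$path, ": ",
                               conditionMessage(e), call. = FALSE))
  })
  list(cms = cms, planted = NULL, atlas = atlas)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full extraction pipeline
#'
#' Connectivity matrices -> positive-edge graphs -> nodal metric feature
#' tables -> GA and/or manual region selection per metric, plus the Newman
#' modularity partition of the group-averaged matrix per condition.  All
#' artefacts are written to `out_dir` as delimited text / JSON; the run is
#' fully determined by `config` and `seed`.
#'
#' @param config A named list or path to a YAML/JSON file.  Recognized
#'   fields: `input` (`mode` = `"simulate"` with `synth` parameters for
#'   [synth_config()], or `"timeseries"`/`"matrices"` with `atlas` and a
#'   `files` table of `path`/`subject`/`condition`), `tau`, `metrics`,
#'   `modes` (subset of `"ga"`, `"manual"`), `alpha`, `ga` (fields of
#'   [ga_config()]), `grid` and `fitness_grid` (lists with `cost`, `gamma`),
#'   `normalized_betweenness`.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed controlling simulation and GA.
#' @param quiet Suppress progress messages?
#' @return The run report (a list, also written to `report.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  cfg <- config_defaults(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stopifnot(all(cfg$metrics %in% c("degree", "clustering", "betweenness")),
            all(cfg$modes %in% c("ga", "manual")))
  grid <- as_grid(cfg$grid, hyper_grid())
  fitness_grid <- as_grid(cfg$fitness_grid, coarse_hyper_grid())
  gacfg <- do.call(ga_config, cfg$ga)

  say("[input] loading connectivity matrices")
  inp <- load_pipeline_matrices(cfg$input, seed = seed)
  cms <- inp$cms

  # group-averaged modularity per condition (descriptive)
  conds <- sort(unique(vapply(cms, `[[`, character(1), "condition")))
  modularity <- lapply(conds, function(cn) {
    gavg <- group_average(cms[vapply(cms, `[[`, character(1),
                                     "condition") == cn])
    part <- newman_modularity(gavg, tau = cfg$tau)
    write_partition(part, file.path(out_dir,
                                    paste0("partition_", cn, ".tsv")))
    list(condition = cn, Q = part$Q, n_communities = part$n_communities)
  })
  names(modularity) <- conds

  results <- list()
  for (met in cfg$metrics) {
    say("[metrics] ", met)
    ft <- compute_features(cms, met, tau = cfg$tau,
                           normalized = isTRUE(cfg$normalized_betweenness))
    write_feature_table(ft, file.path(out_dir,
                                      paste0("features_", met, ".tsv")))
    res <- list(metric = met)
    if ("manual" %in% cfg$modes) {
      say("[select] manual baseline (", met, ")")
      man <- manual_select(ft, alpha = cfg$alpha, grid = grid)
      res$manual <- list(accuracy = man$accuracy,
                         cost = if (!is.null(man$cv)) man$cv$cost,
                         gamma = if (!is.null(man$cv)) man$cv$gamma,
                         regions = man$regions,
                         mask = unname(man$mask))
      writeLines(man$regions,
                 file.path(out_dir, paste0("regions_manual_", met, ".txt")))
    }
    if ("ga" %in% cfg$modes) {
      say("[select] genetic algorithm (", met, ")")
      ga <- ga_select(ft, gacfg, fitness_grid = fitness_grid,
                      final_grid = grid, seed = seed + match(met, cfg$metrics))
      res$ga <- list(accuracy = ga$cv$accuracy, fitness = ga$fitness,
                     cost = ga$cv$cost, gamma = ga$cv$gamma,
                     regions = ga$regions, mask = unname(ga$mask))
      writeLines(ga$regions,
                 file.path(out_dir, paste0("regions_ga_", met, ".txt")))
      utils::write.csv(ga$history,
                       file.path(out_dir, paste0("fitness_", met, ".csv")),
                       row.names = FALSE)
    }
    if (!is.null(inp$planted)) {
      res$recovery <- lapply(
        Filter(Negate(is.null), list(ga = res$ga, manual = res$manual)),
        function(r) recovery_score(r$mask, inp$planted))
    }
    results[[met]] <- res
  }

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  report <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("netselect")),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    tau = cfg$tau,
    modularity = modularity,
    results = results)
  if (!is.null(inp$planted)) report$planted_regions <- inp$planted
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  say("[done] report written to ", file.path(out_dir, "report.json"))
  invisible(report)
}

#' Verify a pipeline report by recomputation
#'
#' Re-reads the serialized feature tables and selection masks of a run and
#' recomputes every reported LOSOCV accuracy at the reported (cost, gamma).
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @return Data frame with one row per metric x mode: reported and
#'   recomputed accuracy and whether they agree exactly.  Raises an error if
#'   any entry disagrees.
#' @export
verify_run <- function(out_dir) {
  report <- jsonlite::read_json(file.path(out_dir, "report.json"),
                                simplifyVector = TRUE)
  rows <- list()
  for (met in names(report$results)) {
    res <- report$results[[met]]
    ft <- read_feature_table(file.path(out_dir,
                                       paste0("features_", met, ".tsv")))
    for (mode in intersect(c("ga", "manual"), names(res))) {
      r <- res[[mode]]
      if (is.null(r$cost) || sum(r$mask) == 0) next
      cv <- losocv_svm(ft, as.numeric(r$mask), cost = r$cost, gamma = r$gamma)
      rows[[paste(met, mode)]] <-
        data.frame(metric = met, mode = mode, reported = r$accuracy,
                   recomputed = cv$accuracy,
                   ok = isTRUE(all.equal(cv$accuracy, r$accuracy)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!all(out$ok))
    stop("report verification failed for: ",
         paste(paste(out$metric[!out$ok], out$mode[!out$ok]), collapse = ", "))
  out
}
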