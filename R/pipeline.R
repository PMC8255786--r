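#' Read a run configuration file
#'
#' JSON always supported; YAML when the \pkg{yaml} package is installed.
#' Missing fields are filled from [default_config()].
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return Configuration list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  utils::modifyList(default_config(), cfg)
}

#' Default pipeline configuration
#'
#' @return List of class `"run_config"` with the generator and analysis
#'   settings used throughout the package: the 2 x 2 factorial stimulus
#'   levels, three agents with individually different fat and sugar
#'   weights, offer-magnitude grid, bootstrap/CV sizes and RL parameters.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    fat_levels = c(0.1, 3.6), sugar_levels = c(4.7, 12.575), protein = 3.4,
    magnitude_grid = seq(0.2, 1.2, by = 0.2),
    n_trials = 200L, repeats = 1L,
    agents = list(
      list(agent_id = "A", w_fat = 0.1196, w_sugar = 0.1164, temperature = 3),
      list(agent_id = "B", w_fat = 0.0600, w_sugar = 0.2000, temperature = 3),
      list(agent_id = "C", w_fat = 0.1500, w_sugar = 0.0500, temperature = 3)
    ),
    n_bootstrap = 200L, cv_folds = 10L, n_bins = 10L,
    reference = "LFLS",
    rl = list(alpha = 0.2, beta = 5, eta = 0.2, n_trials = 100L,
              n_reps = 1000L)
  ), class = "run_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates simulate, fit, cross-predict, mediate, strategy, geometry
#' and RL stages in dependency order under a single config and seed,
#' writing each stage's artifacts (CSV/JSON) plus a log recording the seed,
#' a config hash and the package version. A failing stage halts the run
#' with the stage named; artifacts of completed stages are preserved.
#'
#' @param config A [default_config()]-style list (or [read_run_config()]
#'   result).
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of
#'   `c("simulate", "fit", "cross_predict", "mediate", "strategy",
#'   "geometry", "rl")`; dependencies of requested stages are run
#'   automatically.
#' @return List of class `"pipeline_report"`: per-stage output paths, seed,
#'   config hash and summary tables.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run"),
                         stages = c("simulate", "fit", "cross_predict",
                                    "mediate", "strategy", "geometry", "rl")) {
  all_stages <- c("simulate", "fit", "cross_predict", "mediate", "strategy",
                  "geometry", "rl")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if ("cross_predict" %in% stages) stages <- union(stages, "fit")
  stages <- union("simulate", stages)
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  paths <- list(config = cfg_path)
  summaries <- list()
  log_lines <- c(
    sprintf("nutrichoice %s", as.character(utils::packageVersion("nutrichoice"))),
    sprintf("seed: %d", config$seed),
    sprintf("config md5: %s", cfg_hash)
  )
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  env <- new.env()

  run_stage("simulate", {
    seeds <- derive_seeds(config$seed, 3)
    stim <- make_factorial_stimuli(config$fat_levels, config$sugar_levels,
                                   config$protein)
    stim <- apply_texture(stim, texture_model(), seed = seeds[1])
    agents <- lapply(config$agents, function(a) do.call(nutrient_value_fn, a))
    sched <- pair_schedule(stim, n_trials = config$n_trials,
                           repeats = config$repeats)
    trials <- make_dataset(agents, sched, stim, seed = seeds[2],
                           magnitude_grid = config$magnitude_grid)
    # wider stimulus set (cream-, juice- and intermediate-like) so texture
    # and fat decorrelate enough for the mediation stage to be identifiable
    extra <- stimulus_table(
      id = c("CREAM", "JUICE", "MID"),
      fat = c(9, 0.1, 1.8), sugar = c(4.7, 10, 8), protein = config$protein)
    stim_ext <- rbind(as.data.frame(stim)[1:4, ], as.data.frame(extra))
    stim_ext <- stimulus_table(stim_ext$id, stim_ext$fat, stim_ext$sugar,
                               stim_ext$protein)
    stim_ext <- apply_texture(stim_ext, texture_model(), seed = seeds[1])
    tex_agent <- nutrient_value_fn("TEX", w_sugar = 0.08, w_csf = -2.5,
                                   temperature = 2)
    idx <- utils::combn(nrow(stim_ext), 2)
    sched_med <- data.frame(stim_a = stim_ext$id[idx[1, ]],
                            stim_b = stim_ext$id[idx[2, ]],
                            n_trials = config$n_trials)
    trials_med <- make_dataset(list(tex_agent), sched_med, stim_ext,
                               seed = seeds[3],
                               magnitude_grid = config$magnitude_grid)
    env$stim <- stim
    env$stim_ext <- stim_ext
    env$trials_med <- trials_med
    env$agents <- agents
    env$trials <- trials
    paths$stimuli <- write_stimuli(stim_ext,
                                   file.path(out_dir, "stimuli.csv"))
    paths$trials <- write_trials(trials, file.path(out_dir, "trials.csv"))
    paths$trials_mediation <- write_trials(
      trials_med, file.path(out_dir, "trials_mediation.csv"))
    truth <- lapply(agents, unclass)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    paths$truth <- file.path(out_dir, "truth.json")
    summaries$simulate <- c(n_trials = nrow(trials),
                             n_sessions = length(unique(trials$session_id)))
  })

  by_agent <- split(as.data.frame(env$trials), env$trials$agent_id)
  by_agent <- lapply(by_agent, choice_trials)

  if ("fit" %in% stages) run_stage("fit", {
    fits <- lapply(by_agent, fit_nutrient_model, stimuli = env$stim)
    env$fits <- fits
    psych <- lapply(by_agent, function(tr) {
      sapply(c("HFLS", "LFHS", "HFHS"), function(tg) {
        # an agent with no identifiable inflection for a pair (e.g. it never
        # chose the reference) yields NA rather than halting the run
        tryCatch(
          psychometric_fit(tr, env$stim, config$reference, tg,
                           n_bootstrap = config$n_bootstrap,
                           seed = config$seed)$indifference_point,
          error = function(e) NA_real_)
      })
    })
    out <- list(
      nutrient_models = lapply(fits, function(f) {
        list(coefficients = as.list(f$coefficients), loglik = f$loglik,
             aic = f$aic, pseudo_r2 = f$pseudo_r2)
      }),
      indifference_points = psych
    )
    paths$fits <- file.path(out_dir, "fits.json")
    jsonlite::write_json(out, paths$fits, auto_unbox = TRUE, digits = NA)
    summaries$fit <- do.call(rbind, psych)
  })

  if ("cross_predict" %in% stages) run_stage("cross_predict", {
    ids <- names(by_agent)
    pdis <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i < j) {
        p <- pdi(env$fits[[i]], by_agent[[i]], env$fits[[j]], by_agent[[j]],
                 env$stim)$pdi
        pdis[i, j] <- pdis[j, i] <- p
      }
    }
    paths$pdi <- file.path(out_dir, "pdi.csv")
    utils::write.csv(as.data.frame(pdis), paths$pdi)
    summaries$cross_predict <- pdis
  })

  if ("mediate" %in% stages) run_stage("mediate", {
    med <- mediation_fit(env$trials_med, env$stim_ext,
                         n_bootstrap = config$n_bootstrap, seed = config$seed)
    paths$mediation <- file.path(out_dir, "mediation.json")
    jsonlite::write_json(list(paths = med$paths, verdict = as.list(med$verdict)),
                         paths$mediation, auto_unbox = TRUE, digits = NA)
    summaries$mediate <- med$verdict
  })

  if ("strategy" %in% stages) run_stage("strategy", {
    cmp <- compare_energy_vs_nutrient(env$trials, env$stim)
    paths$strategy <- file.path(out_dir, "strategy.json")
    jsonlite::write_json(cmp[c("AIC_energy", "AIC_nutrient", "delta_AIC")],
                         paths$strategy, auto_unbox = TRUE, digits = NA)
    summaries$strategy <- unlist(cmp[c("AIC_energy", "AIC_nutrient",
                                        "delta_AIC")])
  })

  if ("geometry" %in% stages) run_stage("geometry", {
    balances <- do.call(rbind, lapply(split_sessions(env$trials), function(s) {
      as.data.frame(as.list(choice_balance(s, env$stim)))
    }))
    paths$geometry <- file.path(out_dir, "balances.csv")
    utils::write.csv(balances, paths$geometry, row.names = FALSE)
    summaries$geometry <- colMeans(balances)
  })

  if ("rl" %in% stages) run_stage("rl", {
    sched <- reversal_schedule(n_trials = config$rl$n_trials)
    std <- simulate_reversal(rl_agent(config$rl$alpha, config$rl$beta, 0),
                             sched, config$rl$n_reps, seed = config$seed)
    ns <- simulate_reversal(
      rl_agent(config$rl$alpha, config$rl$beta, config$rl$eta),
      sched, config$rl$n_reps, seed = config$seed)
    tab <- data.frame(model = c("standard", "nutrient_sensitive"),
                      mean_R = c(mean(std$total_reward), mean(ns$total_reward)),
                      mean_N = c(mean(std$nutrient_intake),
                                 mean(ns$nutrient_intake)),
                      switch_latency = c(std$trials_to_criterion,
                                         ns$trials_to_criterion))
    paths$rl <- file.path(out_dir, "rl.csv")
    utils::write.csv(tab, paths$rl, row.names = FALSE)
    summaries$rl <- tab
  })

  log_lines <- c(log_lines, sprintf("completed stage: %s", stages))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  paths$log <- file.path(out_dir, "log.txt")
  structure(list(paths = paths, seed = config$seed, config_hash = cfg_hash,
                 stages = stages, summaries = summaries),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, "| config", substr(x$config_hash, 1, 8),
      ")\nstages:", paste(x$stages, collapse = ", "), "\n")
  for (nm in names(x$paths)) cat(sprintf("  %-12s %s\n", nm, x$paths[[nm]]))
  invisible(x)
}
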