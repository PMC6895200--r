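#' Default pipeline configuration
#'
#' Stage parameters default to the standard protocol values
#' (`min_potential = 4`, `threshold = 0.5`, `n_reps = 100`); everything else
#' defaults to the package's documented choices.
#'
#' @return Named list of configuration defaults. Keys:
#'   \describe{
#'     \item{input_dir}{directory with the four input files, or `NULL` to
#'       generate a synthetic dataset.}
#'     \item{synthetic}{list of [synthetic_config()] overrides.}
#'     \item{metric, shared}{beta-partition options, see [partition_all()].}
#'     \item{min_potential, threshold, strict}{host classification, see
#'       [classify_hosts()].}
#'     \item{n_iter, in_fragment_preferred}{null model, see
#'       [constraint_test()].}
#'     \item{scenarios, n_reps, family_rule, target_grain}{extinction
#'       simulation, see [run_scenarios()].}
#'     \item{seed}{master seed; per-stage seeds are derived from it.}
#'     \item{out_dir}{output directory.}
#'   }
#' @export
default_config <- function() {
  list(input_dir = NULL,
       synthetic = list(),
       metric = "whittaker", shared = "both",
       min_potential = 4, threshold = 0.5, strict = TRUE,
       n_iter = 999, in_fragment_preferred = FALSE,
       scenarios = c("noRW", "RWphylo", "RWrand"),
       n_reps = 100, family_rule = "removed_host_family",
       target_grain = "individual",
       seed = 1, out_dir = "mycorewire_out")
}

resolve_config <- function(config) {
  defaults <- default_config()
  bad <- setdiff(names(config), names(defaults))
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(config$synthetic)) {
    bad_syn <- setdiff(names(config$synthetic),
                       names(formals(synthetic_config)))
    if (length(bad_syn) > 0) {
      stop("unknown synthetic configuration key(s): ",
           paste(bad_syn, collapse = ", "), call. = FALSE)
    }
  }
  utils::modifyList(defaults, config)
}

# Per-stage seeds derived deterministically from the master seed.
stage_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(2147483646L, 5),
                  c("simulate", "betadiv", "preference", "constraint",
                    "robustness"))
}

data_dir_of <- function(cfg) {
  if (is.null(cfg$input_dir)) file.path(cfg$out_dir, "data") else cfg$input_dir
}

load_pipeline_dataset <- function(cfg) {
  d <- data_dir_of(cfg)
  paths <- file.path(d, c("interactions.csv", "individuals.csv",
                          "taxonomy.csv", "phylogeny.nwk"))
  if (!all(file.exists(paths))) {
    stop("input data not found in '", d,
         "'; run the simulate stage first or set input_dir", call. = FALSE)
  }
  read_dataset(paths[1], paths[2], paths[3], paths[4])
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order: `simulate` (synthetic
#' data generation, skipped when `input_dir` is given), `betadiv`,
#' `preference`, `constraint`, `robustness`. Later stages read the on-disk
#' outputs of earlier stages, so any single stage can be re-run from
#' intermediates with identical results. A run manifest (resolved
#' configuration, derived per-stage seeds, input digests, timings, warnings)
#' is written once per run.
#'
#' @param config named list overriding [default_config()]; unknown keys are
#'   rejected.
#' @param stages character vector of stages to run (default: all).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "betadiv", "preference",
                                    "constraint", "robustness")) {
  cfg <- resolve_config(config)
  order_all <- c("simulate", "betadiv", "preference", "constraint",
                 "robustness")
  stages <- order_all[order_all %in% match.arg(stages, order_all,
                                               several.ok = TRUE)]
  seeds <- stage_seeds(cfg$seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "mycorewire",
                   version = as.character(utils::packageVersion("mycorewire")),
                   config = cfg[setdiff(names(cfg), "synthetic")],
                   synthetic = cfg$synthetic,
                   seeds = as.list(seeds),
                   stages_run = stages, timings = list(), warnings = list())
  run_stage <- function(name, fun) {
    if (!(name %in% stages)) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    warns <- character(0)
    withCallingHandlers(fun(), warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    if (length(warns) > 0) manifest$warnings[[name]] <<- warns
    invisible(NULL)
  }

  run_stage("simulate", function() {
    if (!is.null(cfg$input_dir)) return()
    sim <- generate_community(do.call(synthetic_config, cfg$synthetic),
                              seed = seeds[["simulate"]])
    write_synthetic(sim, file.path(cfg$out_dir, "data"))
  })

  dataset <- load_pipeline_dataset(cfg)
  manifest$input_digests <- as.list(tools::md5sum(
    file.path(data_dir_of(cfg), c("interactions.csv", "individuals.csv",
                                  "taxonomy.csv", "phylogeny.nwk"))))

  run_stage("betadiv", function() {
    beta <- partition_all(dataset, metric = cfg$metric, shared = cfg$shared)
    utils::write.csv(as.data.frame(beta),
                     file.path(cfg$out_dir, "beta_components.csv"),
                     row.names = FALSE)
    write_json_file(list(n_pairs = nrow(beta),
                         mean_ratio_st_wn = attr(beta, "mean_ratio"),
                         se_ratio_st_wn = attr(beta, "se_ratio"),
                         metric = cfg$metric),
                    file.path(cfg$out_dir, "beta_summary.json"))
  })

  run_stage("preference", function() {
    prefs <- classify_hosts(cooccurrence_counts(dataset),
                            min_potential = cfg$min_potential,
                            threshold = cfg$threshold, strict = cfg$strict)
    utils::write.csv(as.data.frame(prefs),
                     file.path(cfg$out_dir, "preference.csv"),
                     row.names = FALSE)
    pres <- eligible_presences(dataset, prefs)
    flat <- data.frame(
      otu_id = pres$otu_id, fragment_id = pres$fragment_id,
      nonpreferred_observed = vapply(pres$nonpreferred_observed,
                                     paste, "", collapse = ";"))
    utils::write.csv(flat, file.path(cfg$out_dir, "eligible_presences.csv"),
                     row.names = FALSE)
  })

  run_stage("constraint", function() {
    pref_path <- file.path(cfg$out_dir, "preference.csv")
    if (!file.exists(pref_path)) {
      stop("preference.csv not found; run the preference stage first",
           call. = FALSE)
    }
    prefs <- utils::read.csv(pref_path, stringsAsFactors = FALSE)
    class(prefs) <- c("preference_table", "data.frame")
    ct <- constraint_test(dataset, prefs, n_iter = cfg$n_iter,
                          in_fragment_preferred = cfg$in_fragment_preferred,
                          seed = seeds[["constraint"]])
    utils::write.csv(ct$stats, file.path(cfg$out_dir, "constraint_stats.csv"),
                     row.names = FALSE)
    write_json_file(list(n = ct$n, estimate = ct$estimate, t = ct$t,
                         df = ct$df, p = ct$p, n_dropped = ct$n_dropped,
                         n_iter = ct$n_iter,
                         seed = unname(seeds[["constraint"]])),
                    file.path(cfg$out_dir, "constraint_test.json"))
  })

  run_stage("robustness", function() {
    beta_path <- file.path(cfg$out_dir, "beta_components.csv")
    if (!file.exists(beta_path)) {
      stop("beta_components.csv not found; run the betadiv stage first",
           call. = FALSE)
    }
    beta <- utils::read.csv(beta_path, stringsAsFactors = FALSE)
    rob <- run_scenarios(dataset, scenarios = cfg$scenarios,
                         n_reps = cfg$n_reps, seed = seeds[["robustness"]],
                         family_rule = cfg$family_rule,
                         target_grain = cfg$target_grain,
                         rewire_pool = 1 - beta$ratio_st_wn[
                           !is.na(beta$ratio_st_wn)])
    utils::write.csv(as.data.frame(rob),
                     file.path(cfg$out_dir, "robustness.csv"),
                     row.names = FALSE)
    if (!is.null(attr(rob, "gains"))) {
      utils::write.csv(attr(rob, "gains"),
                       file.path(cfg$out_dir, "gains.csv"), row.names = FALSE)
    }
    write_json_file(list(gain_pct_mean = attr(rob, "gain_mean"),
                         gain_pct_se = attr(rob, "gain_se"),
                         n_reps = cfg$n_reps,
                         seed = unname(seeds[["robustness"]])),
                    file.path(cfg$out_dir, "robustness_summary.json"))
  })

  write_json_file(manifest, file.path(cfg$out_dir, "manifest.json"))
  invisible(manifest)
}
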