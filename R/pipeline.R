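PIPELINE_DEFAULTS <- list(
  iterations = 500L, permutations = 100000L, hier_fraction = 0.3,
  df = 3, lambda = 0.04, n_boot = 1000L, difference = "rank",
  n_orderings = 1000L, K = 200, init_score = 1000,
  group = NULL, category = NULL, input = NULL, abm = NULL,
  output_dir = ".", seed = NULL
)

# Config-file spellings avoid single letters: YAML 1.1 parses bare N/n/Y/y
# as booleans, so the file uses word keys; R-level lists may use either.
ABM_KEYS <- c("individuals", "subgroups", "mean_size", "p_w",
              "N", "X", "G", "P_w", "assorted", "type_code", "seed")

abm_config_from_keys <- function(abm) {
  alias <- c(individuals = "N", subgroups = "X", mean_size = "G",
             p_w = "P_w")
  names(abm) <- ifelse(names(abm) %in% names(alias),
                       alias[names(abm)], names(abm))
  do.call(abm_config, abm)
}

#' Load a pipeline run configuration
#'
#' Reads a YAML configuration file, applies defaults (500 iterations, 100000
#' permutations, hierarchy fraction 0.3, spline df 3 / lambda 0.04, 1000
#' bootstrap replicates, rank differences), and validates the keys. Exactly
#' one of `input` (a dataset path) or an `abm:` section (simulator
#' parameters) must be set before the configuration can be run; values given
#' in `overrides` (e.g. from command-line flags) take precedence over the
#' file.
#'
#' @param path Path to a YAML file (an empty file yields all defaults).
#' @param overrides Named list of values overriding the file.
#' @return A list of class `run_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- PIPELINE_DEFAULTS
  file_vals <- if (!is.null(path)) {
    v <- yaml::read_yaml(path)
    if (is.null(v)) list() else v
  } else list()
  for (vals in list(file_vals, overrides)) {
    unknown <- setdiff(names(vals), names(PIPELINE_DEFAULTS))
    if (length(unknown) > 0)
      stop("unknown configuration key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    cfg[names(vals)] <- vals
  }
  if (!is.null(cfg$abm)) {
    bad <- setdiff(names(cfg$abm), ABM_KEYS)
    if (length(bad) > 0)
      stop("unknown abm key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$input) == is.null(cfg$abm))
    stop("exactly one of 'input' (dataset path) or 'abm' (simulator ",
         "parameters) must be set", call. = FALSE)
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Orchestrates one reproducible end-to-end run: load (or simulate) the
#' interaction dataset, optionally filter to one group, then for each
#' interaction category present infer a full-data hierarchy, fit the
#' strategy band, and — when both aggressive categories are present — run
#' the Bayes-rule cost allocation. All outputs are delimited text plus a
#' JSON manifest recording parameters, seeds and iteration failure counts so
#' the run can be reproduced exactly.
#'
#' @param config A `run_config` from [load_config()], or a named list of
#'   configuration values.
#' @param output_dir Output directory (created if needed); defaults to the
#'   configuration's `output_dir`.
#' @return Invisibly, a list of the fitted objects (`dataset`,
#'   `hierarchies`, `strategy`, `cost_allocation`, `manifest`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (!inherits(config, "run_config"))
    config <- load_config(overrides = config)
  validate_run_config(config)
  out_dir <- output_dir %||% config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  manifest <- list(package_version = as.character(utils::packageVersion("domstrat")),
                   config = config[setdiff(names(config), "abm")],
                   abm = config$abm, complete = FALSE, failures = list())

  if (!is.null(config$abm)) {
    ds <- simulate_dominance(abm_config_from_keys(config$abm))
    write_interactions(ds, file.path(out_dir, "simulated_dataset.csv"))
    manifest$realized_mean_subgroup_size <- mean(lengths(ds$present))
  } else {
    ds <- read_interactions(config$input)
  }
  if (!is.null(config$group))
    ds <- ds[ds$group_id %in% config$group, , drop = FALSE]
  cats <- intersect(CATEGORIES, unique(ds$category))
  if (!is.null(config$category)) cats <- intersect(cats, config$category)
  if (length(cats) == 0) stop("no events in the requested categories",
                              call. = FALSE)

  hier <- list(); strat <- list()
  for (cc in cats) {
    sub <- ds[ds$category == cc, , drop = FALSE]
    h <- suppressWarnings(elo_hierarchy(sub, K = config$K,
                                        init_score = config$init_score,
                                        n_orderings = config$n_orderings))
    utils::write.csv(as.data.frame(h),
                     file.path(out_dir, paste0("hierarchy_", cc, ".csv")),
                     row.names = FALSE)
    fit <- fit_strategy(sub, n_iterations = config$iterations,
                        hier_fraction = config$hier_fraction,
                        n_permutations = config$permutations,
                        difference = config$difference,
                        df = config$df, lambda = config$lambda,
                        K = config$K, init_score = config$init_score,
                        n_orderings = config$n_orderings)
    utils::write.csv(fit$band,
                     file.path(out_dir, paste0("strategy_band_", cc, ".csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(fit$predictions),
                     file.path(out_dir, paste0("strategy_predictions_", cc, ".csv")),
                     row.names = FALSE)
    manifest$failures[[cc]] <- fit$n_failed
    hier[[cc]] <- h; strat[[cc]] <- fit
  }

  alloc <- NULL
  if (all(c("higher_cost_aggressive", "lower_cost_aggressive") %in% cats)) {
    alloc <- bootstrap_allocation(
      ds[ds$category == "higher_cost_aggressive", , drop = FALSE],
      ds[ds$category == "lower_cost_aggressive", , drop = FALSE],
      n_boot = config$n_boot, n_orderings = config$n_orderings)
    tb <- alloc$table
    tb$baseline <- alloc$baseline
    utils::write.csv(tb, file.path(out_dir, "cost_allocation.csv"),
                     row.names = FALSE)
  }
  manifest$complete <- TRUE
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       force = TRUE)
  invisible(list(dataset = ds, hierarchies = hier, strategy = strat,
                 cost_allocation = alloc, manifest = manifest))
}

#' Published per-group interaction summary
#'
#' The per-group, per-category interaction counts and split-half
#' repeatability values reported for the two wild vulturine guineafowl study
#' groups, shipped as a plain-text fixture. Useful for checking summary
#' arithmetic (totals and category shares) and as a reference for
#' paper-scale data density.
#'
#' @return A data frame with columns `group`, `category`, `n_interactions`,
#'   `group_size`, `n_per_individual`, `rs`.
#' @export
guineafowl_summary <- function() {
  utils::read.csv(system.file("extdata", "guineafowl_summary.csv",
                              package = "domstrat"),
                  stringsAsFactors = FALSE)
}
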