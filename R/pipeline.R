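# Command-line-style entry points: simulate a cohort to a directory of CSV
# files, and run the analysis pipeline from those files. A thin executable
# wrapper ships in inst/cli/beliefsim.

#' Simulate a cohort from a config file
#'
#' Reads a YAML (or JSON) config whose keys mirror the [cohort_config()]
#' arguments, generates the cohort and writes `trajectories.csv`,
#' `cohort.csv`, `items.csv` and `loadings.csv` to `out_dir`.
#'
#' @param config_path Path to a YAML/JSON config file, or `NULL` for the
#'   defaults.
#' @param out_dir Output directory.
#' @return The cohort, invisibly.
#' @export
run_simulation <- function(config_path = NULL, out_dir = ".") {
  args <- list()
  if (!is.null(config_path)) {
    args <- if (grepl("\\.json$", config_path)) {
      jsonlite::read_json(config_path, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
      }
      yaml::read_yaml(config_path)
    }
  }
  cfg <- do.call(cohort_config, args)
  cohort <- sample_cohort(cfg)
  write_cohort(cohort, out_dir)
  invisible(cohort)
}

#' Fit the model set and run the analysis from CSV inputs
#'
#' Reads the interchange files produced by [run_simulation()] (or prepared
#' from real data in the same dialect), fits the biased-RW model to every
#' requested run, computes Anderson-Rubin factor scores, and writes
#' `fits.csv` and `analysis_report.json` to `out_dir`.
#'
#' @param data_dir Directory containing `trajectories.csv`, `cohort.csv`,
#'   `items.csv`, `loadings.csv`.
#' @param out_dir Output directory (default: `data_dir`).
#' @param referent Which runs to analyse.
#' @param model_ids Models to fit.
#' @param n_restarts,n_perm,n_boot,seed Tuning knobs, see [fit_cohort()]
#'   and [analyze_cohort()].
#' @return The `analysis_report`, invisibly.
#' @export
run_analysis <- function(data_dir, out_dir = data_dir, referent = "self",
                         model_ids = 3L, n_restarts = 5L, n_perm = 10000L,
                         n_boot = 5000L, seed = 1L) {
  trajectories <- read_trajectories(file.path(data_dir, "trajectories.csv"))
  participants <- utils::read.csv(file.path(data_dir, "cohort.csv"),
                                  stringsAsFactors = FALSE)
  items_df <- utils::read.csv(file.path(data_dir, "items.csv"),
                              check.names = FALSE, stringsAsFactors = FALSE)
  items <- as.matrix(items_df[, -1])
  rownames(items) <- items_df$participant_id
  loadings_df <- utils::read.csv(file.path(data_dir, "loadings.csv"),
                                 check.names = FALSE, stringsAsFactors = FALSE)
  loadings <- as.matrix(loadings_df[, -1])
  rownames(loadings) <- loadings_df$item

  # order trajectories by participant to align with the cohort table
  cohort <- structure(list(participants = participants,
                           trajectories = trajectories,
                           items = items, loadings = loadings),
                      class = "cohort")
  runs <- Filter(function(tr) tr$referent == referent, trajectories)
  fits <- fit_cohort(runs, model_ids = model_ids, seed = seed,
                     n_restarts = n_restarts)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
  report <- analyze_cohort(cohort, fits, referent = referent, n_perm = n_perm,
                           n_boot = n_boot, seed = seed)
  write_analysis_report(report, file.path(out_dir, "analysis_report.json"))
  invisible(report)
}
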