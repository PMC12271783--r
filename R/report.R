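#' Run configuration for the report commands
#'
#' Bundles everything a reporting run needs: the model configuration
#' file, output directory, seed, and analysis options. The referenced
#' configuration file must exist.
#'
#' @param config Path to the YAML model configuration (default: the
#'   packaged base case).
#' @param out_dir Output directory; created if missing.
#' @param seed Integer seed used by every stochastic stage.
#' @param psa_n Monte Carlo draws for the PSA.
#' @param microsim_n Patients per strategy for the microsimulation.
#' @param wtp Optional willingness-to-pay override (USD/QALY).
#' @param wtp_grid CEAC grid (USD/QALY).
#' @param structure Structural options, see [psp_structure()].
#' @param utility_mode `"lifetime"` or `"first_year"`.
#' @param overwrite Allow overwriting existing output files.
#' @return A list of class `psp_run_config`.
#' @export
run_config <- function(config = NULL, out_dir = "psptree-results",
                       seed = 1L, psa_n = 5000, microsim_n = 1000,
                       wtp = NULL, wtp_grid = seq(0, 200000, by = 5000),
                       structure = psp_structure(),
                       utility_mode = c("lifetime", "first_year"),
                       overwrite = FALSE) {
  if (is.null(config))
    config <- system.file("extdata", "psp_base_case.yaml",
                          package = "psptree", mustWork = TRUE)
  if (!file.exists(config))
    stop("configuration error: config file not found: ", config,
         call. = FALSE)
  utility_mode <- match.arg(utility_mode)
  structure(list(config = config, out_dir = out_dir,
                 seed = as.integer(seed), psa_n = psa_n,
                 microsim_n = microsim_n, wtp = wtp, wtp_grid = wtp_grid,
                 structure = structure, utility_mode = utility_mode,
                 overwrite = overwrite),
            class = "psp_run_config")
}

prepare_out <- function(cfg, files) {
  if (!dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)
  paths <- file.path(cfg$out_dir, files)
  clash <- paths[file.exists(paths)]
  if (length(clash) && !cfg$overwrite)
    stop("output exists (use overwrite = TRUE): ",
         paste(clash, collapse = ", "), call. = FALSE)
  stats::setNames(paths, files)
}

load_run <- function(cfg) {
  params <- load_parameters(cfg$config)
  if (!is.null(cfg$wtp)) params$wtp <- cfg$wtp
  params
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# plain-text run log echoing every effective input, enough to reproduce
# the run
write_run_log <- function(cfg, params, path, extra = character()) {
  tab <- parameter_table(params)
  lines <- c(
    "psptree run log",
    paste0("config: ", cfg$config),
    paste0("seed: ", cfg$seed),
    paste0("utility_mode: ", cfg$utility_mode),
    paste0("structure: observation_failure=", cfg$structure$observation_failure,
           " valve_failure=", cfg$structure$valve_failure,
           " vats_billing=", cfg$structure$vats_billing),
    paste0("wtp: ", params$wtp),
    extra,
    "effective parameters (name group base low high):",
    sprintf("  %s %s %.6g %.6g %.6g", tab$parameter, tab$group,
            tab$base, tab$low, tab$high))
  writeLines(lines, path)
  path
}

#' Base-case report: per-strategy outcomes and incremental table
#'
#' Runs load -> build -> rollback -> outcomes and writes
#' `base_case.csv` (one row per strategy, ordered by decreasing NMB),
#' `incremental.csv` (differences versus the NMB-optimal strategy) and
#' `run_log.txt` to the output directory.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the two tables and the written paths.
#' @export
run_base_case <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "psp_run_config"))
  paths <- prepare_out(cfg, c("base_case.csv", "incremental.csv",
                              "run_log.txt"))
  params <- load_run(cfg)
  tree <- build_psp_tree(params, cfg$structure)
  outcomes <- strategy_outcomes(tree, params, cfg$utility_mode)
  ord <- match(rank_by_nmb(outcomes), outcomes$strategy)
  base_tab <- data.frame(strategy = outcomes$strategy,
                         cost_usd = round(outcomes$expected_cost),
                         effectiveness_qaly = round(outcomes$effectiveness, 2),
                         nmb_usd = round(outcomes$nmb))[ord, ]
  rownames(base_tab) <- NULL
  inc <- incremental_analysis(outcomes)
  inc_tab <- data.frame(strategy = inc$strategy,
                        reference = inc$reference,
                        delta_cost_usd = round(inc$delta_cost),
                        delta_effectiveness_qaly = round(inc$delta_effectiveness, 2),
                        icer_usd_per_qaly = round(inc$icer),
                        dominated = inc$dominated,
                        delta_nmb_usd = round(inc$delta_nmb))
  write_table(base_tab, paths[["base_case.csv"]])
  write_table(inc_tab, paths[["incremental.csv"]])
  write_run_log(cfg, params, paths[["run_log.txt"]])
  invisible(list(base_case = base_tab, incremental = inc_tab,
                 outcomes = outcomes, paths = paths))
}

#' Tornado report: one-way sensitivity analysis over all ranged parameters
#'
#' Writes `tornado.csv` (one row per ranged parameter, sorted by bar
#' width) and `run_log.txt`.
#'
#' @param cfg A [run_config()].
#' @param metric,strategy Passed to [tornado_analysis()].
#' @return Invisibly, the tornado table and written paths.
#' @export
run_dsa <- function(cfg = run_config(), metric = "frontier",
                    strategy = NULL) {
  stopifnot(inherits(cfg, "psp_run_config"))
  paths <- prepare_out(cfg, c("tornado.csv", "run_log.txt"))
  params <- load_run(cfg)
  tor <- tornado_analysis(params, cfg$structure, cfg$utility_mode,
                          metric = metric, strategy = strategy)
  write_table(as.data.frame(tor), paths[["tornado.csv"]])
  write_run_log(cfg, params, paths[["run_log.txt"]],
                extra = paste0("tornado_metric: ", metric))
  invisible(list(tornado = tor, paths = paths))
}

#' PSA report: Monte Carlo samples, summary and acceptability curve
#'
#' Writes `psa_samples.csv` (one row per draw and strategy),
#' `psa_summary.csv`, `ceac.csv` and `run_log.txt`.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the `psp_psa` object, the CEAC table and paths.
#' @export
run_psa_report <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "psp_run_config"))
  paths <- prepare_out(cfg, c("psa_samples.csv", "psa_summary.csv",
                              "ceac.csv", "run_log.txt"))
  params <- load_run(cfg)
  psa <- run_psa(params, n = cfg$psa_n, seed = cfg$seed,
                 structure = cfg$structure,
                 utility_mode = cfg$utility_mode)
  cc <- ceac(psa, cfg$wtp_grid)
  write_table(psa$samples, paths[["psa_samples.csv"]])
  write_table(psa$summary, paths[["psa_summary.csv"]])
  write_table(as.data.frame(cc), paths[["ceac.csv"]])
  write_run_log(cfg, params, paths[["run_log.txt"]],
                extra = paste0("psa_n: ", cfg$psa_n))
  invisible(list(psa = psa, ceac = cc, paths = paths))
}

#' Microsimulation report: patient-level cohort per strategy
#'
#' Simulates `microsim_n` patients through every strategy and writes
#' `cohort.csv` (one row per patient) and `run_log.txt`.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the cohort table and written paths.
#' @export
run_microsim_report <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "psp_run_config"))
  paths <- prepare_out(cfg, c("cohort.csv", "run_log.txt"))
  params <- load_run(cfg)
  tree <- build_psp_tree(params, cfg$structure)
  cohorts <- lapply(seq_along(psp_strategies()), function(i)
    simulate_patients(tree, psp_strategies()[i], cfg$microsim_n,
                      seed = cfg$seed + i - 1L))
  cohort <- do.call(rbind, cohorts)
  write_table(cohort, paths[["cohort.csv"]])
  write_run_log(cfg, params, paths[["run_log.txt"]],
                extra = paste0("microsim_n: ", cfg$microsim_n))
  invisible(list(cohort = cohort, paths = paths))
}
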