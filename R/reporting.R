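#' Tabulate operating characteristics of several studies
#'
#' Flattens a list of `umbrella_study` objects into one row per study, laid
#' out like the simulation report tables: allocation proportions (percent,
#' two decimals, with the min-max range across replicates), proportion of
#' patients on their best available arm, the three headline rejection rates
#' (treatment 1 in the biomarker-1 and biomarker-2 populations, treatment 2
#' in the biomarker-1 population) with Monte-Carlo standard errors, and
#' bias/MSE of the tracked estimand.
#'
#' @param studies A non-empty list of `umbrella_study` objects.
#' @return A tibble with one row per study.
#' @export
render_tables <- function(studies) {
  if (length(studies) == 0) abort_config("`studies` must be non-empty.")
  if (inherits(studies, "umbrella_study")) studies <- list(studies)
  purrr::map_dfr(studies, function(s) {
    g <- s$summary
    rate_of <- function(k, l) {
      r <- dplyr::filter(s$rejections, .data$treatment == k, .data$biomarker == l)
      if (nrow(r) == 0) c(NA_real_, NA_real_) else c(r$rate, r$mc_se)
    }
    r11 <- rate_of(1, 1); r12 <- rate_of(1, 2); r21 <- rate_of(2, 1)
    tibble(
      strategy = g$strategy,
      params = strategy_param_string(s$strategy),
      scenario = g$scenario,
      scenario_label = s$scenario$label,
      reps = g$reps,
      prop_experimental_pct = round(100 * g$prop_experimental, 2),
      prop_experimental_min_pct = round(100 * g$prop_experimental_min, 2),
      prop_experimental_max_pct = round(100 * g$prop_experimental_max, 2),
      prop_best_pct = round(100 * g$prop_best, 2),
      reject_T1_B1_pct = round(100 * r11[1], 2),
      reject_T1_B1_se_pct = round(100 * r11[2], 3),
      reject_T1_B2_pct = round(100 * r12[1], 2),
      reject_T1_B2_se_pct = round(100 * r12[2], 3),
      reject_T2_B1_pct = round(100 * r21[1], 2),
      reject_T2_B1_se_pct = round(100 * r21[2], 3),
      bias = g$bias, mse = g$mse, flagged = g$flagged)
  })
}

strategy_param_string <- function(strategy) {
  switch(strategy$name,
    RFAC = paste0("theta=", strategy$theta, ";scope=", strategy$scope),
    HIER = paste0("rho=", strategy$rho),
    CR   = paste0("phi=", strategy$phi, ";mode=", strategy$mode),
    BAR  = paste0("method=", strategy$method),
    "")
}

design_as_list <- function(design) {
  list(K = design$K, prevalences = design$prevalences, N = design$n_max,
       interims = design$interims, test_level = design$test_level,
       negative_policy = design$negative_policy)
}

#' Read a trial design from a YAML/JSON config file
#'
#' Accepted keys: `K`, `prevalences`, `N`, `interims`, `test_level`,
#' `negative_policy`; missing keys fall back to the package defaults.  The
#' parsed design is echoed bit-exactly into every run manifest.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [trial_design()].
#' @export
read_design_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("Config file not found: ", path))
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  d <- trial_design()
  # YAML 1.1 parses a bare `N` key as boolean FALSE; accept that spelling too
  n_max <- cfg$N %||% cfg$n_max %||% cfg[["FALSE"]]
  trial_design(K = cfg$K %||% d$K,
               prevalences = unlist(cfg$prevalences) %||% d$prevalences,
               n_max = n_max %||% d$n_max,
               interims = unlist(cfg$interims) %||%
                 d$interims[d$interims < (n_max %||% d$n_max)],
               test_level = cfg$test_level %||% d$test_level,
               negative_policy = cfg$negative_policy %||% d$negative_policy)
}

#' Write a run manifest
#'
#' Serialises the full run configuration (design echo, scenario
#' coefficients, strategy parameters, replicates, seed, package version and
#' a content hash of the configuration) as JSON, so identical configurations
#' and seeds are verifiably identical runs.
#'
#' @param study An `umbrella_study`.
#' @param path Output path for the JSON manifest.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(study, path) {
  strategy <- study$strategy
  config <- list(
    design = design_as_list(study$design),
    scenario = list(name = study$scenario$name, label = study$scenario$label,
                    alpha = study$scenario$alpha, beta = study$scenario$beta,
                    gamma = study$scenario$gamma,
                    delta = study$scenario$delta),
    strategy = strategy[setdiff(names(strategy), c("state_dependent", "adaptive"))],
    reps = study$summary$reps, seed = study$summary$seed)
  manifest <- list(config = config,
                   config_hash = rlang::hash(config),
                   package_version = as.character(utils::packageVersion("umbrellasim")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(manifest)
}

strategy_from_name <- function(name, opts = list()) {
  num <- function(key, default) as.numeric(opts[[key]] %||% default)
  switch(tolower(name),
    er = strategy_er(),
    rfac = strategy_rfac(theta = num("theta", 0.2),
                         scope = opts$rfac_scope %||% "multi_and_negative"),
    hier = strategy_hier(rho = num("rho", 0.9)),
    cr = strategy_cr(phi = num("phi", 0.75),
                     mode = opts$cr_mode %||% "control_paired"),
    bar = strategy_bar(method = opts$bar_method %||% "laplace",
                       tuning_power = num("tuning_power", 1)),
    abort_config(paste0("Unknown strategy `", name,
                        "`. Valid names: er, rfac, hier, cr, bar."))
  )
}

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      abort_config(paste0("Unexpected argument `", a, "`."))
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1], "--"))
      abort_config(paste0("Missing value for --", key, "."))
    opts[[key]] <- args[i + 1]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' Thin argument-parsing layer over the package functions, used by the
#' shipped `inst/cli/umbrellasim.R` script.  Subcommands:
#'
#' * `simulate` — one study: `--strategy er --scenario scenario1 --reps 100
#'   --seed 7 --out DIR` (optional `--config design.yaml`, `--theta`,
#'   `--rho`, `--phi`, `--cr_mode`, `--rfac_scope`, `--bar_method`); writes
#'   `study.csv` and `manifest.json` into `DIR`.
#' * `table` — a strategy-by-scenario grid: `--strategies er,rfac
#'   --scenarios scenario1,scenario2 --reps 1000 --seed 1 --out DIR`;
#'   writes `table.csv` with one row per (strategy, scenario).
#' * `sweep` — power sweep: `--axis n_max --values 200,400,600 --strategies
#'   er --scenario scenario2 --reps 500 --seed 1 --out DIR`.
#' * `calibrate` — effect calibration: `--strategy cr --target 0.8
#'   --reps 500 --seed 1`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0)
      abort_config("Usage: umbrellasim.R {simulate|table|sweep|calibrate} [--key value ...]")
    sub <- args[1]
    opts <- parse_cli_args(args[-1])
    design <- if (!is.null(opts$config)) read_design_config(opts$config)
              else trial_design()
    reps <- as.integer(opts$reps %||% 100)
    seed <- as.integer(opts$seed %||% 1)
    out <- opts$out %||% "."
    if (sub %in% c("simulate", "table", "sweep") && !dir.exists(out))
      dir.create(out, recursive = TRUE)
    if (sub == "simulate") {
      strategy <- strategy_from_name(opts$strategy %||% "er", opts)
      scenario <- get_scenario(opts$scenario %||% "scenario1")
      message(format(Sys.time()), " simulate: ", strategy$name, " / ",
              scenario$name, ", ", reps, " replicates")
      st <- run_study(design, scenario, strategy, reps = reps, seed = seed)
      utils::write.csv(render_tables(list(st)),
                       file.path(out, "study.csv"), row.names = FALSE)
      write_manifest(st, file.path(out, "manifest.json"))
      message(format(Sys.time()), " wrote ", file.path(out, "study.csv"))
    } else if (sub == "table") {
      strategies <- strsplit(opts$strategies %||% "er", ",")[[1]]
      scenarios <- strsplit(opts$scenarios %||% "scenario1", ",")[[1]]
      studies <- list()
      for (sc in scenarios) for (stn in strategies) {
        message(format(Sys.time()), " table cell: ", stn, " / ", sc)
        studies[[paste(stn, sc)]] <- run_study(
          design, get_scenario(sc), strategy_from_name(stn, opts),
          reps = reps, seed = seed)
      }
      utils::write.csv(render_tables(studies),
                       file.path(out, "table.csv"), row.names = FALSE)
      message(format(Sys.time()), " wrote ", file.path(out, "table.csv"))
    } else if (sub == "sweep") {
      strategies <- strsplit(opts$strategies %||% "er", ",")[[1]]
      strategies <- setNames(lapply(strategies, strategy_from_name, opts = opts),
                             strategies)
      values <- as.numeric(strsplit(opts$values %||% "200,400", ",")[[1]])
      sw <- sweep_power(design, get_scenario(opts$scenario %||% "scenario2"),
                        strategies, axis = opts$axis %||% "n_max",
                        values = values, reps = reps, seed = seed)
      utils::write.csv(sw, file.path(out, "sweep.csv"), row.names = FALSE)
      message(format(Sys.time()), " wrote ", file.path(out, "sweep.csv"))
    } else if (sub == "calibrate") {
      strategy <- strategy_from_name(opts$strategy %||% "er", opts)
      cal <- calibrate_effect(design, strategy, get_scenario("scenario1"),
                              target_power = as.numeric(opts$target %||% 0.8),
                              reps = reps, seed = seed)
      message("calibrated value: ", format(cal$value),
              " (achieved power ", format(cal$power), ")")
    } else {
      abort_config(paste0("Unknown subcommand `", sub, "`."))
    }
    0L
  }, error = function(e) {
    message("Error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
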