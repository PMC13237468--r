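#' Descriptive summary of the analysis sample
#'
#' Proportions of the exposure, the WASH categories, wealth, education and
#' residence (with an exposure-by-residence cross-tab) plus the outcome mean,
#' in the shape of the descriptive tables of a survey report. Empty tables
#' yield an empty summary without error.
#'
#' @param data Analysis table.
#' @return A tibble with columns `variable`, `level`, `statistic`, `value`.
#' @export
summarize_survey <- function(data) {
  data <- tibble::as_tibble(data)
  empty <- tibble::tibble(variable = character(), level = character(),
                          statistic = character(), value = double())
  if (nrow(data) == 0L) return(empty)
  out <- list()
  prop_block <- function(var) {
    if (!var %in% names(data)) return(NULL)
    tab <- table(data[[var]], useNA = "no")
    if (sum(tab) == 0) return(NULL)
    tibble::tibble(variable = var, level = names(tab),
                   statistic = "proportion",
                   value = as.numeric(tab) / sum(tab))
  }
  out$mhm <- if ("mhm" %in% names(data)) {
    tibble::tibble(variable = "mhm", level = "1", statistic = "proportion",
                   value = mean(data$mhm, na.rm = TRUE))
  }
  out$wash <- prop_block("wash")
  out$wealth <- prop_block("wealth")
  out$education <- prop_block("education")
  out$residence <- prop_block("residence")
  if (all(c("mhm", "residence") %in% names(data))) {
    ct <- stats::aggregate(mhm ~ residence, data = data, FUN = mean,
                           na.action = stats::na.omit)
    out$cross <- tibble::tibble(variable = "mhm_by_residence",
                                level = as.character(ct$residence),
                                statistic = "proportion", value = ct$mhm)
  }
  for (v in c("ceb", "live_births", "age")) {
    if (v %in% names(data)) {
      out[[paste0("mean_", v)]] <- tibble::tibble(
        variable = v, level = NA_character_, statistic = "mean",
        value = mean(data[[v]], na.rm = TRUE))
    }
  }
  dplyr::bind_rows(out)
}

#' Build a run configuration
#'
#' Either loads a YAML configuration file or assembles one from arguments.
#' Exactly one of `input` (a CSV path) and `simulate` (a [sim_config()] or a
#' list of its arguments) must be present. An optional `column_mapping`
#' (named list: canonical name = source column) renames input columns.
#'
#' @param path Optional YAML file path; fields given as arguments override it.
#' @param input CSV path of microdata.
#' @param simulate A [sim_config()] or argument list for one.
#' @param roles A [cf_roles()]; defaults to [default_roles()].
#' @param column_mapping Named list mapping canonical to source column names.
#' @param n_boot Bootstrap replicates for the main fit.
#' @param seed Master seed.
#' @param impute_policy `"deterministic"` or `"stochastic"`.
#' @param level Significance level for verdicts.
#' @param output_dir Optional directory for report files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(path = NULL, input = NULL, simulate = NULL,
                       roles = NULL, column_mapping = NULL, n_boot = 200L,
                       seed = 1L, impute_policy = "deterministic",
                       level = 0.05, output_dir = NULL) {
  cfg <- list()
  if (!is.null(path)) {
    cfg <- yaml::read_yaml(path)
  }
  if (!is.null(input)) cfg$input <- input
  if (!is.null(simulate)) cfg$simulate <- simulate
  if (!is.null(column_mapping)) cfg$column_mapping <- column_mapping
  if (!is.null(cfg$simulate) && !inherits(cfg$simulate, "sim_config")) {
    cfg$simulate <- do.call(sim_config, cfg$simulate)
  }
  if (is.null(cfg$input) == is.null(cfg$simulate)) {
    stop("exactly one of `input` and `simulate` must be given", call. = FALSE)
  }
  if (!is.null(roles)) {
    cfg$roles <- roles
  } else if (!is.null(cfg$roles) && !inherits(cfg$roles, "cf_roles")) {
    cfg$roles <- do.call(cf_roles, cfg$roles)
  } else if (is.null(cfg$roles)) {
    cfg$roles <- default_roles()
  }
  cfg$n_boot <- if (!missing(n_boot) || is.null(cfg$n_boot)) n_boot else cfg$n_boot
  cfg$seed <- if (!missing(seed) || is.null(cfg$seed)) seed else cfg$seed
  cfg$impute_policy <- cfg$impute_policy %||% impute_policy
  cfg$level <- cfg$level %||% level
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  structure(cfg, class = "run_config")
}

read_survey_csv <- function(path, column_mapping = NULL) {
  data <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                            na.strings = c("", "NA")))
  if (!is.null(column_mapping)) {
    for (canonical in names(column_mapping)) {
      src <- column_mapping[[canonical]]
      if (!src %in% names(data)) {
        stop("mapped source column '", src, "' not found in ", path,
             call. = FALSE)
      }
      names(data)[names(data) == src] <- canonical
    }
  }
  data
}

log_line <- function(log, stage, message) {
  rec <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stage = stage, level = "info", message = message)
  c(log, jsonlite::toJSON(rec, auto_unbox = TRUE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: load or simulate the microdata, prepare it (variable
#' construction, filters, imputation), descriptive summary, first-stage probit
#' with average marginal effects, the Poisson 2SRI control-function fit with
#' pairs bootstrap, the NB2 sensitivity fit on total live births, instrument
#' diagnostics, the placebo test on household-head age, and the two
#' heterogeneity subsamples (rural; ages 15-29). All randomness derives from
#' the configured seed. When `output_dir` is set, writes CSV report tables
#' (first-stage marginal effects; second-stage coefficients with confidence
#' bounds and percentage-change effects), a machine-readable `results.json`,
#' and a JSON-lines `run.log`.
#'
#' @param config A [run_config()] (or a YAML path accepted by it).
#' @param seed Optional override of the configured seed.
#' @return Invisibly, a named list with every stage's result plus `results`,
#'   the flat numeric summary written to `results.json`.
#' @export
run_analysis <- function(config, seed = NULL) {
  if (is.character(config)) config <- run_config(path = config)
  stopifnot(inherits(config, "run_config"))
  seed <- seed %||% config$seed
  roles <- config$roles
  log <- character(0)

  if (!is.null(config$simulate)) {
    log <- log_line(log, "simulate", paste("seed", seed))
    raw <- strip_truth(simulate_survey(config$simulate, seed = seed))
  } else {
    log <- log_line(log, "load", config$input)
    raw <- read_survey_csv(config$input, config$column_mapping)
  }

  prep <- prepare_survey(raw, roles, impute_policy = config$impute_policy,
                         seed = seed)
  data <- prep$data
  log <- log_line(log, "prepare", paste("rows", nrow(data)))

  descriptives <- summarize_survey(data)

  main <- fit_cf_2sri(data, roles, family = "poisson",
                      n_boot = config$n_boot, seed = seed,
                      level = 1 - config$level)
  log <- log_line(log, "cf_2sri", paste("bootstrap", config$n_boot))
  me <- marginal_effects(main$first_stage)

  naive <- fit_poisson(data, roles)

  sens <- if ("live_births" %in% names(data)) {
    fit_cf_2sri(data, roles, family = "negbin", outcome = "live_births",
                n_boot = 0L, seed = seed)
  }
  diagnostics <- diagnose_instruments(data, roles, cf_fit = main)
  placebo <- if ("head_age" %in% names(data)) {
    run_placebo(data, roles, "head_age", level = config$level)
  }
  subsamples <- list()
  if ("residence" %in% names(data) &&
      sum(data$residence == "rural") >= 500) {
    subsamples$rural <- run_subsample(data, roles, residence == "rural",
                                      label = "rural", seed = seed)
  }
  if ("age" %in% names(data) && sum(data$age <= 29) >= 500) {
    subsamples$young <- run_subsample(data, roles, age <= 29,
                                      label = "age 15-29", seed = seed)
  }
  log <- log_line(log, "done", "pipeline complete")

  exposure <- roles$exposure
  et <- endogeneity_test(main)
  results <- list(
    n = nrow(data),
    exposure_share = mean(data[[exposure]]),
    outcome_mean = mean(data[[roles$outcome]]),
    gamma_naive = unname(naive$coefficients[exposure]),
    gamma_2sri = unname(main$second_stage$coefficients[exposure]),
    irr_percent_2sri = irr_percent(
      unname(main$second_stage$coefficients[exposure])),
    delta_residual = et$estimate,
    endogeneity_z = et$z,
    endogeneity_p = et$p_value,
    kp_rk_lm = diagnostics$kp_lm$statistic,
    kp_rk_lm_p = diagnostics$kp_lm$p_value,
    kp_rk_wald_f = diagnostics$kp_wald_f,
    cragg_donald_f = diagnostics$cragg_donald_f,
    hansen_j = diagnostics$hansen_j$statistic,
    hansen_j_p = diagnostics$hansen_j$p_value,
    stock_yogo_10pct_bias = diagnostics$stock_yogo_10pct_bias,
    nb_alpha = if (!is.null(sens)) sens$second_stage$nb_alpha,
    placebo_exposure_coef = if (!is.null(placebo)) placebo$exposure_estimate_iv,
    seed = seed
  )

  out <- list(config = config, seed = seed, prepared = data,
              audit = prep$audit, imputation = prep$imputation,
              descriptives = descriptives, first_stage = main$first_stage,
              marginal_effects = me, naive_poisson = naive, cf_2sri = main,
              sensitivity_nb = sens, diagnostics = diagnostics,
              placebo = placebo, subsamples = subsamples, results = results,
              log = log)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(me, file.path(config$output_dir,
                                   "first_stage_marginal_effects.csv"),
                     row.names = FALSE)
    utils::write.csv(tidy_second_stage(main),
                     file.path(config$output_dir, "second_stage.csv"),
                     row.names = FALSE)
    utils::write.csv(descriptives,
                     file.path(config$output_dir, "descriptives.csv"),
                     row.names = FALSE)
    jsonlite::write_json(results,
                         file.path(config$output_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(log, file.path(config$output_dir, "run.log"))
  }
  invisible(out)
}

# Table-shaped second-stage report: coefficient, CI bounds, percentage change.
tidy_second_stage <- function(fit) {
  stopifnot(inherits(fit, "cf_2sri_fit"))
  td <- generics::tidy(fit)
  td$irr_percent <- irr_percent(td$estimate)
  td$family <- fit$family
  td
}
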