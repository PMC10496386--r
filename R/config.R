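#' Load, validate and serialize an analysis configuration
#'
#' An analysis configuration bundles everything needed to run the full
#' evaluation: model settings, shared costs, utilities, the three strategy
#' arms (each with OS/PFS survival laws and arm-specific cost rates), and
#' the per-parameter deterministic-sensitivity bounds and probabilistic
#' sampling distributions. The shipped fixture
#' (`system.file("extdata", "taiwan_icc_2022.yaml", package = "psmcea")`)
#' carries the complete published parameter table for second-line
#' pemigatinib versus mFOLFOX and 5-FU in advanced intrahepatic
#' cholangiocarcinoma, in 2022 NT$.
#'
#' @param path Path to a YAML configuration file.
#' @return An `analysis_config` list: `settings`, `costs`, `utilities`,
#'   `arms`, `parameters`, `seed`.
#' @examples
#' cfg <- default_config()
#' cfg$settings$wtp_per_qaly
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  required <- c("settings", "costs", "utilities", "arms", "parameters")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("configuration is missing required sections: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  known <- c(required, "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("ignoring unknown configuration keys: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- structure(list(
    settings = do.call(model_settings, raw$settings),
    costs = do.call(cost_inputs, raw$costs),
    utilities = do.call(utility_inputs, raw$utilities),
    arms = lapply(raw$arms, validate_arm_spec),
    parameters = lapply(raw$parameters, validate_param_spec),
    seed = raw$seed %||% 1L), class = "analysis_config")
  names(cfg$parameters) <- vapply(cfg$parameters, `[[`, character(1), "name")
  n_int <- sum(vapply(cfg$arms, function(a) isTRUE(a$is_intervention),
                      logical(1)))
  if (n_int != 1) {
    stop("exactly one arm must have is_intervention: true", call. = FALSE)
  }
  for (nm in names(cfg$parameters)) {
    if (is.null(param_target(nm))) {
      stop("unknown parameter name in configuration: ", nm, call. = FALSE)
    }
  }
  cfg
}

validate_arm_spec <- function(a) {
  req <- c("label", "os", "pfs", "medication_cost_per_year",
           "nonmedication_cost_per_year", "ae_grade3_proportion",
           "iv_administered")
  missing <- setdiff(req, names(a))
  if (length(missing)) {
    stop("arm specification missing fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  a$is_intervention <- isTRUE(a$is_intervention)
  # constructing the curves validates families and parameter domains
  surv_dist(a$os$family, as.numeric(a$os$params))
  surv_dist(a$pfs$family, as.numeric(a$pfs$params))
  stopifnot(a$ae_grade3_proportion >= 0, a$ae_grade3_proportion <= 1,
            a$medication_cost_per_year >= 0,
            a$nonmedication_cost_per_year >= 0)
  a
}

#' @rdname load_config
#' @export
default_config <- function() {
  load_config(system.file("extdata", "taiwan_icc_2022.yaml",
                          package = "psmcea", mustWork = TRUE))
}

#' @rdname load_config
#' @param config An `analysis_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  out <- list(
    settings = config$settings[c("horizon_years", "cycles_per_year",
                                 "annual_discount_rate", "wtp_per_qaly",
                                 "half_cycle_correction")],
    costs = unclass(config$costs),
    utilities = unclass(config$utilities),
    arms = config$arms,
    parameters = unname(lapply(config$parameters, unclass)),
    seed = config$seed)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf(paste0("<analysis_config> %d arms (%s), horizon %g y, ",
                     "discount %g%%, WTP NT$%s/QALY, %d parameters\n"),
              length(x$arms), paste(names(x$arms), collapse = ", "),
              x$settings$horizon_years,
              100 * x$settings$annual_discount_rate,
              format(x$settings$wtp_per_qaly, big.mark = ","),
              length(x$parameters)))
  invisible(x)
}

#' Build strategy arms from a configuration
#'
#' @param config An `analysis_config`.
#' @return Named list of [strategy_arm()] objects.
#' @export
build_arms <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  lapply(config$arms, function(a) {
    strategy_arm(
      name = a$label,
      os = surv_dist(a$os$family, as.numeric(a$os$params)),
      pfs = surv_dist(a$pfs$family, as.numeric(a$pfs$params)),
      medication_cost_per_year = a$medication_cost_per_year,
      nonmedication_cost_per_year = a$nonmedication_cost_per_year,
      ae_grade3_proportion = a$ae_grade3_proportion,
      iv_administered = isTRUE(a$iv_administered),
      is_intervention = isTRUE(a$is_intervention))
  })
}

#' Run the deterministic model for every arm in a configuration
#'
#' @param config An `analysis_config`.
#' @return Named list of `arm_outcomes`.
#' @export
run_model <- function(config) {
  arms <- build_arms(config)
  lapply(arms, run_arm, costs = config$costs,
         utilities = config$utilities, settings = config$settings)
}

intervention_key <- function(config) {
  names(config$arms)[vapply(config$arms,
                            function(a) isTRUE(a$is_intervention),
                            logical(1))]
}

comparator_keys <- function(config) {
  setdiff(names(config$arms), intervention_key(config))
}

#' Deterministic base-case results table
#'
#' Runs every arm and assembles per-arm discounted totals plus pairwise
#' incremental results (intervention versus each comparator): incremental
#' cost, incremental LY/QALY, ICERs on both effect scales, and INMB at the
#' configured willingness-to-pay threshold.
#'
#' @param config An `analysis_config`.
#' @return A `base_case` list: `outcomes` (per-arm list), `arm_table`
#'   (data frame, one row per arm), `incremental` (data frame, one row per
#'   comparator), `wtp`.
#' @examples
#' bc <- run_base_case(default_config())
#' bc$incremental
#' @export
run_base_case <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  out <- run_model(config)
  int_key <- intervention_key(config)
  comps <- comparator_keys(config)
  wtp <- config$settings$wtp_per_qaly

  fields <- c("ly_pf", "ly_total", "qaly_pf", "qaly_total",
              "cost_medication", "cost_nonmedication", "cost_pd_supportive",
              "cost_testing", "cost_total")
  arm_table <- data.frame(
    arm = vapply(out, `[[`, character(1), "arm"),
    sapply(fields, function(f) vapply(out, `[[`, numeric(1), f)),
    row.names = NULL, check.names = TRUE)

  incremental <- do.call(rbind, lapply(comps, function(cm) {
    iq <- icer(out[[int_key]], out[[cm]], "qaly")
    il <- icer(out[[int_key]], out[[cm]], "ly")
    data.frame(comparator = out[[cm]]$arm,
               delta_cost = iq$delta_cost,
               delta_qaly = iq$delta_effect, delta_ly = il$delta_effect,
               icer_qaly = iq$icer, icer_ly = il$icer,
               inmb_qaly = inmb(out[[int_key]], out[[cm]], wtp, "qaly"),
               inmb_ly = inmb(out[[int_key]], out[[cm]], wtp, "ly"))
  }))
  rownames(incremental) <- NULL
  structure(list(outcomes = out, arm_table = arm_table,
                 incremental = incremental, wtp = wtp,
                 intervention = int_key, comparators = comps),
            class = "base_case")
}

#' @export
print.base_case <- function(x, ...) {
  cat("Partitioned survival model, deterministic base case\n\n")
  tab <- x$arm_table
  tab[-1] <- lapply(tab[-1], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  cat(sprintf("\nIncremental (vs %s), WTP NT$%s/QALY:\n",
              x$outcomes[[x$intervention]]$arm,
              format(x$wtp, big.mark = ",")))
  inc <- x$incremental
  for (cc in c("delta_cost", "icer_qaly", "icer_ly", "inmb_qaly", "inmb_ly"))
    inc[[cc]] <- round(inc[[cc]])
  print(inc, row.names = FALSE)
  invisible(x)
}

#' Modify a configuration by named parameter values
#'
#' Applies named parameter values (the names used in the `parameters`
#' section, e.g. `os_pem_scale`, `cost_med_pem`, `u_pf`, `discount_rate`)
#' onto a configuration, returning a new configuration. This single mapping
#' backs both the tornado analysis and the probabilistic draws.
#'
#' @param config An `analysis_config`.
#' @param values Named numeric vector/list of parameter values.
#' @return The modified `analysis_config`.
#' @export
apply_params <- function(config, values) {
  stopifnot(inherits(config, "analysis_config"))
  for (nm in names(values)) {
    tgt <- param_target(nm)
    if (is.null(tgt)) stop("unknown parameter: ", nm, call. = FALSE)
    config <- tgt(config, as.numeric(values[[nm]]))
  }
  # re-validate derived settings objects
  config$settings <- do.call(model_settings,
    config$settings[c("horizon_years", "cycles_per_year",
                      "annual_discount_rate", "wtp_per_qaly",
                      "half_cycle_correction")])
  config
}

# map a parameter name to a closure updating the configuration
param_target <- function(name) {
  set_surv <- function(arm, curve, i) function(cfg, v) {
    cfg$arms[[arm]][[curve]]$params[i] <- v; cfg
  }
  set_arm <- function(arm, field) function(cfg, v) {
    cfg$arms[[arm]][[field]] <- v; cfg
  }
  set_in <- function(section, field) function(cfg, v) {
    cfg[[section]][[field]] <- v; cfg
  }
  switch(name,
    os_pem_scale      = set_surv("pemigatinib", "os", 1),
    os_pem_shape      = set_surv("pemigatinib", "os", 2),
    pfs_pem_meanlog   = set_surv("pemigatinib", "pfs", 1),
    pfs_pem_sdlog     = set_surv("pemigatinib", "pfs", 2),
    os_mfolfox_meanlog  = set_surv("mfolfox", "os", 1),
    os_mfolfox_sdlog    = set_surv("mfolfox", "os", 2),
    pfs_mfolfox_meanlog = set_surv("mfolfox", "pfs", 1),
    pfs_mfolfox_sdlog   = set_surv("mfolfox", "pfs", 2),
    os_fu_meanlog     = set_surv("fu", "os", 1),
    os_fu_sdlog       = set_surv("fu", "os", 2),
    pfs_fu_meanlog    = set_surv("fu", "pfs", 1),
    pfs_fu_sdlog      = set_surv("fu", "pfs", 2),
    cost_med_pem      = set_arm("pemigatinib", "medication_cost_per_year"),
    cost_med_mfolfox  = set_arm("mfolfox", "medication_cost_per_year"),
    cost_med_fu       = set_arm("fu", "medication_cost_per_year"),
    cost_nonmed_pem   = set_arm("pemigatinib", "nonmedication_cost_per_year"),
    cost_nonmed_chemo = function(cfg, v) {
      cfg$arms$mfolfox$nonmedication_cost_per_year <- v
      cfg$arms$fu$nonmedication_cost_per_year <- v
      cfg
    },
    cost_supportive     = set_in("costs", "supportive_care_per_year"),
    genetic_testing_fee = set_in("costs", "genetic_testing_fee"),
    conversion_factor   = set_in("costs", "nonmedication_conversion_factor"),
    u_pf              = set_in("utilities", "u_pf"),
    u_pd              = set_in("utilities", "u_pd"),
    disutility_ae     = set_in("utilities", "disutility_ae"),
    disutility_iv     = set_in("utilities", "disutility_iv"),
    ae_prop_pem       = set_arm("pemigatinib", "ae_grade3_proportion"),
    ae_prop_mfolfox   = set_arm("mfolfox", "ae_grade3_proportion"),
    ae_prop_fu        = set_arm("fu", "ae_grade3_proportion"),
    discount_rate     = set_in("settings", "annual_discount_rate"),
    horizon_years     = set_in("settings", "horizon_years"),
    NULL)
}

#' Write result tables and a run log
#'
#' @param dir Output directory (created if needed).
#' @param tables Named list of data frames; each is written as `<name>.csv`.
#' @param seed Master seed used for the run.
#' @param config_path Path of the configuration file the run used (hashed
#'   into the log), or `NULL`.
#' @return The directory, invisibly. A `run_log.txt` records the seed,
#'   configuration checksum and package version so every number is
#'   regenerable.
#' @export
write_results <- function(dir, tables, seed = NA, config_path = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  hash <- if (!is.null(config_path)) unname(tools::md5sum(config_path))
          else NA_character_
  writeLines(c(
    sprintf("psmcea %s", as.character(utils::packageVersion("psmcea"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %s", seed),
    sprintf("config_md5: %s", hash),
    sprintf("tables: %s", paste(names(tables), collapse = ", "))),
    file.path(dir, "run_log.txt"))
  invisible(dir)
}
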