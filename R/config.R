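#' Path to the packaged base-case configuration
#' @export
default_config_path <- function() {
  system.file("extdata", "base_case.yaml", package = "ceahcc",
              mustWork = TRUE)
}

config_known_keys <- function() list(
  top = c("model", "survival", "arms", "sensitivity", "psa", "life_table"),
  model = names(formals(model_config)),
  os = c("median_months", "landmark_time_months", "landmark_survival", "shape"),
  pfs = c("median_months", "shape"),
  arm = c("drug_cost_per_cycle", "admin_cost_per_cycle", "utility_pf",
          "utility_pp", "ae_profile", "postprog_treated_fraction",
          "postprog_cost_per_cycle", "postprog_duration_cycles", "eol_cost"),
  spec = c("name", "path", "base", "low", "high", "distribution"))

reject_unknown <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

# OS curves: an arm with a printed landmark is calibrated to
# median + landmark; arms with only a median share the landmark arm's
# Weibull shape (exponential if no arm has a landmark or shape).
build_os_curves <- function(os_cfg) {
  shapes <- list()
  curves <- list()
  landmark_arm <- NULL
  for (a in names(os_cfg)) {
    e <- os_cfg[[a]]
    reject_unknown(e, config_known_keys()$os, paste0("survival.os.", a))
    if (!is.null(e$landmark_time_months)) {
      curves[[a]] <- calibrate_weibull(
        e$median_months,
        landmark = c(e$landmark_time_months, e$landmark_survival))
      landmark_arm <- a
    } else if (!is.null(e$shape)) {
      curves[[a]] <- calibrate_weibull(e$median_months, shape = e$shape)
    }
  }
  for (a in setdiff(names(os_cfg), names(curves))) {
    e <- os_cfg[[a]]
    if (!is.null(landmark_arm)) {
      k <- curves[[landmark_arm]]$params$shape
      curves[[a]] <- calibrate_weibull(e$median_months, shape = k)
    } else {
      curves[[a]] <- calibrate_weibull(e$median_months)
    }
  }
  curves[names(os_cfg)]
}

#' Load and validate a model configuration
#'
#' Reads the YAML schema (`model`, `survival`, `arms`, and optional
#' `sensitivity`, `psa`, `life_table` sections), rejects unknown keys,
#' fills documented defaults, builds the survival curves from the
#' calibration statements, and returns the assembled model context plus
#' the sensitivity parameter set.
#'
#' @param path YAML file; defaults to the packaged base case.
#' @return a list with `context` (a [cea_context()]), `specs` (list of
#'   [param_spec()]) and `psa_n` (default PSA draw count).
#' @export
load_config <- function(path = default_config_path()) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg) || !is.list(cfg)) {
    stop("empty configuration; required sections: model, survival, arms",
         call. = FALSE)
  }
  reject_unknown(cfg, config_known_keys()$top, "configuration")
  for (sec in c("model", "survival", "arms")) {
    if (is.null(cfg[[sec]])) {
      stop(sprintf("configuration is missing required section '%s' (required: model, survival, arms)",
                   sec), call. = FALSE)
    }
  }
  reject_unknown(cfg$model, config_known_keys()$model, "model")
  config <- do.call(model_config, cfg$model)

  if (is.null(cfg$survival$os) || is.null(cfg$survival$pfs)) {
    stop("survival section needs 'os' and 'pfs' blocks", call. = FALSE)
  }
  arm_names <- names(cfg$arms)
  if (length(arm_names) != 2) {
    stop("exactly two arms are required (reference first)", call. = FALSE)
  }
  if (!setequal(names(cfg$survival$os), arm_names) ||
      !setequal(names(cfg$survival$pfs), arm_names)) {
    stop("survival.os and survival.pfs must cover exactly the configured arms",
         call. = FALSE)
  }
  os_curves <- build_os_curves(cfg$survival$os)
  pfs_curves <- lapply(arm_names, function(a) {
    e <- cfg$survival$pfs[[a]]
    reject_unknown(e, config_known_keys()$pfs, paste0("survival.pfs.", a))
    calibrate_weibull(e$median_months,
                      shape = if (is.null(e$shape)) NULL else e$shape)
  })
  names(pfs_curves) <- arm_names

  arms <- lapply(arm_names, function(a) {
    e <- cfg$arms[[a]]
    reject_unknown(e, config_known_keys()$arm, paste0("arms.", a))
    e$name <- a
    e$os_curve <- os_curves[[a]]
    e$pfs_curve <- pfs_curves[[a]]
    do.call(arm_parameters, e)
  })

  lt <- if (is.null(cfg$life_table) || identical(cfg$life_table, "default")) {
    default_life_table()
  } else {
    read_life_table(cfg$life_table)
  }

  specs <- if (is.null(cfg$sensitivity) || identical(cfg$sensitivity, "default")) {
    default_parameter_specs()
  } else {
    lapply(cfg$sensitivity, function(s) {
      reject_unknown(s, config_known_keys()$spec, "sensitivity entry")
      do.call(param_spec, s)
    })
  }
  psa_n <- if (is.null(cfg$psa$n_draws)) 10000L else as.integer(cfg$psa$n_draws)

  list(context = cea_context(config, arms, lt), specs = specs, psa_n = psa_n)
}

#' Base-case model context
#'
#' Convenience wrapper: the context of the packaged base-case
#' configuration.
#' @return a [cea_context()].
#' @export
base_case_context <- function() load_config()$context

#' Published base-case values being reproduced
#'
#' The headline results reported by the published cost-effectiveness
#' analysis this package re-implements, used only for side-by-side
#' comparison in [reproduce_analysis()].
#'
#' @return a named numeric vector.
#' @export
published_reference <- function() {
  c(life_years_pembrolizumab = 1.324,
    life_years_placebo = 1.171,
    incremental_life_years = 0.153,
    qalys_pembrolizumab = 0.954,
    qalys_placebo = 0.816,
    incremental_qalys = 0.138,
    incremental_cost = 47057,
    icer_per_life_year = 308377,
    icer_per_qaly = 340409,
    threshold_price_per_cycle = 2925,
    threshold_pct_reduction = 57.7,
    icer_cure_scenario = 222109,
    icer_q6w_schedule = 286884,
    icer_horizon_5y = 233064,
    icer_horizon_10y = 197305,
    icer_horizon_lifetime = 196317)
}

result_row <- function(res) {
  data.frame(
    quantity = c("life_years_pembrolizumab", "life_years_placebo",
                 "incremental_life_years", "qalys_pembrolizumab",
                 "qalys_placebo", "incremental_qalys", "incremental_cost",
                 "icer_per_life_year", "icer_per_qaly"),
    value = c(res$comparator$life_years, res$reference$life_years, res$d_ly,
              res$comparator$qalys, res$reference$qalys, res$d_qaly,
              res$d_cost, res$icer_per_ly, res$icer_per_qaly))
}

#' Reproduce the full analysis suite
#'
#' Runs the packaged base case end to end — base-case comparison, one-way
#' sensitivity (tornado), threshold price search, scenario analyses and
#' (unless skipped) the probabilistic sensitivity analysis — writes all
#' outputs as CSV/JSON under `outdir`, prints a side-by-side comparison
#' against the published values, and returns a run manifest.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed for the PSA.
#' @param n_psa Monte Carlo draws (defaults to the configured count).
#' @param skip_psa skip the probabilistic stage.
#' @param config_path configuration file.
#' @param quiet suppress console output.
#' @return (invisibly) the manifest list, also written as
#'   `manifest.json`.
#' @export
reproduce_analysis <- function(outdir, seed = 1L, n_psa = NULL,
                               skip_psa = FALSE,
                               config_path = default_config_path(),
                               quiet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    v <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    v
  }
  bundle <- stage("load_config", load_config(config_path))
  ctx <- bundle$context
  if (is.null(n_psa)) n_psa <- bundle$psa_n

  base <- stage("base_case", run_cea(ctx))
  tab <- result_row(base)
  tab$published <- unname(published_reference()[tab$quantity])
  tab$rel_diff_pct <- 100 * (tab$value - tab$published) / tab$published
  utils::write.csv(tab, file.path(outdir, "cea_table.csv"), row.names = FALSE)

  torn <- stage("tornado", one_way(bundle$specs, ctx))
  utils::write.csv(torn, file.path(outdir, "tornado.csv"), row.names = FALSE)

  thr <- stage("threshold",
               threshold_price(ctx, ctx$config$wtp_per_qaly))
  writeLines(jsonlite::toJSON(thr, auto_unbox = TRUE, digits = NA),
             file.path(outdir, "threshold.json"))

  scen <- stage("scenarios", {
    rows <- list(
      c("base", run_scenario("base", ctx)$icer_per_qaly),
      c("cure_30mo", run_scenario("cure_30mo", ctx)$icer_per_qaly),
      c("dose_400q6w", run_scenario("dose_400q6w", ctx)$icer_per_qaly),
      c("horizon_5y", run_scenario("horizon", ctx, 5)$icer_per_qaly),
      c("horizon_10y", run_scenario("horizon", ctx, 10)$icer_per_qaly),
      c("horizon_lifetime",
        run_scenario("horizon", ctx, "lifetime")$icer_per_qaly))
    data.frame(scenario = vapply(rows, `[`, character(1), 1),
               icer_per_qaly = as.numeric(vapply(rows, `[`, character(1), 2)))
  })
  utils::write.csv(scen, file.path(outdir, "scenarios.csv"), row.names = FALSE)

  psa_files <- character(0)
  if (!skip_psa) {
    ps <- stage("psa", psa(bundle$specs, ctx, n_draws = n_psa, seed = seed))
    utils::write.csv(ps$ceac, file.path(outdir, "ceac.csv"), row.names = FALSE)
    utils::write.csv(ps$draws, file.path(outdir, "psa_draws.csv"),
                     row.names = FALSE)
    psa_files <- c("ceac.csv", "psa_draws.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ceahcc")),
    config = config_path,
    config_md5 = unname(tools::md5sum(config_path)),
    seed = seed,
    n_psa = if (skip_psa) "skipped" else n_psa,
    stages = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    outputs = c("cea_table.csv", "tornado.csv", "threshold.json",
                "scenarios.csv", psa_files))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(outdir, "manifest.json"))

  if (!quiet) {
    cat("Base case vs published values:\n")
    print(transform(tab, value = round(value, 4),
                    rel_diff_pct = round(rel_diff_pct, 1)),
          row.names = FALSE)
    cat(sprintf("\nThreshold price at $%s/QALY: $%.0f per cycle (%.1f%% reduction; published: $%.0f, %.1f%%)\n",
                format(ctx$config$wtp_per_qaly, big.mark = " "),
                thr$price, thr$pct_reduction,
                published_reference()["threshold_price_per_cycle"],
                published_reference()["threshold_pct_reduction"]))
    print(scen, row.names = FALSE)
  }
  invisible(manifest)
}
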