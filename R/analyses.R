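#' Bundle a full model context
#'
#' The context holds everything needed to run the paired-arm comparison:
#' the [model_config()], the two [arm_parameters()] (with their survival
#' curves attached) and a [life_table()]. The first arm is the reference
#' strategy (placebo), the second the comparator (pembrolizumab).
#'
#' @param config a [model_config()].
#' @param arms named list of two `arm_parameters`, reference first.
#' @param life_table a [life_table()].
#' @return an object of class `cea_context`.
#' @export
cea_context <- function(config, arms, life_table = default_life_table()) {
  stopifnot(inherits(config, "model_config"), length(arms) == 2)
  for (a in arms) {
    stopifnot(inherits(a, "arm_parameters"))
    if (is.null(a$os_curve) || is.null(a$pfs_curve)) {
      stop(sprintf("arm '%s' has no survival curves attached", a$name),
           call. = FALSE)
    }
  }
  names(arms) <- vapply(arms, function(a) a$name, character(1))
  structure(list(config = config, arms = arms, life_table = life_table),
            class = "cea_context")
}

#' Run the paired-arm cost-effectiveness comparison
#'
#' Builds one cohort trace per arm from its survival curves and accrues
#' discounted costs, life-years and QALYs.
#'
#' @param context a [cea_context()].
#' @return a [compare()] result (`cea_result`).
#' @export
run_cea <- function(context) {
  stopifnot(inherits(context, "cea_context"))
  acc <- lapply(context$arms, function(arm) {
    tr <- build_trace(arm$os_curve, arm$pfs_curve, context$life_table,
                      context$config)
    accrue(tr, arm, context$config)
  })
  compare(acc[[1]], acc[[2]])
}

#' A sensitivity-analysis parameter
#'
#' Describes one tunable model input: where it lives (a dotted path, see
#' [set_param()]), its base value, its deterministic range, and the
#' distribution used for probabilistic draws. Distribution hyperparameters
#' are derived by method of moments with mean = `base` and
#' sd = (`high` - `low`) / 3.92, i.e. the range is read as a 95% interval
#' (`lognormal`: meanlog = log(base), sdlog = (log(high) - log(low))/3.92;
#' `uniform`: on \[low, high\]).
#'
#' @param name display name.
#' @param path dotted parameter path (see [set_param()]).
#' @param base,low,high base value and deterministic range
#'   (`low <= base <= high`).
#' @param distribution `"beta"`, `"gamma"`, `"lognormal"` or `"uniform"`.
#' @return an object of class `param_spec`.
#' @export
param_spec <- function(name, path, base, low, high,
                       distribution = c("uniform", "beta", "gamma", "lognormal")) {
  distribution <- match.arg(distribution)
  if (!(low <= base && base <= high)) {
    stop(sprintf("'%s': need low <= base <= high", name), call. = FALSE)
  }
  if (distribution == "beta" && (low < 0 || high > 1)) {
    stop(sprintf("'%s': beta range must lie in [0, 1]", name), call. = FALSE)
  }
  if (distribution %in% c("gamma", "lognormal") && low < 0) {
    stop(sprintf("'%s': %s range must be non-negative", name, distribution),
         call. = FALSE)
  }
  structure(list(name = name, path = path, base = base,
                 low = low, high = high, distribution = distribution),
            class = "param_spec")
}

#' Set a model parameter by dotted path
#'
#' Recognized paths:
#'
#' * `arms.<arm>.<field>` — any numeric field of [arm_parameters()];
#' * `model.<field>` — any numeric/logical field of [model_config()];
#' * `utility_pp` — postprogression utility in both arms at once;
#' * `hr_os` — overall-survival hazard ratio of the comparator versus the
#'   reference arm: the comparator's OS curve is re-derived from the
#'   reference curve under proportional hazards with shared Weibull shape;
#' * `os_median.<arm>` / `pfs_median.<arm>` — recalibrate that arm's curve
#'   to a new median, keeping its Weibull shape.
#'
#' @param context a [cea_context()].
#' @param path dotted path.
#' @param value new value.
#' @return the modified context.
#' @export
set_param <- function(context, path, value) {
  stopifnot(inherits(context, "cea_context"))
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  ref_arm <- names(context$arms)[1]
  cmp_arm <- names(context$arms)[2]
  if (path == "hr_os") {
    context$arms[[cmp_arm]]$os_curve <-
      apply_hazard_ratio(context$arms[[ref_arm]]$os_curve, value)
    return(context)
  }
  if (path == "utility_pp") {
    for (a in names(context$arms)) context$arms[[a]]$utility_pp <- value
    return(context)
  }
  if (parts[1] %in% c("os_median", "pfs_median")) {
    if (length(parts) != 2 || !parts[2] %in% names(context$arms)) {
      stop(sprintf("unknown arm in path '%s'", path), call. = FALSE)
    }
    slot <- if (parts[1] == "os_median") "os_curve" else "pfs_curve"
    old <- as_weibull(context$arms[[parts[2]]][[slot]])
    context$arms[[parts[2]]][[slot]] <-
      calibrate_weibull(value, shape = old$params$shape)
    return(context)
  }
  if (parts[1] == "arms") {
    if (length(parts) != 3 || !parts[2] %in% names(context$arms)) {
      stop(sprintf("cannot resolve path '%s'", path), call. = FALSE)
    }
    arm <- context$arms[[parts[2]]]
    if (!parts[3] %in% names(arm)) {
      stop(sprintf("unknown arm field '%s'", parts[3]), call. = FALSE)
    }
    arm[[parts[3]]] <- value
    # revalidate through the constructor
    context$arms[[parts[2]]] <- do.call(arm_parameters, unclass(arm))
    return(context)
  }
  if (parts[1] == "model") {
    if (length(parts) != 2 || !parts[2] %in% names(context$config)) {
      stop(sprintf("unknown model field in path '%s'", path), call. = FALSE)
    }
    cfg <- unclass(context$config)
    cfg[[parts[2]]] <- value
    context$config <- do.call(model_config, cfg)
    return(context)
  }
  stop(sprintf("cannot resolve parameter path '%s'", path), call. = FALSE)
}

# ICER for deterministic sweeps: capped for display when the incremental
# QALY collapses toward zero (hazard ratio -> 1 end of its range).
tornado_icer <- function(result, cap = 2e6) {
  if (is.na(result$icer_per_qaly) || result$d_qaly <= 0) return(cap)
  min(result$icer_per_qaly, cap)
}

#' One-way (tornado) sensitivity analysis
#'
#' Recomputes the ICER per QALY with each parameter at its low and at its
#' high value, all others held at base. Rows are sorted by spread
#' (|ICER_high - ICER_low|) descending. ICERs are capped at $2,000,000 per
#' QALY for display where the incremental QALY approaches zero.
#'
#' @param specs list of [param_spec()].
#' @param context a [cea_context()] at base case.
#' @return a data frame with columns `parameter`, `low`, `high`,
#'   `icer_at_low`, `icer_at_high`, `spread`.
#' @export
one_way <- function(specs, context) {
  if (inherits(specs, "param_spec")) specs <- list(specs)
  rows <- lapply(specs, function(sp) {
    at <- function(v) tornado_icer(run_cea(set_param(context, sp$path, v)))
    lo <- at(sp$low); hi <- at(sp$high)
    data.frame(parameter = sp$name, low = sp$low, high = sp$high,
               icer_at_low = lo, icer_at_high = hi,
               spread = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out[order(out$spread, decreasing = TRUE), , drop = FALSE]
}

#' Two-way sensitivity analysis
#'
#' ICER per QALY over a grid of two parameters, with each grid point
#' classified as cost-effective or not against a willingness-to-pay.
#'
#' @param spec_a,spec_b [param_spec()]s.
#' @param context a [cea_context()].
#' @param grid_n grid points per axis (>= 2).
#' @param wtp threshold for the classification; defaults to the
#'   configuration's `wtp_per_qaly`.
#' @return a data frame with `a_value`, `b_value`, `icer`,
#'   `cost_effective`.
#' @export
two_way <- function(spec_a, spec_b, context, grid_n = 11L,
                    wtp = context$config$wtp_per_qaly) {
  if (grid_n < 2) stop("grid_n must be >= 2", call. = FALSE)
  va <- seq(spec_a$low, spec_a$high, length.out = grid_n)
  vb <- seq(spec_b$low, spec_b$high, length.out = grid_n)
  grid <- expand.grid(a_value = va, b_value = vb)
  grid$icer <- mapply(function(a, b) {
    ctx <- set_param(set_param(context, spec_a$path, a), spec_b$path, b)
    tornado_icer(run_cea(ctx))
  }, grid$a_value, grid$b_value)
  grid$cost_effective <- grid$icer <= wtp
  grid
}

# One joint draw of all PSA parameters; rejection-samples any value whose
# deterministic range hints at a bounded domain the distribution ignores.
# `counter` (an environment with $n) tallies rejected draws.
draw_params <- function(specs, counter = NULL) {
  vapply(specs, function(sp) {
    sd <- (sp$high - sp$low) / 3.92
    if (sd == 0) return(sp$base)
    for (i in 1:1000) {
      v <- switch(sp$distribution,
        uniform = stats::runif(1, sp$low, sp$high),
        beta = {
          m <- sp$base
          vv <- sd^2
          a <- m * (m * (1 - m) / vv - 1)
          b <- (1 - m) * (m * (1 - m) / vv - 1)
          if (a <= 0 || b <= 0) stats::runif(1, sp$low, sp$high)
          else stats::rbeta(1, a, b)
        },
        gamma = stats::rgamma(1, shape = (sp$base / sd)^2,
                              rate = sp$base / sd^2),
        lognormal = stats::rlnorm(1, log(sp$base),
                                  (log(sp$high) - log(sp$low)) / 3.92))
      ok <- switch(sp$distribution,
                   beta = v >= 0 && v <= 1,
                   v >= 0)
      if (ok) return(v)
      if (!is.null(counter)) counter$n <- counter$n + 1L
    }
    stop(sprintf("'%s': could not draw a value inside its domain", sp$name),
         call. = FALSE)
  }, numeric(1))
}

#' Probabilistic sensitivity analysis
#'
#' Joint Monte Carlo draws of all parameters from their prespecified
#' distributions, one full model evaluation per draw, and the
#' cost-effectiveness acceptability curve CEAC(wtp) = fraction of draws
#' with positive net monetary benefit.
#'
#' @param specs list of [param_spec()] with distributions.
#' @param context a [cea_context()] at base case.
#' @param n_draws number of Monte Carlo draws (>= 1).
#' @param seed integer seed.
#' @param wtp_grid willingness-to-pay grid for the CEAC (USD/QALY).
#' @return an object of class `psa_result`: `draws` (data frame with the
#'   drawn parameter values, `d_cost`, `d_qaly`), `ceac` (data frame
#'   `wtp`, `prob_cost_effective`), and `n_rejected` (domain rejections
#'   during sampling).
#' @export
psa <- function(specs, context, n_draws = 1000L, seed = 1L,
                wtp_grid = seq(0, 5e5, by = 1e4)) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  for (sp in specs) {
    if (is.null(sp$distribution)) {
      stop(sprintf("'%s' has no distribution", sp$name), call. = FALSE)
    }
  }
  set.seed(seed)
  rejected <- new.env(); rejected$n <- 0L
  pm <- matrix(NA_real_, n_draws, length(specs))
  colnames(pm) <- vapply(specs, function(s) s$name, character(1))
  for (i in seq_len(n_draws)) pm[i, ] <- draw_params(specs, rejected)
  d_cost <- d_qaly <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    ctx <- context
    for (j in seq_along(specs)) {
      ctx <- set_param(ctx, specs[[j]]$path, pm[i, j])
    }
    res <- run_cea(ctx)
    d_cost[i] <- res$d_cost
    d_qaly[i] <- res$d_qaly
  }
  ceac <- data.frame(
    wtp = wtp_grid,
    prob_cost_effective = vapply(
      wtp_grid, function(w) mean(w * d_qaly - d_cost > 0), numeric(1)))
  structure(
    list(draws = cbind(as.data.frame(pm),
                       data.frame(d_cost = d_cost, d_qaly = d_qaly)),
         ceac = ceac, n_rejected = rejected$n, seed = seed),
    class = "psa_result")
}

#' Value-based price threshold search
#'
#' Bisects a per-cycle price until the ICER per QALY equals the target
#' willingness-to-pay to within $1/QALY. The bracket must contain the
#' solution: ICER(low price) < target < ICER(high price).
#'
#' @param context a [cea_context()].
#' @param target_wtp target ICER (USD per QALY).
#' @param price_path parameter path of the price being solved for.
#' @param bracket `c(low, high)` price bracket (USD per cycle).
#' @return a list with `price`, `icer`, `base_price`, `pct_reduction`,
#'   `iterations`.
#' @export
threshold_price <- function(context, target_wtp,
                            price_path = "arms.pembrolizumab.drug_cost_per_cycle",
                            bracket = NULL) {
  parts <- strsplit(price_path, ".", fixed = TRUE)[[1]]
  base_price <- context$arms[[parts[2]]][[parts[3]]]
  if (is.null(bracket)) bracket <- c(0, base_price)
  icer_at <- function(p) {
    res <- run_cea(set_param(context, price_path, p))
    if (is.na(res$icer_per_qaly)) {
      if (res$d_qaly <= 0) stop(
        "incremental QALYs are not positive; no price threshold exists",
        call. = FALSE)
      # cheaper and more effective: treat as ICER below any positive target
      res$d_cost / res$d_qaly
    } else {
      res$icer_per_qaly
    }
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- icer_at(lo) - target_wtp
  f_hi <- icer_at(hi) - target_wtp
  tol <- 1e-3  # dollars per QALY; well inside the $1 guarantee
  if (abs(f_lo) < tol || abs(f_hi) < tol) {
    mid <- if (abs(f_lo) < tol) lo else hi
    f <- if (abs(f_lo) < tol) f_lo else f_hi
    return(list(price = mid, icer = f + target_wtp, base_price = base_price,
                pct_reduction = 100 * (base_price - mid) / base_price,
                iterations = 0L))
  }
  if (f_lo > 0 || f_hi < 0) {
    stop(sprintf(
      "bracket [%g, %g] does not straddle the target: ICER(low) = %.0f, ICER(high) = %.0f, target = %.0f",
      lo, hi, f_lo + target_wtp, f_hi + target_wtp, target_wtp),
      call. = FALSE)
  }
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    f <- icer_at(mid) - target_wtp
    if (abs(f) < tol || it >= 200L) break
    if (f > 0) hi <- mid else lo <- mid
  }
  list(price = mid, icer = f + target_wtp, base_price = base_price,
       pct_reduction = 100 * (base_price - mid) / base_price,
       iterations = it)
}

#' Scenario analyses
#'
#' Named structural scenarios over a base context:
#'
#' * `"base"` — the context unchanged;
#' * `"cure_30mo"` — patients alive after 30 months (both arms) face only
#'   background mortality thereafter;
#' * `"dose_400q6w"` — 400 mg every 6 weeks: equal drug cost per unit
#'   time, administration events halved; clinical curves unchanged;
#' * `"horizon"` — the time horizon overridden to `years`; `years =
#'   "lifetime"` runs to age 100.
#'
#' @param name scenario name.
#' @param context a [cea_context()].
#' @param years horizon override (numeric years or `"lifetime"`), only for
#'   `name = "horizon"`.
#' @return a `cea_result`.
#' @export
run_scenario <- function(name = c("base", "cure_30mo", "dose_400q6w", "horizon"),
                         context, years = NULL) {
  name <- match.arg(name)
  ctx <- context
  if (name == "cure_30mo") {
    ctx <- set_param(ctx, "model.cure_scenario", TRUE)
    ctx <- set_param(ctx, "model.cure_time_months", 30)
  } else if (name == "dose_400q6w") {
    ctx$config$dose_schedule <- "q6w"
  } else if (name == "horizon") {
    if (is.null(years)) stop("horizon scenario needs 'years'", call. = FALSE)
    if (identical(years, "lifetime")) {
      years <- 100 - ctx$config$start_age_years
    }
    ctx <- set_param(ctx, "model.horizon_years", years)
  }
  run_cea(ctx)
}

#' Subgroup analysis through an overall-survival hazard ratio
#'
#' Holds the reference (placebo) OS curve fixed and re-derives the
#' comparator's OS curve from it under proportional hazards with the
#' shared Weibull shape, then reruns the full comparison.
#'
#' @param hr_os subgroup hazard ratio (> 0).
#' @param context a [cea_context()].
#' @return a `cea_result`.
#' @export
subgroup <- function(hr_os, context) {
  if (hr_os <= 0) stop("hr_os must be > 0", call. = FALSE)
  run_cea(set_param(context, "hr_os", hr_os))
}

#' Default deterministic/probabilistic sensitivity parameter set
#'
#' The printed one-way ranges (OS hazard ratio 0.78 \[0.61, 1.00\],
#' placebo progression-free utility 0.76 \[0.59, 0.93\], pembrolizumab
#' price $6915 \[$5531, $8297\], postprogression therapy prices $6620
#' \[$5596, $7944\] and $5963 \[$4770, $7156\]) plus +/-20% ranges for the
#' remaining utilities, the administration cost and the postprogression
#' treated fractions. Distributions follow standard practice: beta for
#' utilities and fractions, gamma for costs, lognormal for the hazard
#' ratio.
#'
#' @return a list of [param_spec()].
#' @export
default_parameter_specs <- function() {
  pm20 <- function(x, cap1 = FALSE) {
    hi <- if (cap1) min(1, 1.2 * x) else 1.2 * x
    c(0.8 * x, hi)
  }
  list(
    param_spec("OS hazard ratio (pembrolizumab vs placebo)", "hr_os",
               0.78, 0.61, 1.00, "lognormal"),
    param_spec("Utility, progression-free (placebo)",
               "arms.placebo.utility_pf", 0.76, 0.59, 0.93, "beta"),
    param_spec("Utility, progression-free (pembrolizumab)",
               "arms.pembrolizumab.utility_pf", 0.84,
               pm20(0.84, TRUE)[1], pm20(0.84, TRUE)[2], "beta"),
    param_spec("Utility, postprogression", "utility_pp", 0.68,
               pm20(0.68, TRUE)[1], pm20(0.68, TRUE)[2], "beta"),
    param_spec("Pembrolizumab price per cycle",
               "arms.pembrolizumab.drug_cost_per_cycle",
               6915, 5531, 8297, "gamma"),
    param_spec("Postprogression therapy price (pembrolizumab arm)",
               "arms.pembrolizumab.postprog_cost_per_cycle",
               6620, 5596, 7944, "gamma"),
    param_spec("Postprogression therapy price (placebo arm)",
               "arms.placebo.postprog_cost_per_cycle",
               5963, 4770, 7156, "gamma"),
    param_spec("Administration cost per cycle",
               "arms.pembrolizumab.admin_cost_per_cycle", 150,
               pm20(150)[1], pm20(150)[2], "gamma"),
    param_spec("Postprogression treated fraction (pembrolizumab arm)",
               "arms.pembrolizumab.postprog_treated_fraction", 0.417,
               pm20(0.417, TRUE)[1], pm20(0.417, TRUE)[2], "beta"),
    param_spec("Postprogression treated fraction (placebo arm)",
               "arms.placebo.postprog_treated_fraction", 0.474,
               pm20(0.474, TRUE)[1], pm20(0.474, TRUE)[2], "beta"))
}
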