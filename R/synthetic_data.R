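#' Specification of a synthetic two-endpoint trial arm simulation
#'
#' Ground-truth survival laws per arm for overall survival (OS) and
#' progression-free survival (PFS), plus the trial logistics needed to
#' emulate administrative censoring. Defaults emulate a KEYNOTE-240-like
#' second-line hepatocellular carcinoma trial: Weibull OS with medians
#' 13.9 / 10.6 months (shape 0.901, i.e. mildly decreasing hazard, implied
#' hazard ratio about 0.78), short Weibull PFS (medians 3.0 / 2.8 months,
#' shape 1.2), uniform accrual over 18 months and a 30-month data cutoff.
#'
#' @param os_family,pfs_family family name per arm (named character vectors
#'   or single names recycled across arms).
#' @param os_params,pfs_params named list per arm of family parameters.
#' @param n_per_arm patients per arm (>= 1).
#' @param accrual_months uniform accrual window (months, >= 0).
#' @param cutoff_months administrative censoring time (months, > 0). A
#'   patient accrued at time a in \[0, min(accrual, cutoff)\] is followed
#'   for `cutoff_months - a`, so `cutoff_months` is the maximum follow-up.
#' @param seed integer random seed.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(os_family = "weibull",
                            os_params = list(
                              pembrolizumab = list(shape = 0.901, scale = 20.877),
                              placebo = list(shape = 0.901, scale = 15.921)),
                            pfs_family = "weibull",
                            pfs_params = list(
                              pembrolizumab = list(shape = 1.2, scale = 4.072),
                              placebo = list(shape = 1.2, scale = 3.800)),
                            n_per_arm = 200L,
                            accrual_months = 18,
                            cutoff_months = 30,
                            seed = 1L) {
  arms <- names(os_params)
  if (is.null(arms) || !identical(arms, names(pfs_params))) {
    stop("os_params and pfs_params must be named lists with identical arm names",
         call. = FALSE)
  }
  if (n_per_arm < 1) stop("n_per_arm must be >= 1", call. = FALSE)
  if (cutoff_months <= 0) stop("cutoff_months must be > 0", call. = FALSE)
  if (accrual_months < 0) stop("accrual_months must be >= 0", call. = FALSE)
  os_family <- rep_len(os_family, length(arms))
  pfs_family <- rep_len(pfs_family, length(arms))
  for (f in c(os_family, pfs_family)) {
    if (!f %in% surv_families()) {
      stop(sprintf("unknown survival family '%s'", f), call. = FALSE)
    }
  }
  structure(
    list(arms = arms,
         os_family = stats::setNames(os_family, arms),
         os_params = os_params,
         pfs_family = stats::setNames(pfs_family, arms),
         pfs_params = pfs_params,
         n_per_arm = as.integer(n_per_arm),
         accrual_months = accrual_months,
         cutoff_months = cutoff_months,
         seed = as.integer(seed)),
    class = "simulation_spec")
}

# Inverse survival function: the time t with S(t) = u, in the package's
# parameterization.
qsurv <- function(u, family, params) {
  family <- match.arg(family, surv_families())
  p <- as.list(params)
  switch(family,
    exponential = -log(u) / p$rate,
    weibull     = p$scale * (-log(u))^(1 / p$shape),
    loglogistic = p$scale * ((1 - u) / u)^(1 / p$shape),
    lognormal   = stats::qlnorm(u, p$meanlog, p$sdlog, lower.tail = FALSE))
}

# One arm's latent event times and censoring times. Progression-free and
# overall survival are coupled comonotonically: a single uniform rank per
# patient is pushed through both inverse survival functions, which
# preserves both marginal laws exactly and guarantees T_prog <= T_death
# per patient whenever S_pfs(t) <= S_os(t) for all t (as in every
# configuration shipped here); a max() guard enforces the ordering in any
# remaining crossings.
simulate_arm_latent <- function(spec, arm) {
  i <- match(arm, spec$arms)
  if (is.na(i)) {
    stop(sprintf("unknown arm '%s' (have: %s)", arm,
                 paste(spec$arms, collapse = ", ")), call. = FALSE)
  }
  # deterministic per-arm substream
  set.seed(spec$seed + 7919L * (i - 1L))
  n <- spec$n_per_arm
  u <- stats::runif(n)
  t_os <- qsurv(u, spec$os_family[[arm]], spec$os_params[[arm]])
  t_pfs <- qsurv(u, spec$pfs_family[[arm]], spec$pfs_params[[arm]])
  t_os <- pmax(t_os, t_pfs)
  accrual <- stats::runif(n, 0, min(spec$accrual_months, spec$cutoff_months))
  follow_up <- pmax(spec$cutoff_months - accrual, .Machine$double.eps)
  list(t_os = t_os, t_pfs = t_pfs, follow_up = follow_up)
}

#' Simulate pseudo individual-patient data from known ground truth
#'
#' Draws per-patient OS and PFS times from the spec's survival laws
#' (coupled so that PFS <= OS for every patient), applies administrative
#' censoring from the accrual/cutoff structure, and returns the requested
#' endpoint as `(time, event)` records. Identical spec (including seed)
#' gives identical output.
#'
#' @param spec a [simulation_spec()].
#' @param endpoint `"OS"` or `"PFS"`.
#' @param arm arm name present in the spec.
#' @return a [pseudo_ipd()].
#' @export
simulate_ipd <- function(spec, endpoint = c("OS", "PFS"), arm) {
  stopifnot(inherits(spec, "simulation_spec"))
  endpoint <- match.arg(endpoint)
  lat <- simulate_arm_latent(spec, arm)
  t_event <- if (endpoint == "OS") lat$t_os else lat$t_pfs
  event <- as.integer(t_event <= lat$follow_up)
  time <- pmin(t_event, lat$follow_up)
  pseudo_ipd(time, event, arm = arm, endpoint = endpoint)
}

#' Emulate graph digitization of a Kaplan-Meier curve
#'
#' Computes the KM estimate of the input records, samples it on a regular
#' time grid, optionally adds Gaussian digitization jitter (clipped to
#' \[0, 1\]) and repairs monotonicity with a non-increasing
#' pool-adjacent-violators pass. `jitter_sd = 0` reproduces the exact KM
#' step values on the grid.
#'
#' @param ipd a [pseudo_ipd()].
#' @param grid_step_months grid spacing (months, > 0).
#' @param jitter_sd standard deviation of the jitter (>= 0).
#' @param seed seed for the jitter.
#' @param horizon_months last grid time; defaults to the largest record time.
#' @return a [digitized_curve()].
#' @export
digitize_curve <- function(ipd, grid_step_months = 1, jitter_sd = 0,
                           seed = 1L, horizon_months = NULL) {
  ipd <- as_pseudo_ipd(ipd)
  if (grid_step_months <= 0) stop("grid_step_months must be > 0", call. = FALSE)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  if (is.null(horizon_months)) horizon_months <- max(ipd$time_months)
  grid <- seq(0, horizon_months, by = grid_step_months)
  km <- km_estimate(ipd)
  s <- km_step_at(km, grid)
  if (jitter_sd > 0) {
    set.seed(seed)
    s <- s + stats::rnorm(length(s), 0, jitter_sd)
    s <- pmin(pmax(s, 0), 1)
    s[1] <- max(s[1], s[-1])  # anchor: survival starts at its maximum
    s <- pava_nonincreasing(s)
  }
  digitized_curve(grid, s)
}

# Right-continuous step-function lookup on a KM curve (curve includes t=0).
km_step_at <- function(curve, t) {
  idx <- findInterval(t, curve$time_months)
  idx[idx < 1] <- 1
  curve$survival[idx]
}

# Non-increasing isotonic regression (pool adjacent violators),
# least-squares, equal weights.
pava_nonincreasing <- function(y) {
  -stats::isoreg(seq_along(y), -y)$yf
}

#' Number-at-risk table from patient-level records
#'
#' Counts patients still at risk (record time >= interval start) at each
#' multiple of `interval_months`, emulating the risk row printed under a
#' published KM figure.
#'
#' @param ipd a [pseudo_ipd()].
#' @param interval_months interval between entries (months, > 0).
#' @param horizon_months last entry time; defaults to the largest record time.
#' @return a [risk_table()].
#' @export
make_risk_table <- function(ipd, interval_months, horizon_months = NULL) {
  ipd <- as_pseudo_ipd(ipd)
  if (interval_months <= 0) stop("interval_months must be > 0", call. = FALSE)
  if (is.null(horizon_months)) horizon_months <- max(ipd$time_months)
  times <- seq(0, horizon_months, by = interval_months)
  n_risk <- vapply(times, function(t) sum(ipd$time_months >= t), integer(1))
  risk_table(times, n_risk)
}

#' Synthetic US-like life table
#'
#' Ages 60-100 with annual death probabilities rising geometrically from
#' 0.011 to 0.3 — an approximate all-cause average for a US adult cohort.
#' A stand-in constructed for this package (no deposited table is bundled);
#' background mortality is a second-order effect at the model's horizon.
#'
#' @return a [life_table()].
#' @export
default_life_table <- function() {
  ages <- 60:100
  q <- 0.011 * (0.3 / 0.011)^((ages - 60) / 40)
  life_table(ages, q)
}
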