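#' Parametric survival curves
#'
#' A `param_surv` object is a fitted or directly calibrated survival law:
#' a distribution family plus its parameters, evaluable at any time.
#' Supported families and parameterizations (time in months throughout):
#'
#' * `exponential`: `rate` r, with S(t) = exp(-r t)
#' * `weibull`: `shape` k, `scale` s, with S(t) = exp(-(t/s)^k)
#' * `loglogistic`: `shape` k, `scale` s, with S(t) = 1 / (1 + (t/s)^k)
#' * `lognormal`: `meanlog`, `sdlog`, with S(t) = 1 - Phi((log t - meanlog)/sdlog)
#'
#' @param family one of `"exponential"`, `"weibull"`, `"loglogistic"`,
#'   `"lognormal"`.
#' @param params named list/vector of family parameters (see above).
#' @param loglik maximized log-likelihood, if the curve was fitted; `NA`
#'   for calibrated curves.
#' @param n number of records the curve was fitted to (`NA` if calibrated).
#' @return an object of class `param_surv`.
#' @export
param_surv <- function(family, params, loglik = NA_real_, n = NA_integer_) {
  family <- match.arg(family, surv_families())
  params <- as.list(params)
  need <- surv_param_names(family)
  if (!all(need %in% names(params))) {
    stop(sprintf("family '%s' needs parameters: %s", family,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  params <- params[need]
  pos <- setdiff(need, "meanlog")  # meanlog may be any real
  bad <- vapply(params[pos], function(p) !is.finite(p) || p <= 0, logical(1))
  if (any(bad)) {
    stop(sprintf("parameters must be positive finite: %s",
                 paste(pos[bad], collapse = ", ")), call. = FALSE)
  }
  structure(
    list(family = family, params = params, loglik = loglik,
         n_params = length(need), n = n),
    class = "param_surv"
  )
}

surv_families <- function() c("exponential", "weibull", "loglogistic", "lognormal")

surv_param_names <- function(family) {
  switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    loglogistic = c("shape", "scale"),
    lognormal   = c("meanlog", "sdlog"))
}

#' @export
print.param_surv <- function(x, ...) {
  pars <- paste(sprintf("%s = %.5g", names(x$params), unlist(x$params)),
                collapse = ", ")
  cat(sprintf("<param_surv> %s(%s)\n", x$family, pars))
  if (is.finite(x$loglik)) {
    cat(sprintf("  loglik = %.3f, AIC = %.3f (n = %s)\n",
                x$loglik, surv_aic(x), x$n))
  }
  invisible(x)
}

#' Evaluate a survival curve
#'
#' @param curve a [param_surv()] object.
#' @param t_months vector of non-negative times (months).
#' @return survival probabilities S(t) in \[0, 1\]; S(0) = 1.
#' @export
surv_prob <- function(curve, t_months) {
  stopifnot(inherits(curve, "param_surv"))
  if (any(t_months < 0)) stop("t_months must be >= 0", call. = FALSE)
  p <- curve$params
  s <- switch(curve$family,
    exponential = exp(-p$rate * t_months),
    weibull     = exp(-(t_months / p$scale)^p$shape),
    loglogistic = 1 / (1 + (t_months / p$scale)^p$shape),
    lognormal   = stats::plnorm(t_months, p$meanlog, p$sdlog,
                                lower.tail = FALSE))
  s[t_months == 0] <- 1
  pmin(pmax(s, 0), 1)
}

surv_aic <- function(curve) 2 * curve$n_params - 2 * curve$loglik

flexsurv_dist <- function(family) {
  switch(family, exponential = "exp", weibull = "weibull",
         loglogistic = "llogis", lognormal = "lnorm")
}

#' Fit a parametric survival family to (pseudo-)IPD by maximum likelihood
#'
#' Right-censored maximum likelihood via [flexsurv::flexsurvreg()]. The
#' fitted parameters are mapped into the package's parameterization
#' (see [param_surv()]).
#'
#' @param ipd a [pseudo_ipd()] data frame with columns `time_months`, `event`.
#' @param family family name (see [param_surv()]).
#' @return a `param_surv` with `loglik` and `n` filled in.
#' @export
fit_param_surv <- function(ipd, family) {
  family <- match.arg(family, surv_families())
  ipd <- as_pseudo_ipd(ipd)
  if (sum(ipd$event) < 2) {
    stop(sprintf("fitting '%s' requires at least 2 events (got %d)",
                 family, sum(ipd$event)), call. = FALSE)
  }
  fit <- tryCatch(
    flexsurv::flexsurvreg(
      survival::Surv(time_months, event) ~ 1,
      data = ipd, dist = flexsurv_dist(family)),
    error = function(e) {
      stop(sprintf(
        "fit of family '%s' failed (n = %d, events = %d): %s",
        family, nrow(ipd), sum(ipd$event), conditionMessage(e)),
        call. = FALSE)
    })
  est <- fit$res[, "est"]
  names(est) <- rownames(fit$res)
  params <- switch(family,
    exponential = list(rate = unname(est["rate"])),
    weibull     = list(shape = unname(est["shape"]), scale = unname(est["scale"])),
    loglogistic = list(shape = unname(est["shape"]), scale = unname(est["scale"])),
    lognormal   = list(meanlog = unname(est["meanlog"]), sdlog = unname(est["sdlog"])))
  param_surv(family, params, loglik = fit$loglik, n = nrow(ipd))
}

#' Select the best-fitting curve by Akaike information criterion
#'
#' AIC = 2 k - 2 logL. Ties (within `tol`) are broken by fewer parameters,
#' then by family order exponential < weibull < loglogistic < lognormal.
#'
#' @param fits list of fitted [param_surv()] objects (with log-likelihoods).
#' @param tol AIC difference treated as a tie.
#' @return the selected `param_surv`.
#' @export
aic_select <- function(fits, tol = 1e-9) {
  if (inherits(fits, "param_surv")) fits <- list(fits)
  ok <- vapply(fits, function(f) is.finite(f$loglik), logical(1))
  if (!any(ok)) stop("no candidate has a log-likelihood", call. = FALSE)
  fits <- fits[ok]
  aics <- vapply(fits, surv_aic, numeric(1))
  npar <- vapply(fits, function(f) f$n_params, numeric(1))
  fam <- match(vapply(fits, function(f) f$family, character(1)), surv_families())
  # among AIC ties, prefer fewer parameters, then declared family order
  best <- which(aics <= min(aics) + tol)
  best <- best[order(npar[best], fam[best])]
  fits[[best[1]]]
}

#' Calibrate a Weibull survival curve from printed summary statistics
#'
#' Three modes, mirroring how published trial summaries are usually the only
#' available inputs:
#'
#' * `median + landmark`: solve S(median) = 0.5 and S(t_L) = s_L for
#'   (shape, scale). Closed form:
#'   shape = log(log(s_L)/log(0.5)) / log(t_L/median).
#' * `median + hazard_ratio + reference`: proportional hazards within a
#'   shared Weibull shape; the new scale is `scale_ref * hr^(-1/shape)`
#'   (the `median_months` argument is ignored and may be `NULL`).
#' * `median` only: exponential (shape 1), scale = median / log(2).
#'
#' @param median_months printed median survival (months).
#' @param landmark optional `c(time_months, survival)` landmark constraint.
#' @param hazard_ratio optional hazard ratio versus `reference`.
#' @param reference optional reference `param_surv` (weibull or exponential)
#'   whose shape is shared.
#' @param shape optional: directly impose a Weibull shape together with
#'   `median_months` (used for, e.g., progression-free survival defaults).
#' @return a calibrated `param_surv` of family `weibull`.
#' @export
calibrate_weibull <- function(median_months = NULL, landmark = NULL,
                              hazard_ratio = NULL, reference = NULL,
                              shape = NULL) {
  modes <- c(!is.null(landmark), !is.null(hazard_ratio), !is.null(shape))
  if (sum(modes) > 1) {
    stop("supply at most one of landmark, hazard_ratio(+reference), shape",
         call. = FALSE)
  }
  if (!is.null(hazard_ratio)) {
    if (is.null(reference)) stop("hazard_ratio needs a reference curve", call. = FALSE)
    ref <- as_weibull(reference)
    k <- ref$params$shape
    return(param_surv("weibull",
                      list(shape = k,
                           scale = ref$params$scale * hazard_ratio^(-1 / k))))
  }
  if (is.null(median_months) || median_months <= 0) {
    stop("median_months must be a positive number", call. = FALSE)
  }
  if (!is.null(landmark)) {
    t_l <- landmark[[1]]; s_l <- landmark[[2]]
    if (t_l <= 0 || s_l <= 0 || s_l >= 1) {
      stop("landmark must be (time > 0, survival in (0,1))", call. = FALSE)
    }
    if ((t_l > median_months && s_l >= 0.5) ||
        (t_l < median_months && s_l <= 0.5)) {
      stop(sprintf(
        "landmark S(%g) = %g is inconsistent with median %g months",
        t_l, s_l, median_months), call. = FALSE)
    }
    k <- log(log(s_l) / log(0.5)) / log(t_l / median_months)
  } else if (!is.null(shape)) {
    k <- shape
  } else {
    k <- 1
  }
  param_surv("weibull",
             list(shape = k, scale = median_months / log(2)^(1 / k)))
}

# View an exponential as a Weibull(shape 1); pass Weibulls through.
as_weibull <- function(curve) {
  stopifnot(inherits(curve, "param_surv"))
  if (curve$family == "weibull") return(curve)
  if (curve$family == "exponential") {
    return(param_surv("weibull",
                      list(shape = 1, scale = 1 / curve$params$rate)))
  }
  stop(sprintf("cannot treat family '%s' as a Weibull", curve$family),
       call. = FALSE)
}

#' Rescale a Weibull/exponential curve by a hazard ratio
#'
#' Proportional hazards within the curve's own shape: the scale becomes
#' `scale * hr^(-1/shape)`, so `hr < 1` lengthens survival.
#'
#' @param curve a weibull or exponential `param_surv`.
#' @param hr positive hazard ratio (new vs old).
#' @return a `param_surv` of family `weibull`.
#' @export
apply_hazard_ratio <- function(curve, hr) {
  if (!is.numeric(hr) || hr <= 0) stop("hr must be positive", call. = FALSE)
  w <- as_weibull(curve)
  param_surv("weibull",
             list(shape = w$params$shape,
                  scale = w$params$scale * hr^(-1 / w$params$shape)))
}

#' Weibull median survival time
#' @param curve a weibull or exponential `param_surv`.
#' @return median survival in months.
#' @export
median_survival <- function(curve) {
  w <- as_weibull(curve)
  w$params$scale * log(2)^(1 / w$params$shape)
}

#' Restricted mean survival time by quadrature
#'
#' Area under S(t) (optionally discounted continuously at an annual rate)
#' from 0 to the horizon. Used mostly as an independent check on the
#' cohort-trace life-year accruals.
#'
#' @param curve a `param_surv`.
#' @param horizon_months upper limit of integration (months).
#' @param discount_rate_annual annual discount rate (default 0: plain RMST).
#' @return restricted mean survival in months.
#' @export
rmst <- function(curve, horizon_months, discount_rate_annual = 0) {
  f <- function(t) surv_prob(curve, t) * (1 + discount_rate_annual)^(-t / 12)
  stats::integrate(f, 0, horizon_months, rel.tol = 1e-9,
                   subdivisions = 500L)$value
}

#' Serialize a fitted curve to JSON
#' @param curve a `param_surv`.
#' @param path optional file; if `NULL` the JSON string is returned.
#' @export
write_param_surv <- function(curve, path = NULL) {
  x <- list(family = curve$family, params = curve$params,
            loglik = curve$loglik, n = curve$n,
            aic = if (is.finite(curve$loglik)) surv_aic(curve) else NA_real_)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a serialized curve
#' @param path JSON file written by [write_param_surv()].
#' @export
read_param_surv <- function(path) {
  x <- jsonlite::fromJSON(path)
  param_surv(x$family, x$params,
             loglik = if (is.null(x$loglik)) NA_real_ else x$loglik,
             n = if (is.null(x$n)) NA_integer_ else x$n)
}
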