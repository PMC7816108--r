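#' Economic and clinical inputs for one strategy
#'
#' All per-arm parameters of the cost-effectiveness comparison. Cost
#' defaults are 2020 USD; no inflation adjustment is performed internally.
#' The base case assigns the pembrolizumab arm a drug cost of $6915 per
#' 3-week cycle plus $150 administration, progression-free utility 0.84
#' (0.76 for placebo), postprogression utility 0.68 in both arms, and
#' postprogression anticancer therapy to 41.7% (pembrolizumab) / 47.4%
#' (placebo) of progressing patients at $6620 / $5963 per cycle for 6
#' cycles. The adverse-event profile is a list of
#' `list(probability =, cost =, utility_decrement =)` entries applied once
#' per patient at model start; end-of-life cost is applied once per death.
#'
#' @param name arm label.
#' @param drug_cost_per_cycle USD per cycle while on treatment.
#' @param admin_cost_per_cycle USD per administration while on treatment.
#' @param utility_pf,utility_pp health-state utilities in \[0, 1\].
#' @param ae_profile list of adverse-event entries (may be empty).
#' @param postprog_treated_fraction fraction of progressing patients who
#'   receive postprogression anticancer therapy.
#' @param postprog_cost_per_cycle USD per cycle of postprogression therapy.
#' @param postprog_duration_cycles fixed duration of postprogression
#'   therapy (cycles).
#' @param eol_cost one-time end-of-life cost per death (USD).
#' @param os_curve,pfs_curve [param_surv()] survival laws for the arm.
#' @return an object of class `arm_parameters`.
#' @export
arm_parameters <- function(name,
                           drug_cost_per_cycle,
                           admin_cost_per_cycle = 150,
                           utility_pf,
                           utility_pp = 0.68,
                           ae_profile = list(),
                           postprog_treated_fraction,
                           postprog_cost_per_cycle,
                           postprog_duration_cycles = 6L,
                           eol_cost = 0,
                           os_curve = NULL,
                           pfs_curve = NULL) {
  costs <- c(drug_cost_per_cycle, admin_cost_per_cycle,
             postprog_cost_per_cycle, eol_cost)
  if (any(costs < 0)) stop("costs must be >= 0", call. = FALSE)
  utils_ <- c(utility_pf, utility_pp)
  if (any(utils_ < 0 | utils_ > 1)) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  if (postprog_treated_fraction < 0 || postprog_treated_fraction > 1) {
    stop("postprog_treated_fraction must lie in [0, 1]", call. = FALSE)
  }
  for (ae in ae_profile) {
    if (is.null(ae$probability) || ae$probability < 0 || ae$probability > 1 ||
        is.null(ae$cost) || ae$cost < 0 ||
        is.null(ae$utility_decrement) || ae$utility_decrement < 0) {
      stop("each ae_profile entry needs probability in [0,1], cost >= 0, utility_decrement >= 0",
           call. = FALSE)
    }
  }
  structure(
    list(name = name,
         drug_cost_per_cycle = drug_cost_per_cycle,
         admin_cost_per_cycle = admin_cost_per_cycle,
         utility_pf = utility_pf,
         utility_pp = utility_pp,
         ae_profile = ae_profile,
         postprog_treated_fraction = postprog_treated_fraction,
         postprog_cost_per_cycle = postprog_cost_per_cycle,
         postprog_duration_cycles = as.integer(postprog_duration_cycles),
         eol_cost = eol_cost,
         os_curve = os_curve,
         pfs_curve = pfs_curve),
    class = "arm_parameters")
}

#' Accrue discounted costs, life-years and QALYs over a cohort trace
#'
#' Costs: drug + administration while on treatment (under the `"q6w"`
#' schedule, drug at twice the price every second cycle and administration
#' every second cycle); postprogression therapy applied per newly
#' progressing patient as treated fraction x per-cycle cost x a
#' fixed-duration annuity discounted from the progression cycle; one-time
#' end-of-life cost per new death; one-time adverse-event costs at model
#' start. QALYs: half-cycle-corrected state occupancies weighted by the
#' state utilities, minus one-time adverse-event decrements.
#'
#' @param trace a [build_trace()] result.
#' @param arm an [arm_parameters()].
#' @param config the [model_config()] the trace was built from.
#' @return a list with `total_cost`, `life_years`, `qalys` (all
#'   discounted) and the arm `name`.
#' @export
accrue <- function(trace, arm, config = trace_config(trace)) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(arm, "arm_parameters"))
  tcfg <- trace_config(trace)
  if (!isTRUE(all.equal(tcfg[c("cycle_days", "horizon_years")],
                        config[c("cycle_days", "horizon_years")]))) {
    stop("trace and config disagree on cycle/horizon structure", call. = FALSE)
  }
  n <- nrow(trace) - 1L
  cyc <- cycle_length_months(config)
  r <- config$discount_rate_annual
  disc <- trace$discount[seq_len(n)]
  t0 <- trace$time_months[seq_len(n)]
  dt_years <- diff(trace$time_months) / 12
  on_tx <- trace$on_treatment[seq_len(n)]
  new_prog <- trace$new_prog[seq_len(n)]
  new_dead <- trace$new_dead[seq_len(n)]

  # treatment costs per cycle actually administered
  if (config$dose_schedule == "q6w") {
    dosing <- (trace$cycle[seq_len(n)] %% 2L) == 0L
    tx_cost <- ifelse(dosing,
                      2 * arm$drug_cost_per_cycle + arm$admin_cost_per_cycle, 0)
  } else {
    tx_cost <- rep(arm$drug_cost_per_cycle + arm$admin_cost_per_cycle, n)
  }
  cost_tx <- sum(disc * on_tx * tx_cost)

  # postprogression therapy: fixed-duration annuity from the progression cycle
  dur <- arm$postprog_duration_cycles
  annuity <- if (dur > 0) {
    vapply(t0, function(t) sum((1 + r)^(-(t + (0:(dur - 1)) * cyc) / 12)),
           numeric(1))
  } else {
    rep(0, n)
  }
  cost_pp <- sum(new_prog * arm$postprog_treated_fraction *
                   arm$postprog_cost_per_cycle * annuity)

  cost_eol <- sum(new_dead * arm$eol_cost * disc)

  ae_cost <- sum(vapply(arm$ae_profile,
                        function(ae) ae$probability * ae$cost, numeric(1)))
  ae_dec <- sum(vapply(arm$ae_profile,
                       function(ae) ae$probability * ae$utility_decrement,
                       numeric(1)))

  util <- trace$pf * arm$utility_pf + trace$pp * arm$utility_pp
  alive <- trace$pf + trace$pp
  if (config$half_cycle_correction) {
    u_occ <- (util[-(n + 1L)] + util[-1]) / 2
    a_occ <- (alive[-(n + 1L)] + alive[-1]) / 2
  } else {
    u_occ <- util[seq_len(n)]
    a_occ <- alive[seq_len(n)]
  }
  qalys <- sum(u_occ * dt_years * disc) - ae_dec
  ly <- sum(a_occ * dt_years * disc)

  list(name = arm$name,
       total_cost = cost_tx + cost_pp + cost_eol + ae_cost,
       life_years = ly,
       qalys = qalys)
}

#' Pairwise cost-effectiveness comparison
#'
#' Incremental cost, life-years and QALYs of `b` versus `a`, with
#' incremental cost-effectiveness ratios when they are well-defined
#' (positive incremental effect and cost) and a dominance classification
#' otherwise: `"b dominant"` (cheaper and more effective),
#' `"b dominated"` (costlier and less or equally effective),
#' `"equivalent"`, or `"cost saving"` (cheaper but also less effective —
#' the ICER then measures savings per QALY forgone and is reported).
#'
#' @param a,b [accrue()] results; `a` is the reference strategy.
#' @return an object of class `cea_result`.
#' @export
compare <- function(a, b) {
  d_cost <- b$total_cost - a$total_cost
  d_ly <- b$life_years - a$life_years
  d_qaly <- b$qalys - a$qalys
  eps <- 1e-12
  dominance <- NA_character_
  icer_ly <- icer_qaly <- NA_real_
  if (abs(d_cost) < 1e-6 && abs(d_qaly) < eps) {
    dominance <- "equivalent"
  } else if (d_qaly > eps && d_cost <= 0) {
    dominance <- "b dominant"
  } else if (d_qaly <= eps && d_cost >= 0) {
    dominance <- "b dominated"
  } else if (d_qaly > eps && d_cost > 0) {
    icer_qaly <- d_cost / d_qaly
    if (d_ly > eps) icer_ly <- d_cost / d_ly
  } else {
    dominance <- "cost saving"
    icer_qaly <- d_cost / d_qaly
    if (abs(d_ly) > eps) icer_ly <- d_cost / d_ly
  }
  structure(
    list(reference = a, comparator = b,
         d_cost = d_cost, d_ly = d_ly, d_qaly = d_qaly,
         icer_per_ly = icer_ly, icer_per_qaly = icer_qaly,
         dominance = dominance),
    class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  fmt <- function(v, d = 3) formatC(v, format = "f", digits = d, big.mark = " ")
  cat(sprintf("%-28s %14s %14s\n", "", x$reference$name, x$comparator$name))
  cat(sprintf("%-28s %14s %14s\n", "Total cost, $",
              fmt(x$reference$total_cost, 0), fmt(x$comparator$total_cost, 0)))
  cat(sprintf("%-28s %14s %14s\n", "Incremental total cost, $", "",
              fmt(x$d_cost, 0)))
  cat(sprintf("%-28s %14s %14s\n", "QALYs",
              fmt(x$reference$qalys), fmt(x$comparator$qalys)))
  cat(sprintf("%-28s %14s %14s\n", "QALY gain", "", fmt(x$d_qaly)))
  cat(sprintf("%-28s %14s %14s\n", "Life-years",
              fmt(x$reference$life_years), fmt(x$comparator$life_years)))
  cat(sprintf("%-28s %14s %14s\n", "Incremental life-years", "", fmt(x$d_ly)))
  if (!is.na(x$icer_per_ly)) {
    cat(sprintf("%-28s %14s %14s\n", "ICER per life-year, $", "NA",
                fmt(x$icer_per_ly, 0)))
  }
  if (!is.na(x$icer_per_qaly)) {
    cat(sprintf("%-28s %14s %14s\n", "ICER per QALY, $", "NA",
                fmt(x$icer_per_qaly, 0)))
  }
  if (!is.na(x$dominance)) cat("Classification:", x$dominance, "\n")
  invisible(x)
}

#' Net monetary benefit of the comparator at a willingness-to-pay
#'
#' `wtp x incremental QALYs - incremental cost`; positive exactly when the
#' comparator is cost-effective at that threshold.
#'
#' @param result a [compare()] result.
#' @param wtp willingness-to-pay (USD per QALY, >= 0).
#' @export
net_monetary_benefit <- function(result, wtp) {
  stopifnot(inherits(result, "cea_result"))
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  wtp * result$d_qaly - result$d_cost
}
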